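# Batch runner for the full factorial preparation experiment:
# cropping (EEC / BCO) x smoothing (on / off) x resampling ladder,
# with per-row failure bookkeeping (a metric that cannot be computed is
# recorded as missing with a reason, and that data point is simply omitted
# from downstream analyses).

#' Run a factorial preparation study
#'
#' For every specimen and every requested combination of cropping method,
#' resampling level and smoothing flag, executes the canonical pipeline
#' crop -> decimate -> smooth -> metrics and collects one tidy row. EEC
#' (entire enamel cap) keeps the surface as supplied; BCO (basin cut-off)
#' crops at a horizontal plane, estimated from the mesh via
#' [estimate_basin_plane()] unless supplied per specimen. Decimation always
#' starts from the cropped original, never from a previously decimated level.
#' Failures (degenerate levels, destroyed surfaces) produce rows with missing
#' metrics and a reason code; the run continues.
#'
#' @param specimens named list of [ct_mesh()] objects, or a data frame with
#'   columns `specimen_id`, `path` (PLY files) and optional `diet`, `clade`.
#' @param manifest optional data frame with `specimen_id` plus `diet`,
#'   `clade`, `z_plane` columns to join onto the results.
#' @param croppings subset of `c("EEC", "BCO")`.
#' @param smoothing subset of `c(FALSE, TRUE)`.
#' @param ladder_mode `"count"` or `"resolution"`.
#' @param ladder_values numeric resampling levels (default the canonical
#'   ladder for the mode).
#' @param lambda_step,iterations smoothing parameters.
#' @param basin_margin margin fraction for [estimate_basin_plane()].
#' @param metrics metrics to compute (see [compute_metrics()]).
#' @param pcv_croppings,pcv_min_count restrict the expensive PCV measurement
#'   to these croppings and to levels whose realized triangle count is at
#'   least this large.
#' @param dne_opts,opcr_opts,pcv_opts metric option lists.
#' @param out_csv if non-NULL, the results table is also written here
#'   (deterministically; re-running yields an identical file).
#' @return data frame, one row per specimen x cropping x level x smoothing,
#'   with metric columns and a `reason` column for missing values.
#' @export
run_study <- function(specimens,
                      manifest = NULL,
                      croppings = c("EEC", "BCO"),
                      smoothing = c(FALSE, TRUE),
                      ladder_mode = c("count", "resolution"),
                      ladder_values = NULL,
                      lambda_step = 0.6, iterations = 100L,
                      basin_margin = 0.25,
                      metrics = c("dne", "opcr", "rfi", "pcv",
                                  "surface_area", "tooth_size"),
                      pcv_croppings = "EEC",
                      pcv_min_count = 0L,
                      dne_opts = dne_options(),
                      opcr_opts = opcr_options(),
                      pcv_opts = pcv_options(),
                      out_csv = NULL) {
  ladder_mode <- match.arg(ladder_mode)
  ladder_values <- ladder_values %||% resample_ladder(ladder_mode)
  if (!length(ladder_values)) ct_stop("empty resampling ladder", "ct_config_error")
  croppings <- match.arg(croppings, c("EEC", "BCO"), several.ok = TRUE)

  if (is.data.frame(specimens)) {
    ids <- specimens$specimen_id
    loaders <- lapply(specimens$path, function(p) function() read_ply(p))
    names(loaders) <- ids
    if (is.null(manifest)) {
      keep <- intersect(c("specimen_id", "diet", "clade", "z_plane"), names(specimens))
      manifest <- specimens[keep]
    }
  } else {
    ids <- names(specimens)
    if (is.null(ids)) ct_stop("specimen list must be named", "ct_config_error")
    loaders <- lapply(specimens, function(m) function() m)
  }

  rows <- list()
  for (id in ids) {
    base <- tryCatch(loaders[[id]](), error = function(e) e)
    if (inherits(base, "error")) {
      for (cr in croppings) for (lv in ladder_values) for (sm in smoothing)
        rows[[length(rows) + 1L]] <- .study_row(id, cr, sm, ladder_mode, lv,
                                                reason = conditionMessage(base))
      next
    }
    z_plane <- NULL
    if (!is.null(manifest) && "z_plane" %in% names(manifest)) {
      zi <- manifest$z_plane[match(id, manifest$specimen_id)]
      if (length(zi) == 1L && is.finite(zi)) z_plane <- zi
    }
    for (cr in croppings) {
      cropped <- tryCatch({
        if (cr == "EEC") base
        else crop_bco(base, z_plane %||% estimate_basin_plane(base, basin_margin))
      }, error = function(e) e)
      if (inherits(cropped, "error")) {
        for (lv in ladder_values) for (sm in smoothing)
          rows[[length(rows) + 1L]] <- .study_row(id, cr, sm, ladder_mode, lv,
                                                  reason = conditionMessage(cropped))
        next
      }
      for (lv in ladder_values) {
        level_mesh <- tryCatch({
          if (ladder_mode == "count") decimate_to_count(cropped, lv)
          else decimate_to_resolution(cropped, lv)$mesh
        }, error = function(e) e, warning = function(w) {
          suppressWarnings(if (ladder_mode == "count") decimate_to_count(cropped, lv)
                           else decimate_to_resolution(cropped, lv)$mesh)
        })
        for (sm in smoothing) {
          if (inherits(level_mesh, "error")) {
            rows[[length(rows) + 1L]] <- .study_row(id, cr, sm, ladder_mode, lv,
                                                    reason = conditionMessage(level_mesh))
            next
          }
          prepared <- tryCatch({
            if (sm) suppressWarnings(smooth_mesh(level_mesh, lambda_step, iterations))
            else level_mesh
          }, error = function(e) e)
          if (inherits(prepared, "error")) {
            rows[[length(rows) + 1L]] <- .study_row(id, cr, sm, ladder_mode, lv,
                                                    reason = conditionMessage(prepared))
            next
          }
          want <- metrics
          if (!(cr %in% pcv_croppings) || n_faces(prepared) < pcv_min_count)
            want <- setdiff(want, "pcv")
          ms <- compute_metrics(prepared, metrics = want, dne_opts = dne_opts,
                                opcr_opts = opcr_opts, pcv_opts = pcv_opts)
          reasons <- attr(ms, "reasons")
          reason <- if (length(reasons))
            paste(names(reasons), unlist(reasons), sep = ": ", collapse = "; ")
          else if (isTRUE(attr(prepared, "ct_destroyed"))) "surface destroyed by smoothing"
          else NA_character_
          row <- .study_row(id, cr, sm, ladder_mode, lv, reason = reason)
          row[names(ms)] <- as.data.frame(ms)
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(manifest)) {
    extra <- setdiff(intersect(c("diet", "clade"), names(manifest)), names(out))
    for (col in extra)
      out[[col]] <- manifest[[col]][match(out$specimen_id, manifest$specimen_id)]
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

.study_row <- function(id, cropping, smoothed, level_mode, level_value,
                       reason = NA_character_) {
  data.frame(specimen_id = id, cropping = cropping, smoothed = smoothed,
             level_mode = level_mode, level_value = level_value,
             dne = NA_real_, opcr = NA_real_, rfi = NA_real_,
             pcv_mean = NA_real_, surface_area = NA_real_,
             tooth_size = NA_real_, triangle_count = NA_integer_,
             resolution = NA_real_, reason = reason,
             stringsAsFactors = FALSE)
}

#' Summarize a study table
#'
#' Assembles the standard sensitivity report from a [run_study()] table:
#' percent-difference distribution summaries for smoothing (smoothed vs
#' unsmoothed) and cropping (EEC vs BCO) by triangle-count class, ln-ln
#' scaling fits of DNE and OPCR per specimen, convergence curves for the
#' converging metrics, and (when diet labels are present) per-level group
#' tests and discriminant classification rates.
#'
#' @param tbl a [run_study()] result.
#' @param metrics metric columns to summarize.
#' @return nested list of report sections; sections whose inputs are absent
#'   (e.g. convergence with a single level) are omitted with a notice in
#'   `$notes`.
#' @export
study_report <- function(tbl, metrics = c("dne", "opcr", "rfi", "pcv_mean",
                                          "surface_area", "tooth_size")) {
  stopifnot(nrow(tbl) > 0)
  metrics <- intersect(metrics, names(tbl))
  notes <- character()
  rep <- list()

  key <- c("specimen_id", "cropping", "level_mode", "level_value")
  if (all(c(TRUE, FALSE) %in% unique(tbl$smoothed))) {
    sm <- tbl[tbl$smoothed, c(key, metrics, "triangle_count")]
    un <- tbl[!tbl$smoothed, c(key, metrics)]
    j <- merge(sm, un, by = key, suffixes = c("_s", "_u"))
    j$bin <- bin_by_triangle_count(j$triangle_count)
    rep$smoothing <- .pct_diff_section(j, metrics, "_s", "_u", "smoothing")
  } else notes <- c(notes, "smoothing comparison omitted: need both smoothed and unsmoothed runs")

  key2 <- c("specimen_id", "smoothed", "level_mode", "level_value")
  if (all(c("EEC", "BCO") %in% unique(tbl$cropping))) {
    crop_metrics <- setdiff(metrics, "pcv_mean")  # PCV is usually EEC-only
    ee <- tbl[tbl$cropping == "EEC", c(key2, crop_metrics, "triangle_count")]
    bc <- tbl[tbl$cropping == "BCO", c(key2, crop_metrics)]
    j <- merge(ee, bc, by = key2, suffixes = c("_e", "_b"))
    j$bin <- bin_by_triangle_count(j$triangle_count)
    rep$cropping <- .pct_diff_section(j, crop_metrics, "_e", "_b", "cropping")
  } else notes <- c(notes, "cropping comparison omitted: need both EEC and BCO runs")

  lvls <- sort(unique(tbl$level_value))
  if (length(lvls) >= 7L) {
    fits <- list()
    for (m in intersect(c("dne", "opcr"), metrics)) {
      per_spec <- lapply(split(tbl, list(tbl$specimen_id, tbl$cropping, tbl$smoothed),
                               drop = TRUE), function(d) {
        tryCatch(loglog_fit(d$level_value, d[[m]]), error = function(e) NULL)
      })
      per_spec <- Filter(Negate(is.null), per_spec)
      if (length(per_spec))
        fits[[m]] <- data.frame(
          group = names(per_spec),
          slope = vapply(per_spec, `[[`, 0.0, "slope"),
          intercept = vapply(per_spec, `[[`, 0.0, "intercept"),
          r_squared = vapply(per_spec, `[[`, 0.0, "r_squared"),
          row.names = NULL)
    }
    rep$loglog <- fits
  } else notes <- c(notes, "ln-ln fits omitted: need at least 7 levels")

  if (length(lvls) >= 2L) {
    conv <- list()
    for (m in intersect(c("rfi", "pcv_mean", "surface_area", "tooth_size"), metrics)) {
      per_spec <- lapply(split(tbl, list(tbl$specimen_id, tbl$cropping, tbl$smoothed),
                               drop = TRUE), function(d) {
        d <- d[is.finite(d[[m]]), ]
        if (nrow(d) < 2L) return(NULL)
        cv <- tryCatch(convergence_curve(d$level_value, d[[m]]),
                       error = function(e) NULL)
        cv
      })
      per_spec <- Filter(Negate(is.null), per_spec)
      if (length(per_spec)) {
        all <- do.call(rbind, per_spec)
        conv[[m]] <- stats::aggregate(abs_pct_diff ~ level, data = all, FUN = mean)
      }
    }
    rep$convergence <- conv
  } else notes <- c(notes, "convergence section omitted: single level")

  if ("diet" %in% names(tbl) && length(unique(stats::na.omit(tbl$diet))) >= 2L) {
    groups <- list()
    cells <- split(tbl, list(tbl$cropping, tbl$smoothed, tbl$level_value), drop = TRUE)
    for (cell in names(cells)) {
      d <- cells[[cell]]
      res <- list()
      for (m in metrics) {
        ok <- is.finite(d[[m]]) & !is.na(d$diet)
        if (sum(ok) < 4L || length(unique(d$diet[ok])) < 2L) next
        res[[m]] <- tryCatch(list(
          anova = anova_oneway(d[[m]][ok], d$diet[ok])[c("f", "p")],
          dfa_success = dfa_loocv(d[[m]][ok], d$diet[ok])
        ), error = function(e) NULL)
      }
      groups[[cell]] <- Filter(Negate(is.null), res)
    }
    rep$diet <- groups
  }

  rep$notes <- notes
  rep
}

.pct_diff_section <- function(j, metrics, suf_a, suf_b, mode) {
  out <- list()
  for (m in metrics) {
    a <- j[[paste0(m, suf_a)]]
    b <- j[[paste0(m, suf_b)]]
    pd <- percent_difference(a, b, mode)
    keep <- is.finite(pd)
    n_excluded <- sum(!keep & !is.na(a) & !is.na(b))
    per_bin <- lapply(split(pd[keep], j$bin[keep], drop = TRUE),
                      function(x) if (length(x)) summarize_distribution(x) else NULL)
    per_bin <- Filter(Negate(is.null), per_bin)
    if (length(per_bin)) {
      s <- do.call(rbind, per_bin)
      s$bin <- names(per_bin)
      out[[m]] <- list(by_bin = s, n_excluded_infinite = n_excluded)
    }
  }
  out
}
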