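test_that("percent differences follow the study formulas", {
  expect_equal(percent_difference(90, 100, "smoothing"), -100 / 9, tolerance = 1e-6)
  expect_equal(percent_difference(100, 50, "cropping"), 50)
  expect_identical(percent_difference(0, 5, "smoothing"), Inf)
  expect_true(is.nan(percent_difference(0, 0, "smoothing")))
  # vectorized
  expect_equal(percent_difference(c(100, 200), c(50, 100), "cropping"), c(50, 50))
})

test_that("triangle-count classes use the stated half-open boundaries", {
  x <- bin_by_triangle_count(c(100, 209, 210, 1799, 1800, 9999, 10000, 250000))
  expect_equal(as.character(x), c("L", "L", "ML", "ML", "MH", "MH", "H", "H"))
})

test_that("distribution summaries use linear-interpolation quantiles", {
  s <- summarize_distribution(c(-1, 0, 1))
  expect_equal(s$mean, 0)
  expect_equal(s$median, 0)
  expect_equal(s$prob_gt_zero, 1 / 3, tolerance = 1e-6)

  s2 <- summarize_distribution(1:100)
  expect_equal(s2$q025, 3.475)
  expect_equal(s2$q975, 97.525)

  s3 <- summarize_distribution(rep(7, 5))
  expect_equal(s3$sd, 0)
  expect_equal(c(s3$q025, s3$median, s3$q975), c(7, 7, 7))
  expect_true(s3$q025 <= s3$median && s3$median <= s3$q975)

  expect_error(summarize_distribution(c(1, Inf)), class = "ct_validation_error")
  expect_error(summarize_distribution(numeric()), class = "ct_validation_error")
})

test_that("one-way ANOVA matches the textbook F statistic", {
  # equal group means: F exactly 0, p = 1
  y <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- anova_oneway(y, g)
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)

  # strong separation is detected
  set.seed(21)
  y2 <- c(rnorm(50), rnorm(50, 5))
  g2 <- rep(c("a", "b"), each = 50)
  expect_lt(anova_oneway(y2, g2)$p, 1e-6)

  # dual route: aov-based F equals a hand-computed F
  set.seed(22)
  y3 <- rnorm(30)
  g3 <- sample(c("a", "b", "c"), 30, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  expect_equal(anova_oneway(y3, g3)$f, manual_f_stat(y3, g3))

  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "b",
               class = "ct_validation_error")
})

test_that("factorial ANOVA reduces to one-way and calibrates interactions", {
  set.seed(31)
  d <- data.frame(y = rnorm(40), f1 = rep(c("a", "b"), each = 20))
  tab <- anova_factorial(d, "f1", "y")
  ow <- anova_oneway(d$y, d$f1)
  expect_equal(tab$f, ow$f)
  expect_equal(tab$p, ow$p)

  # balanced 2x2 with purely additive effects: interaction rarely significant
  set.seed(32)
  hits <- replicate(200, {
    d <- expand.grid(f1 = c("a", "b"), f2 = c("c", "d"), rep = 1:8)
    d$y <- rnorm(nrow(d)) + (d$f1 == "b") * 1 + (d$f2 == "d") * 2
    tab <- anova_factorial(d, c("f1", "f2"), "y")
    tab$p[tab$term == "f1:f2"] < 0.05
  })
  expect_lt(mean(hits), 0.10)

  # an injected interaction is detected at large n
  set.seed(33)
  d <- expand.grid(f1 = c("a", "b"), f2 = c("c", "d"), rep = 1:50)
  d$y <- rnorm(nrow(d)) + (d$f1 == "b" & d$f2 == "d") * 1.5
  tab <- anova_factorial(d, c("f1", "f2"), "y")
  expect_lt(tab$p[tab$term == "f1:f2"], 0.01)

  # aliased designs are refused
  d2 <- data.frame(y = rnorm(8), f1 = rep(c("a", "b"), 4),
                   f2 = rep(c("a", "b"), 4))  # f2 identical to f1
  expect_error(anova_factorial(d2, c("f1", "f2"), "y"),
               class = "ct_validation_error")
})

test_that("Tukey HSD flags only genuinely shifted pairs", {
  y <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  t0 <- tukey_hsd(y, g)
  expect_true(all(t0$p_matrix >= 0.99))
  expect_identical(diag(t0$p_matrix), c(a = 1, b = 1, c = 1))
  expect_identical(t0$p_matrix, t(t0$p_matrix))

  set.seed(41)
  y2 <- c(rnorm(20), rnorm(20), rnorm(20, 4))
  g2 <- rep(c("a", "b", "c"), each = 20)
  t2 <- tukey_hsd(y2, g2)
  expect_lt(t2$p_matrix["a", "c"], 0.001)
  expect_lt(t2$p_matrix["b", "c"], 0.001)
  expect_gt(t2$p_matrix["a", "b"], 0.05)

  # five classes give choose(5, 2) = 10 pairwise comparisons
  set.seed(42)
  y5 <- rnorm(50)
  g5 <- rep(letters[1:5], each = 10)
  expect_equal(nrow(tukey_hsd(y5, g5)$pairs), 10L)
})

test_that("equal-prior LOO-CV discriminant analysis classifies sanely", {
  # perfectly separated one-dimensional classes
  y <- c(rep(0, 10) + seq(0, 0.9, 0.1), rep(10, 10) + seq(0, 0.9, 0.1))
  g <- rep(c("a", "b"), each = 10)
  expect_equal(dfa_loocv(y, g), 100)

  # identical distributions: near 50% for two classes
  set.seed(51)
  y2 <- rnorm(400)
  g2 <- rep(c("a", "b"), each = 200)
  expect_lt(abs(dfa_loocv(y2, g2) - 50), 10)

  # invariant to affine rescaling of a feature
  set.seed(52)
  x <- cbind(rnorm(60), rnorm(60))
  g3 <- rep(c("a", "b", "c"), each = 20)
  x[, 1] <- x[, 1] + (g3 == "a") * 1.5
  r1 <- dfa_loocv(x, g3)
  x2 <- x
  x2[, 1] <- 100 * x2[, 1] - 7
  expect_equal(dfa_loocv(x2, g3), r1)

  expect_error(dfa_loocv(rep(1, 20), rep(c("a", "b"), 10)),
               class = "ct_validation_error")
})

test_that("the correlation screen applies the Bonferroni family threshold", {
  set.seed(61)
  x <- data.frame(a = rnorm(50))
  x$b <- 2 * x$a
  x$c <- rnorm(50)
  x$d <- rnorm(50)
  x$e <- rnorm(50)
  x$f <- rnorm(50)
  cs <- correlation_screen(x)
  expect_equal(nrow(cs), 15L)                  # choose(6, 2)
  expect_equal(attr(cs, "threshold"), 0.05 / 15)
  ab <- cs[cs$var1 == "a" & cs$var2 == "b", ]
  expect_equal(ab$r, 1)
  expect_true(ab$significant)
  cd <- cs[cs$var1 == "c" & cs$var2 == "d", ]
  expect_false(cd$significant)

  # constant columns yield NA, never a significance flag
  x$f <- 1
  cs2 <- correlation_screen(x)
  expect_true(all(is.na(cs2$r[cs2$var1 == "f" | cs2$var2 == "f"])))
  expect_false(any(cs2$significant[cs2$var1 == "f" | cs2$var2 == "f"]))
})

test_that("ln-ln fits recover exact power laws on the top seven levels", {
  lv <- c(100, 200, 500, 1000, 2000, 5000, 10000, 20000, 50000, 100000)
  fit <- loglog_fit(lv, 2 * lv^0.5)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, log(2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_levels_used, 7L)

  # the three lowest levels are ignored entirely
  y <- 2 * lv^0.5
  y[1:3] <- c(9999, 1, 42)                     # garbage below the cut
  fit2 <- loglog_fit(lv, y)
  expect_equal(fit2$slope, 0.5, tolerance = 1e-10)

  fit3 <- loglog_fit(lv, rep(3, 10))
  expect_equal(fit3$slope, 0)

  expect_error(loglog_fit(lv[1:5], lv[1:5]), class = "ct_validation_error")
  y4 <- 2 * lv^0.5
  y4[10] <- -1
  expect_error(loglog_fit(lv, y4), class = "ct_validation_error")
})

test_that("convergence curves measure distance to the highest level", {
  cc <- convergence_curve(c(1, 2, 3), c(8, 9, 10))
  expect_equal(cc$abs_pct_diff, c(20, 10, 0))
  cc2 <- convergence_curve(1:5, rep(2.5, 5))
  expect_true(all(cc2$abs_pct_diff == 0))
  expect_error(convergence_curve(1:3, c(1, 2, 0)), class = "ct_validation_error")
  expect_error(convergence_curve(1, 1), class = "ct_validation_error")
})
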