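test_that("Kendall tau matches brute-force pair counting", {
  # (1,2,3,4) vs (1,3,2,4): 5 concordant, 1 discordant -> 4/6
  kt <- kendall_tau(c(1, 2, 3, 4, 5), c(1, 3, 2, 4, 5))
  pairs <- utils::combn(5, 2)
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 4, 5)
  conc <- sum(sign(x[pairs[2, ]] - x[pairs[1, ]]) ==
                sign(y[pairs[2, ]] - y[pairs[1, ]]))
  expect_equal(unname(kt["tau"]), (conc - (10 - conc)) / 10)
  # perfect concordance and antisymmetry
  expect_equal(unname(kendall_tau(1:6, 2 * (1:6))["tau"]), 1)
  expect_equal(unname(kendall_tau(6:1, c(1, 3, 2, 4, 5, 6))["tau"]),
               -unname(kendall_tau(1:6, c(1, 3, 2, 4, 5, 6))["tau"]))
  expect_error(kendall_tau(rep(1, 6), 1:6), "constant")
})

test_that("detectable effect sizes reproduce the closed-form power analysis", {
  p158 <- detectable_effect(158)
  expect_equal(round(p158$r_min, 2), 0.22)
  expect_equal(round(p158$tau_min, 2), 0.14)
  p40 <- detectable_effect(40)
  expect_equal(round(p40$r_min, 2), 0.43)
  expect_equal(round(p40$tau_min, 2), 0.28)
  # consistency limit: detectable effect shrinks with n
  rs <- vapply(c(20, 50, 100, 500, 5000), function(n) detectable_effect(n)$r_min,
               numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_lt(rs[5], 0.05)
  expect_error(detectable_effect(3), "exceed 3")
})

test_that("all-subsets averaging has coherent weights and degenerate limits", {
  set.seed(10)
  n <- 80
  dd <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dd$carbon <- exp(1 + 0.8 * dd$x1 + rnorm(n, 0, 0.2))
  ms <- fit_all_subsets(dd, response = "carbon",
                        predictors = c("x1", "x2", "x3"))
  expect_equal(nrow(ms$models), 8)                     # 2^3 subsets
  expect_equal(sum(ms$models$weight), 1)
  # weights re-derivable from AICc (e^(-delta/2) normalization)
  w <- exp(-(ms$models$aicc - min(ms$models$aicc)) / 2)
  expect_equal(ms$models$weight, w / sum(w), tolerance = 1e-12)
  # weights invariant to a constant shift of AICc
  w2 <- exp(-((ms$models$aicc + 7) - min(ms$models$aicc + 7)) / 2)
  expect_equal(w2 / sum(w2), ms$models$weight, tolerance = 1e-12)
  # the true driver dominates; noise predictors shrink toward zero
  expect_gt(ms$sum_weights["x1"], 0.99)
  expect_lt(abs(ms$averaged_coef["x2"]), 0.1)
  expect_gt(ms$averaged_coef["x1"], 0.5)
  # confidence set: cumulative weight reaches the cutoff at the last member
  tab <- ms$models
  cw <- cumsum(tab$weight)
  k <- sum(tab$in_confidence_set)
  expect_gte(cw[k], 0.95)
  if (k > 1) expect_lt(cw[k - 1], 0.95)
})

test_that("a cwd-driven world concentrates summed weights on cwd", {
  set.seed(12)
  n <- 150
  dd <- data.frame(diversity = rnorm(n), cwd = rnorm(n), mat = rnorm(n),
                   map_ = rnorm(n), teb = rnorm(n), cn = rnorm(n),
                   texture = rnorm(n))
  dd$carbon <- exp(5 + 0.5 * dd$cwd + rnorm(n, 0, 0.3))
  ms <- fit_all_subsets(dd)
  expect_equal(nrow(ms$models), 128)
  expect_gt(ms$sum_weights["cwd"], 0.98)
  expect_lt(abs(ms$averaged_coef["diversity"]),
            abs(ms$averaged_coef["cwd"]))
})

test_that("SAR error model nests OLS at lambda zero and ML dominates OLS", {
  set.seed(3)
  n <- 60
  lat <- runif(n, -3, 3); lon <- runif(n, 10, 20)
  W <- knn_weights(lat, lon, k = 6)
  expect_equal(rowSums(W), rep(1, n))
  X <- cbind(a = rnorm(n), b = rnorm(n))
  u <- solve(diag(n) - 0.5 * W, rnorm(n))
  y <- 2 + X[, 1] - 0.5 * X[, 2] + u
  f0 <- fit_sar_error(y, X, W, lambda = 0)
  ols <- stats::lm(y ~ X)
  expect_equal(unname(f0$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(f0$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-8)
  fml <- fit_sar_error(y, X, W)
  expect_gte(fml$logLik, fml$logLik_ols - 1e-8)
  expect_error(fit_sar_error(y, cbind(X, X[, 1]), W), "singular")
})

test_that("continent summaries bootstrap CIs and Tukey letters behave", {
  set.seed(5)
  g <- rep(c("A", "B", "C"), each = 30)
  v <- c(rnorm(30, 10), rnorm(30, 10), rnorm(30, 20))
  cs <- continent_summaries(v, g, n_boot = 500, seed = 9)
  expect_equal(nrow(cs), 3)
  expect_true(all(cs$ci_lo <= cs$mean & cs$mean <= cs$ci_hi))
  # far-apart group gets its own letter; similar groups share
  expect_equal(cs$letter[cs$group == "A"], cs$letter[cs$group == "B"])
  expect_false(cs$letter[cs$group == "C"] %in%
                 cs$letter[cs$group %in% c("A", "B")])
  # constant group: degenerate CI at the constant
  v2 <- c(rep(7, 30), rnorm(60, 9))
  g2 <- rep(c("A", "B", "C"), each = 30)
  cs2 <- continent_summaries(v2, g2, n_boot = 100, seed = 1)
  expect_equal(cs2$ci_lo[cs2$group == "A"], 7)
  expect_equal(cs2$ci_hi[cs2$group == "A"], 7)
})

test_that("bootstrap CI of a normal mean has near-nominal coverage", {
  set.seed(77)
  cover <- vapply(1:200, function(i) {
    v <- rnorm(60)
    g <- rep(c("A", "B"), each = 30)
    cs <- continent_summaries(v, g, n_boot = 200, seed = i)
    cs$ci_lo[1] <= 0 && 0 <= cs$ci_hi[1]
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 0.99)
})

test_that("structural correlates report all eight comparisons", {
  sc <- structural_correlates(fix_carbon_plot, fix_div_plot)
  expect_equal(nrow(sc), 8)
  # carbon is built from basal area, so the association must be positive
  expect_gt(sc$tau[sc$response == "carbon" & sc$attribute == "basal_area"], 0)
})
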