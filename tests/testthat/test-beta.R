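test_that("Sorensen similarity counts shared and unique taxa", {
  expect_equal(sorensen(c("x", "y", "z"), c("x", "y", "z")), 1)
  expect_equal(sorensen(c("a", "b"), c("c", "d")), 0)
  expect_equal(sorensen(c("x", "y", "z"), c("y", "z", "w")), 4 / 6)
  # duplicates and NA are ignored; symmetry
  expect_equal(sorensen(c("x", "x", "y", NA), c("y", "w")),
               sorensen(c("y", "w"), c("x", "y")))
  expect_error(sorensen(character(0), "a"), "non-empty")
})

test_that("haversine distance matches arc length and is symmetric", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  # one degree of longitude on the equator
  expect_equal(haversine_km(0, 0, 0, 1), 6371.0088 * pi / 180, tolerance = 1e-9)
  set.seed(2)
  for (i in 1:10) {
    p <- runif(4, -60, 60)
    expect_equal(haversine_km(p[1], p[2], p[3], p[4]),
                 haversine_km(p[3], p[4], p[1], p[2]))
  }
  expect_error(haversine_km(95, 0, 0, 0), "lat")
})

test_that("pairwise similarity matrix logic is symmetric with unit diagonal", {
  pr <- pairwise_similarity(fix_stems, fix_data$plots, min_identified = 0)
  expect_true(all(pr$sorensen >= 0 & pr$sorensen <= 1))
  expect_true(all(pr$distance_km >= 0))
  # only within-continent pairs
  n_sa <- sum(fix_data$plots$continent == "SouthAmerica")
  n_af <- sum(fix_data$plots$continent == "Africa")
  expect_equal(nrow(pr), choose(n_sa, 2) + choose(n_af, 2))
  # self-similarity via the underlying metric
  taxa <- unique(fix_stems$taxon[!is.na(fix_stems$taxon)])
  expect_equal(sorensen(taxa, taxa), 1)
})

test_that("flat similarities produce a zero slope and log-mean intercept", {
  set.seed(4)
  cmb <- utils::combn(10, 2)
  pr <- data.frame(plot_a = sprintf("p%d", cmb[1, ]),
                   plot_b = sprintf("p%d", cmb[2, ]),
                   sorensen = 0.4, distance_km = runif(45, 0, 800))
  fit <- fit_distance_decay(pr, n_boot = 50, seed = 1)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$alpha, log(0.4), tolerance = 1e-8)
  expect_true(fit$ci_beta[1] <= fit$beta && fit$beta <= fit$ci_beta[2])
})

test_that("decay fit is invariant to plot relabeling", {
  cfg <- sim_config(n_plots_per_continent = c(Africa = 20), seed = 15)
  d <- make_plots(cfg, make_pool(cfg, "Africa"))
  pr <- pairwise_similarity(d$stems, d$plots, min_identified = 0)
  f1 <- fit_distance_decay(pr, n_boot = 10, seed = 1)
  pr2 <- pr[sample(nrow(pr)), ]
  relab <- setNames(sprintf("q%02d", seq_along(unique(c(pr$plot_a, pr$plot_b)))),
                    unique(c(pr$plot_a, pr$plot_b)))
  pr2$plot_a <- unname(relab[pr2$plot_a])
  pr2$plot_b <- unname(relab[pr2$plot_b])
  f2 <- fit_distance_decay(pr2, n_boot = 10, seed = 1)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-10)
})

test_that("gamma null similarity matches the closed-form expectation", {
  pairs <- data.frame(plot_a = "A", plot_b = "B", sorensen = 0.5)
  rich <- c(A = 20, B = 30)
  u <- gamma_null_similarity(pairs, rich, pool_size = 100, mode = "uniform")
  expect_equal(u$expected_sorensen, 2 * (20 * 30 / 100) / (20 + 30))
  expect_equal(u$delta_sorensen, 0.5 - u$expected_sorensen)
  # both plots drawing the whole pool are identical
  full <- gamma_null_similarity(data.frame(plot_a = "A", plot_b = "B",
                                           sorensen = 1),
                                c(A = 50, B = 50), pool_size = 50, "uniform")
  expect_equal(full$expected_sorensen, 1)
  # frequency mode with equal frequencies agrees with uniform (MC tolerance)
  f <- gamma_null_similarity(pairs, rich, pool_size = rep(1, 100),
                             mode = "frequency", n_rep = 4000, seed = 2)
  mc_se <- 0.02
  expect_lt(abs(f$expected_sorensen - u$expected_sorensen), 2 * mc_se)
  expect_error(gamma_null_similarity(pairs, c(A = 200, B = 30), 100, "uniform"),
               "pool smaller")
})

test_that("with zero turnover the decay CI excludes zero at near-nominal rate", {
  # 40 independent null worlds; the bootstrap CI should exclude zero in
  # about 5% of them (binomial-consistent upper bound at this sample size)
  excl <- vapply(1:40, function(s) {
    cfg <- sim_config(n_plots_per_continent = c(Africa = 25), decay_rate = 0,
                      seed = 500 + s)
    d <- make_plots(cfg, make_pool(cfg, "Africa"))
    pr <- pairwise_similarity(d$stems, d$plots, min_identified = 0)
    f <- fit_distance_decay(pr, n_boot = 199, seed = 1)
    f$ci_beta[1] > 0 || f$ci_beta[2] < 0
  }, logical(1))
  expect_lte(mean(excl), 0.15)
})
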