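test_that("trait summaries compute basal-area-weighted means and dispersion", {
  # basal areas in ratio 1:3 via D = 20 and 20*sqrt(3)
  stems <- data.frame(plot_id = "P", subplot_id = 1,
                      taxon = c("s1", "s2"),
                      diameter_cm = c(20, 20 * sqrt(3)))
  traits <- data.frame(taxon = c("s1", "s2"), wood_density = c(0.5, 0.9),
                       max_diameter = c(50, 90))
  ts <- trait_summaries(stems, traits, "plot")
  expect_equal(ts$cwm_wd, 0.8)
  expect_true(ts$has_large)   # s2 reaches 90 >= 70 cm
  expect_true(ts$has_dense)   # s2 at 0.9 >= 0.8
  # monoculture: no dispersion
  mono <- data.frame(plot_id = "P", subplot_id = 1, taxon = "s1",
                     diameter_cm = c(20, 30, 40))
  tm <- trait_summaries(mono, traits, "plot")
  expect_equal(tm$fdis, 0)
  expect_equal(tm$sd_wd, 0)
})

test_that("functional dispersion is invariant to species relabeling", {
  set.seed(3)
  traits <- data.frame(taxon = sprintf("s%d", 1:6),
                       wood_density = runif(6, 0.3, 1),
                       max_diameter = runif(6, 20, 120))
  stems <- data.frame(plot_id = "P", subplot_id = 1,
                      taxon = sample(traits$taxon, 40, replace = TRUE),
                      diameter_cm = runif(40, 10, 60))
  t1 <- trait_summaries(stems, traits, "plot")
  relab <- setNames(sprintf("z%d", 6:1), traits$taxon)
  stems2 <- transform(stems, taxon = unname(relab[taxon]))
  traits2 <- transform(traits, taxon = unname(relab[taxon]))
  t2 <- trait_summaries(stems2, traits2, "plot")
  expect_equal(t2$fdis, t1$fdis, tolerance = 1e-12)
  expect_equal(t2$cwm_wd, t1$cwm_wd, tolerance = 1e-12)
})

test_that("uniform null curve is exact hypergeometric and monotone", {
  pool <- data.frame(wood_density = runif(100, 0.3, 0.7),
                     max_diameter = c(rep(80, 20), rep(40, 80)))
  nc <- null_sampling_curve(pool, "max_diameter", 70, "uniform",
                            richness_grid = c(1, 5, 20, 81, 100))
  expect_equal(nc$p_expected[1], 0.2)                       # single draw
  expect_equal(nc$p_expected[2], 1 - choose(80, 5) / choose(100, 5))
  expect_equal(nc$p_expected[4], 1)                         # pigeonhole
  expect_equal(nc$p_expected[5], 1)
  full <- null_sampling_curve(pool, "max_diameter", 70, "uniform")
  expect_true(all(diff(full$p_expected) >= -1e-12))         # monotone
  expect_error(null_sampling_curve(pool, "max_diameter", 70, "uniform",
                                   richness_grid = 200), "pool size")
  expect_error(null_sampling_curve(
    data.frame(wood_density = 1, max_diameter = c(80, 90)),
    "max_diameter", 70, "uniform"), "both sides")
})

test_that("frequency-mode null curve matches uniform under equal frequencies", {
  pool <- data.frame(wood_density = runif(60, 0.3, 0.7),
                     max_diameter = c(rep(90, 12), rep(30, 48)),
                     rel_freq = rep(1 / 60, 60))
  grid <- c(2, 5, 10, 25)
  u <- null_sampling_curve(pool, "max_diameter", 70, "uniform", grid)
  f <- null_sampling_curve(pool, "max_diameter", 70, "frequency", grid,
                           n_rep = 5000, seed = 4)
  mc_se <- sqrt(u$p_expected * (1 - u$p_expected) / 5000)
  expect_true(all(abs(f$p_expected - u$p_expected) <= 2 * mc_se + 1e-9))
  expect_true(all(diff(f$p_expected) >= -2 * max(mc_se)))
})

test_that("occurrence model flags saturation and recovers positive slopes", {
  # saturated outcome: every subplot contains a large species
  ts <- data.frame(unit_id = sprintf("P%d:1", 1:25),
                   plot_id = sprintf("P%d", 1:25), has_large = TRUE,
                   has_dense = FALSE)
  dv <- data.frame(unit_id = ts$unit_id, richness = 5:29)
  res <- occurrence_glmm(ts, dv)
  expect_true(res$saturated)
  # synthetic world: richer subplots are likelier to hold a large species
  ts2 <- trait_summaries(fix_stems, fix_data$traits, "subplot")
  res2 <- occurrence_glmm(ts2, fix_div_sub)
  if (!res2$saturated) {
    expect_gt(res2$slope, 0)
    expect_lt(res2$p, 0.05)
  }
})

test_that("carbon-trait regressions return one row per trait predictor", {
  ts2 <- trait_summaries(fix_stems, fix_data$traits, "subplot")
  tab <- cwm_fd_regressions(fix_carbon_sub, ts2, "subplot")
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$predictor, c("cwm_wd", "cwm_maxd", "sd_wd", "fdis"))
  # carbon is allometric in wood density, so cwm_wd must come out positive
  expect_gt(tab$estimate[tab$predictor == "cwm_wd"], 0)
})
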