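test_that("Weibull height model matches its closed form and limits", {
  expect_equal(estimate_height(30, a = 50, b = 0.03, c = 0.8),
               50 * (1 - exp(-0.03 * 30^0.8)))
  # asymptote: very fast saturation approaches a for any diameter
  expect_equal(estimate_height(12, a = 50, b = 1e6, c = 0.8), 50)
  # monotone in diameter
  expect_gt(estimate_height(40, 50, 0.03, 0.8), estimate_height(20, 50, 0.03, 0.8))
  expect_error(estimate_height(30, a = -1, b = 0.03, c = 0.8), "positive")
})

test_that("stem allometry evaluates the published form in kg", {
  # rho=0.6, D=30, H=25: 0.0673 * 13500^0.976
  expect_equal(stem_agb(0.6, 30, 25), 0.0673 * (0.6 * 30^2 * 25)^0.976)
  expect_equal(stem_agb(0.6, 30, 25), 723.14, tolerance = 1e-4)
  # unit argument: rho D^2 H = 1 gives the coefficient itself
  expect_equal(stem_agb(1, 1, 1), 0.0673)
  # power-law scaling in wood density
  expect_equal(stem_agb(1.2, 30, 25) / stem_agb(0.6, 30, 25), 2^0.976)
  expect_error(stem_agb(NA, 30, 25), "resolved")
})

test_that("wood density resolves by species, genus, family, then plot mean", {
  stems <- data.frame(
    plot_id = "P1",
    taxon = c("sp1", "msp_a", "msp_b", NA),
    genus = c("g1", "g1", NA, NA),
    family = c("f1", "f1", "f1", NA),
    id_level = c("species", "genus", "family", "unidentified"),
    stringsAsFactors = FALSE
  )
  traits <- data.frame(taxon = c("sp1", "sp2", "sp3"),
                       wood_density = c(0.5, 0.7, 0.9),
                       genus = c("g1", "g1", "g2"),
                       family = c("f1", "f1", "f1"),
                       stringsAsFactors = FALSE)
  r <- resolve_wood_density(stems, traits)
  expect_equal(r$wood_density[1], 0.5)               # species match
  expect_equal(r$wood_density[2], 0.6)               # genus mean of 0.5, 0.7
  expect_equal(r$wood_density[3], 0.7)               # family mean of all three
  expect_equal(r$wood_density[4], mean(c(0.5, 0.6, 0.7)))  # plot mean
  expect_equal(r$wd_source, c("species", "genus", "family", "plot"))
})

test_that("carbon aggregation applies the 47.1% fraction and area scaling", {
  plots <- data.frame(plot_id = "P1", area_ha = 1.0, continent = "Africa",
                      subplots = 25)
  stems <- data.frame(plot_id = "P1", subplot_id = 1, taxon = "sp1",
                      diameter_cm = 30, wood_density = 0.6)
  ce <- suppressWarnings(aggregate_carbon(stems, plots, "plot"))
  h <- estimate_height(30, 50.453, 0.0471, 0.8120)
  expect_equal(ce$carbon, 0.471 * stem_agb(0.6, 30, h) / 1000)
  expect_equal(ce$carbon / ce$agb, 0.471)
  # 0.96 ha plot scales per-ha values by 1/0.96
  plots96 <- transform(plots, area_ha = 0.96)
  ce96 <- suppressWarnings(aggregate_carbon(stems, plots96, "plot"))
  expect_equal(ce96$carbon, ce$carbon / 0.96)
  expect_error(aggregate_carbon(transform(stems, diameter_cm = 9), plots, "plot"),
               ">= 10")
})

test_that("equal-sized stems give zero size inequality", {
  plots <- data.frame(plot_id = "P1", area_ha = 1, continent = "Asia",
                      subplots = 25)
  stems <- data.frame(plot_id = "P1", subplot_id = 1:5, taxon = "sp1",
                      diameter_cm = 25, wood_density = 0.6)
  ce <- suppressWarnings(aggregate_carbon(stems, plots, "plot"))
  expect_equal(ce$size_inequality, 0)
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_gt(gini(c(1, 1, 1, 100)), 0.5)
})

test_that("plot carbon equals the area-weighted aggregation of its subplots", {
  cp <- fix_carbon_plot
  cs <- fix_carbon_sub
  agg <- tapply(cs$carbon * cs$area, cs$plot_id, sum) /
    tapply(cs$area, cs$plot_id, sum)
  expect_equal(as.numeric(agg[cp$plot_id]), cp$carbon, tolerance = 1e-10)
  expect_equal(cp$carbon / cp$agb, rep(0.471, nrow(cp)), tolerance = 1e-12)
})

test_that("stemless subplots are completed with zero carbon and flagged", {
  plots <- data.frame(plot_id = "P1", area_ha = 1, continent = "Africa",
                      subplots = 4)
  stems <- data.frame(plot_id = "P1", subplot_id = c(1, 2, 2), taxon = "sp1",
                      diameter_cm = 30, wood_density = 0.6)
  expect_warning(ce <- aggregate_carbon(stems, plots, "subplot"), "no stems")
  expect_equal(nrow(ce), 4)
  expect_equal(sum(ce$flag_empty), 2)
  expect_true(all(ce$carbon[ce$flag_empty] == 0))
})

test_that("AGB increases in each of wood density, diameter and height", {
  base <- stem_agb(0.6, 30, 25)
  expect_gt(stem_agb(0.7, 30, 25), base)
  expect_gt(stem_agb(0.6, 35, 25), base)
  expect_gt(stem_agb(0.6, 30, 30), base)
})
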