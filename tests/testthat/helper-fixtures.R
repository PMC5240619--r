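# Shared small synthetic world, built once per test run. Two continents,
# 10 plots each, default study conditions.
fix_cfg <- sim_config(
  n_plots_per_continent = c(SouthAmerica = 10, Africa = 10),
  seed = 42
)
fix_data <- simulate_inventory(fix_cfg)
fix_stems <- resolve_wood_density(fix_data$stems, fix_data$traits)
fix_carbon_plot <- aggregate_carbon(fix_stems, fix_data$plots, "plot")
fix_carbon_sub <- suppressWarnings(
  aggregate_carbon(fix_stems, fix_data$plots, "subplot"))
fix_div_plot <- diversity_profile(fix_stems, "plot")
fix_div_sub <- diversity_profile(fix_stems, "subplot", correct = FALSE)

# Brute-force rarefaction oracle: enumerate every n-stem subset of a small
# community and average the species counts.
brute_rarefaction <- function(abundances, n) {
  ids <- rep(seq_along(abundances), abundances)
  subsets <- utils::combn(length(ids), n)
  mean(apply(subsets, 2, function(ix) length(unique(ids[ix]))))
}

# Bisection oracle for Fisher's alpha, independent of the package solver.
bisect_alpha <- function(S, N, lo = 1e-10, hi = 1e8, iter = 200) {
  f <- function(a) a * log(1 + N / a) - S
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
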