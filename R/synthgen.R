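#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic inventory
#' generator. Defaults emulate the study conditions of a pan-tropical
#' 1 ha plot network: plots of 1 ha divided into 25 subplots of 0.04 ha,
#' 400-700 stems >= 10 cm diameter per ha, continental species pools with
#' log-series abundance structure whose Fisher's alpha differs by continent
#' (low in Africa), compositional similarity decaying with distance, and a
#' configurable true within-subplot diversity-carbon coupling
#' (`beta_true`, default 0.096 ln carbon per ln species).
#'
#' @param n_plots_per_continent Named or unnamed counts of plots per
#'   continent (default c(SouthAmerica = 50, Africa = 50, Asia = 50)).
#' @param plot_area Plot area in ha (default 1.0).
#' @param subplots_per_plot Subplots per plot (default 25, each 0.04 ha).
#' @param stems_per_ha_range Interval of stem densities (default c(400, 700)).
#' @param pool_size Species-pool sizes per continent; NULL (default) derives
#'   them from `logseries_alpha` and `regional_stems` via the log-series
#'   relation S = alpha log(1 + N/alpha).
#' @param logseries_alpha Fisher's alpha of the pool abundance structure per
#'   continent (default c(SouthAmerica = 80, Africa = 28, Asia = 84)).
#' @param regional_stems Notional regional stem count used to derive pool
#'   sizes (default 5e5).
#' @param decay_rate Compositional turnover rate in km^-1 (default 0.001);
#'   expected similarity declines approximately as exp(-decay_rate * d).
#' @param box_km Bounding box (length, width) of each continental domain in
#'   km (default c(2000, 200); elongated so turnover is expressed along the
#'   long axis).
#' @param env_range_km Spatial range of the exponential-covariance
#'   environmental fields (default 300).
#' @param beta_true True ln-carbon per ln-richness coupling at subplot scale
#'   (default 0.096; 0 gives a null world).
#' @param gamma_true True ln-carbon per ln-stem-count coupling (default 1).
#' @param noise_sd Lognormal sd of subplot carbon noise (default 0.3).
#' @param plot_sd Between-plot sd of baseline ln carbon when
#'   `baseline_lncarbon` is set (default 0.15).
#' @param baseline_lncarbon If non-NULL, plot baselines are
#'   baseline + environmental effects + N(0, plot_sd) instead of preserving
#'   each plot's allometric carbon level.
#' @param env_effect Named coefficients of plot-level environmental drivers
#'   of ln carbon (default c(cwd = 0.001): wetter plots store more carbon).
#' @param id_probs Identification-level probabilities for
#'   species/genus/family/unidentified stems (default
#'   c(0.903, 0.05, 0.03, 0.017), matching typical inventory completeness).
#' @param pareto_shape Shape of the truncated Pareto diameter distribution
#'   (default 1.4; heavier tails mean more very large stems).
#' @param seed Master integer seed; all substreams derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_plots_per_continent = c(SouthAmerica = 50, Africa = 50,
                                                 Asia = 50),
                       plot_area = 1.0, subplots_per_plot = 25,
                       stems_per_ha_range = c(400, 700),
                       pool_size = NULL,
                       logseries_alpha = c(SouthAmerica = 80, Africa = 28,
                                           Asia = 84),
                       regional_stems = 5e5,
                       decay_rate = 0.001, box_km = c(2000, 200),
                       env_range_km = 300,
                       beta_true = 0.096, gamma_true = 1,
                       noise_sd = 0.3, plot_sd = 0.15,
                       baseline_lncarbon = NULL,
                       env_effect = c(cwd = 0.001),
                       id_probs = c(species = 0.903, genus = 0.05,
                                    family = 0.03, unidentified = 0.017),
                       pareto_shape = 1.4, seed = 1) {
  if (is.null(names(n_plots_per_continent))) {
    names(n_plots_per_continent) <-
      c("SouthAmerica", "Africa", "Asia")[seq_along(n_plots_per_continent)]
  }
  stopifnot(all(n_plots_per_continent > 0), plot_area > 0,
            subplots_per_plot >= 1, all(stems_per_ha_range > 0),
            length(stems_per_ha_range) == 2,
            all(logseries_alpha > 0), decay_rate >= 0,
            noise_sd >= 0, abs(sum(id_probs) - 1) < 1e-8,
            pareto_shape > 1, seed == as.integer(seed))
  if (!is.null(pool_size) && any(pool_size < 2)) {
    stop("pool_size must be at least 2")
  }
  cfg <- list(
    n_plots_per_continent = n_plots_per_continent, plot_area = plot_area,
    subplots_per_plot = subplots_per_plot,
    stems_per_ha_range = stems_per_ha_range,
    pool_size = pool_size, logseries_alpha = logseries_alpha,
    regional_stems = regional_stems, decay_rate = decay_rate,
    box_km = box_km, env_range_km = env_range_km,
    beta_true = beta_true, gamma_true = gamma_true,
    noise_sd = noise_sd, plot_sd = plot_sd,
    baseline_lncarbon = baseline_lncarbon, env_effect = env_effect,
    id_probs = id_probs, pareto_shape = pareto_shape, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic log-series rank relative frequencies. The expected number of
# species with abundance >= n under a log-series with parameters (alpha, x)
# is alpha * E1(n * log(1/x)); inverting it at ranks i - 0.5 gives a smooth
# rank-abundance curve with the configured Fisher's alpha.
logseries_rank_freq <- function(G, alpha, N) {
  eps <- -log(N / (N + alpha))   # log(1/x)
  e1 <- function(t) pracma::expint_E1(t)
  n_at <- function(q) {
    # solve alpha * E1(eps * n) = q for n
    f <- function(ln_n) alpha * e1(eps * exp(ln_n)) - q
    exp(stats::uniroot(f, c(log(1e-8), log(N * 10)), tol = 1e-10)$root)
  }
  q <- seq_len(G) - 0.5
  n <- vapply(q, n_at, numeric(1))
  n / sum(n)
}

#' Build a continental species pool
#'
#' Generates `pool_size` species with (i) relative occurrence frequencies
#' following a deterministic log-series rank-abundance curve with the
#' configured Fisher's alpha, (ii) wood densities from a truncated normal
#' (mean 0.6, sd 0.15, bounds 0.1-1.2 g cm^-3), (iii) maximum diameters
#' from a lognormal (median 45 cm, sdlog 0.65, floor 10 cm), and a
#' genus/family taxonomy (about 2.5 species per genus, 4 genera per
#' family).
#'
#' @param config A [sim_config()].
#' @param continent Continent label (must appear in the config).
#' @return data.frame of class `species_pool` with columns continent,
#'   species_id, genus, family, rel_freq, wood_density, max_diameter.
#' @export
make_pool <- function(config, continent) {
  alpha <- config$logseries_alpha[[continent]]
  if (is.null(alpha)) stop("no logseries_alpha for continent ", continent)
  N <- config$regional_stems
  G <- if (!is.null(config$pool_size)) {
    if (length(config$pool_size) > 1) config$pool_size[[continent]] else config$pool_size
  } else {
    max(2L, round(alpha * log1p(N / alpha)))
  }
  if (G < 2) stop("pool_size must be at least 2")
  ci <- match(continent, names(config$n_plots_per_continent))
  set.seed(substream_seed(config$seed, 11 + ci))
  rel_freq <- logseries_rank_freq(G, alpha, N)

  # traits, independent across species
  wd <- stats::qnorm(stats::runif(G, stats::pnorm(0.1, 0.6, 0.15),
                                  stats::pnorm(1.2, 0.6, 0.15)), 0.6, 0.15)
  maxd <- pmax(10.5, exp(stats::rnorm(G, log(45), 0.65)))

  n_gen <- max(1L, round(G / 2.5))
  n_fam <- max(1L, round(n_gen / 4))
  genus <- sprintf("%s_gen%03d", substr(continent, 1, 2),
                   sample.int(n_gen, G, replace = TRUE))
  fam_of_gen <- sample.int(n_fam, n_gen, replace = TRUE)
  family <- sprintf("%s_fam%03d", substr(continent, 1, 2),
                    fam_of_gen[as.integer(sub(".*gen", "", genus))])
  out <- data.frame(
    continent = continent,
    species_id = sprintf("%s_sp%04d", substr(continent, 1, 2), seq_len(G)),
    genus = genus, family = family,
    rel_freq = rel_freq, wood_density = wd, max_diameter = maxd,
    stringsAsFactors = FALSE
  )
  class(out) <- c("species_pool", "data.frame")
  out
}

# Calibrate the exponential rate of the species range-band widths so that
# the log-linear slope of expected availability similarity over the pair
# distance distribution equals the requested decay_rate (see vignette).
calibrate_band_rate <- function(decay_rate, box_length) {
  if (decay_rate <= 0) return(0)
  tgrid <- seq(0.01, 1, length.out = 40) * box_length
  wgt <- 2 * (box_length - tgrid) / box_length^2      # pair-distance density
  sim_curve <- function(lam) {
    num <- vapply(tgrid, function(t) {
      stats::integrate(function(w) pmax(w - t, 0) / (box_length + w) *
                         lam * exp(-lam * w), t, Inf, rel.tol = 1e-9)$value
    }, numeric(1))
    den <- stats::integrate(function(w) w / (box_length + w) * lam * exp(-lam * w),
                            0, Inf, rel.tol = 1e-9)$value
    num / den
  }
  fitted_slope <- function(lam) {
    # mirror the analysis model: log-link quasibinomial GLM of the
    # theoretical similarity curve over the pair-distance density
    mu <- pmin(1 - 1e-9, pmax(sim_curve(lam), 1e-12))
    fit <- suppressWarnings(stats::glm(
      mu ~ tgrid, weights = wgt,
      family = stats::quasibinomial(link = "log"),
      start = c(log(stats::weighted.mean(mu, wgt)), 0)))
    unname(stats::coef(fit)[2])
  }
  f <- function(lam) fitted_slope(lam) + decay_rate
  stats::uniroot(f, c(decay_rate / 50, decay_rate * 50), tol = decay_rate * 1e-6)$root
}

# truncated Pareto(min = 10, shape) capped below each stem's species maximum
rtrunc_pareto <- function(n, shape, upper) {
  u <- stats::runif(n)
  # inverse CDF of Pareto truncated to [10, upper]
  fu <- 1 - (10 / upper)^shape
  10 * (1 - u * fu)^(-1 / shape)
}

#' Generate plots, environments and stems for one continental pool
#'
#' Scatters plots over an elongated continental bounding box, samples
#' spatially autocorrelated environmental covariates (exponential-covariance
#' Gaussian fields), assigns each species a geographic range band along the
#' long axis (widths exponentially distributed with a rate calibrated to the
#' configured distance-decay of similarity), and draws each plot's stems
#' multinomially from the locally available pool, with truncated-Pareto
#' diameters capped near each species' maximum and stochastic identification
#' levels.
#'
#' @param config A [sim_config()].
#' @param pool A pool from [make_pool()].
#' @return List of class `synthetic_dataset` with elements stems, plots,
#'   traits, truth.
#' @export
make_plots <- function(config, pool) {
  if (nrow(pool) == 0) stop("empty species pool")
  if (any(config$box_km <= 0)) stop("degenerate bounding box")
  continent <- pool$continent[1]
  ci <- match(continent, names(config$n_plots_per_continent))
  if (is.na(ci)) stop("pool continent absent from config")
  n_plots <- config$n_plots_per_continent[[continent]]
  set.seed(substream_seed(config$seed, 101 + ci))

  bl <- config$box_km[1]; bw <- config$box_km[2]
  x <- stats::runif(n_plots, 0, bl)
  y <- stats::runif(n_plots, 0, bw)
  lon0 <- c(-70, 20, 110)[ci %% 3 + 1]
  lat <- y / 111.1949
  lon <- lon0 + x / (111.1949 * cos(lat * pi / 180))

  # spatially autocorrelated environments
  D <- as.matrix(stats::dist(cbind(x, y)))
  Sigma <- exp(-D / config$env_range_km)
  z <- MASS::mvrnorm(6, mu = rep(0, n_plots), Sigma = Sigma)
  cwd <- if (continent == "Asia") rep(0, n_plots) else pmin(0, -200 + 120 * z[1, ])
  env <- data.frame(
    cwd = cwd,
    mat = 24 + 1.5 * z[2, ],
    map_ = pmax(1300, 2200 + 400 * z[3, ]),
    teb = pmax(0.5, 8 + 3 * z[4, ]),
    cn = pmax(5, 13 + 2.5 * z[5, ]),
    texture = pmin(9, pmax(1, round(5 + 1.8 * z[6, ])))
  )
  env$mat <- pmax(20, env$mat)

  plot_id <- sprintf("%s_p%03d", substr(continent, 1, 2), seq_len(n_plots))
  plots <- data.frame(
    plot_id = plot_id, lat = lat, lon = lon, x_km = x, y_km = y,
    area_ha = config$plot_area, subplots = config$subplots_per_plot,
    continent = continent, env, stringsAsFactors = FALSE
  )

  # species availability: range bands along the long axis
  G <- nrow(pool)
  if (config$decay_rate > 0) {
    lam <- calibrate_band_rate(config$decay_rate, bl)
    W <- stats::rexp(G, rate = lam)
    L <- stats::runif(G, -W, bl)
    avail <- outer(seq_len(G), seq_len(n_plots),
                   function(s, p) x[p] >= L[s] & x[p] <= L[s] + W[s])
  } else {
    lam <- 0
    avail <- matrix(TRUE, G, n_plots)
  }

  n_stems <- round(stats::runif(n_plots, config$stems_per_ha_range[1],
                                config$stems_per_ha_range[2]) * config$plot_area)
  id_lv <- names(config$id_probs)
  stems <- vector("list", n_plots)
  for (p in seq_len(n_plots)) {
    w <- pool$rel_freq * avail[, p]
    if (sum(w) == 0) w <- pool$rel_freq
    sp <- sample.int(G, n_stems[p], replace = TRUE, prob = w)
    d <- rtrunc_pareto(n_stems[p], config$pareto_shape,
                       upper = pool$max_diameter[sp])
    lev <- sample(id_lv, n_stems[p], replace = TRUE, prob = config$id_probs)
    taxon <- ifelse(lev == "species", pool$species_id[sp],
                    ifelse(lev == "unidentified", NA_character_,
                           paste0("msp_", pool$species_id[sp])))
    stems[[p]] <- data.frame(
      plot_id = plot_id[p],
      subplot_id = sample.int(config$subplots_per_plot, n_stems[p],
                              replace = TRUE),
      taxon = taxon,
      family = ifelse(lev == "unidentified", NA_character_, pool$family[sp]),
      genus = ifelse(lev %in% c("unidentified", "family"), NA_character_,
                     pool$genus[sp]),
      species = ifelse(lev == "species", pool$species_id[sp], NA_character_),
      id_level = lev,
      diameter_cm = d,
      continent = continent,
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    stems = do.call(rbind, stems),
    plots = plots,
    traits = pool[, c("species_id", "genus", "family", "rel_freq",
                      "wood_density", "max_diameter")],
    truth = list(continent = continent, band_rate = lam,
                 decay_rate = config$decay_rate, config = config)
  )
  names(out$traits)[1] <- "taxon"
  class(out) <- "synthetic_dataset"
  out
}

# subplot carbon (Mg C ha^-1) for a set of stems, given heights model coefs
subplot_carbon <- function(diam, wd, hm, area_ha) {
  h <- estimate_height(diam, hm$a, hm$b, hm$c)
  sum(stem_agb(wd, diam, h)) / 1000 / area_ha * 0.471
}

#' Inject a known diversity-carbon coupling
#'
#' Rescales stem diameters within each subplot (power transform
#' D -> 10 (D/10)^tau, which preserves the 10 cm minimum) so that subplot
#' ln carbon equals a_plot + beta_true ln(richness) + gamma_true ln(stems)
#' + N(0, noise_sd) noise exactly. Plot baselines a_plot either preserve
#' each plot's allometric carbon level plus configured environmental
#' effects (default) or are set from `baseline_lncarbon`. Ground truth is
#' recorded in the `truth` element.
#'
#' @param data A `synthetic_dataset` from [make_plots()] (or several merged
#'   by [simulate_inventory()]).
#' @param config The same [sim_config()].
#' @return The dataset with adjusted stem diameters and augmented truth.
#' @export
inject_carbon_coupling <- function(data, config) {
  if (config$subplots_per_plot < 2 && config$beta_true != 0) {
    stop("beta_true requires at least 2 subplots per plot")
  }
  stems <- resolve_wood_density(data$stems, data$traits)
  plots <- data$plots
  set.seed(substream_seed(config$seed, 997))

  unit <- paste(stems$plot_id, stems$subplot_id, sep = ":")
  uu <- unique(unit)
  f <- match(unit, uu)
  rich <- vapply(split(stems$taxon, f), function(tx) {
    length(unique(tx[!is.na(tx)]))
  }, integer(1))
  nst <- tabulate(f, nbins = length(uu))
  up <- sub(":[0-9]+$", "", uu)
  area_sub <- plots$area_ha[match(up, plots$plot_id)] /
    plots$subplots[match(up, plots$plot_id)]
  cont <- plots$continent[match(up, plots$plot_id)]
  hm_all <- height_models(unique(cont))

  c0 <- numeric(length(uu))
  idx_by_unit <- split(seq_len(nrow(stems)), f)
  for (k in seq_along(uu)) {
    i <- idx_by_unit[[k]]
    hm <- hm_all[hm_all$continent == cont[k], ]
    c0[k] <- subplot_carbon(stems$diameter_cm[i], stems$wood_density[i],
                            hm, area_sub[k])
  }
  lnS <- log(pmax(rich, 1))
  lnN <- log(pmax(nst, 1))
  struct <- config$beta_true * lnS + config$gamma_true * lnN

  # plot baseline: preserve allometric level or set explicitly; add env effects
  ee <- config$env_effect
  envshift_p <- rep(0, nrow(plots))
  for (v in names(ee)) {
    envshift_p <- envshift_p + ee[[v]] * (plots[[v]] - mean(plots[[v]]))
  }
  names(envshift_p) <- plots$plot_id
  if (is.null(config$baseline_lncarbon)) {
    base_p <- tapply(log(pmax(c0, 1e-6)) - struct, up, mean)
    a_p <- base_p[up] + envshift_p[up]
  } else {
    delta <- stats::rnorm(nrow(plots), 0, config$plot_sd)
    names(delta) <- plots$plot_id
    a_p <- config$baseline_lncarbon + envshift_p[up] + delta[up]
  }
  eps <- stats::rnorm(length(uu), 0, config$noise_sd)
  target <- as.numeric(a_p) + struct + eps

  new_diam <- stems$diameter_cm
  for (k in seq_along(uu)) {
    i <- idx_by_unit[[k]]
    hm <- hm_all[hm_all$continent == cont[k], ]
    d0 <- stems$diameter_cm[i]
    wdk <- stems$wood_density[i]
    g <- function(tau) {
      log(subplot_carbon(10 * (d0 / 10)^tau, wdk, hm, area_sub[k])) - target[k]
    }
    lo <- 0.05; hi <- 5
    while (g(lo) > 0 && lo > 1e-4) lo <- lo / 2
    while (g(hi) < 0 && hi < 50) hi <- hi * 2
    tau <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
    new_diam[i] <- 10 * (d0 / 10)^tau
  }
  data$stems$diameter_cm <- new_diam
  data$truth$beta_true <- config$beta_true
  data$truth$gamma_true <- config$gamma_true
  data$truth$noise_sd <- config$noise_sd
  data$truth$env_effect <- config$env_effect
  data
}

#' Simulate a full multi-continent inventory
#'
#' Runs [make_pool()], [make_plots()] and [inject_carbon_coupling()] for
#' every continent in the configuration and merges the results.
#'
#' @param config A [sim_config()].
#' @return `synthetic_dataset` with stems, plots, traits, pools and truth.
#' @export
simulate_inventory <- function(config) {
  parts <- lapply(names(config$n_plots_per_continent), function(ct) {
    pool <- make_pool(config, ct)
    inject_carbon_coupling(make_plots(config, pool), config)
  })
  out <- list(
    stems = do.call(rbind, lapply(parts, `[[`, "stems")),
    plots = do.call(rbind, lapply(parts, `[[`, "plots")),
    traits = do.call(rbind, lapply(parts, `[[`, "traits")),
    truth = list(config = config,
                 per_continent = lapply(parts, `[[`, "truth"))
  )
  rownames(out$stems) <- rownames(out$plots) <- rownames(out$traits) <- NULL
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic inventory: %d stems, %d plots, %d taxa with traits\n",
              nrow(x$stems), nrow(x$plots), nrow(x$traits)))
  cat("  continents:", paste(unique(x$plots$continent), collapse = ", "), "\n")
  invisible(x)
}
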