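#' Sorensen similarity of two communities
#'
#' Presence-absence similarity 2a / (2a + b + c), where a is the number of
#' shared taxa and b, c the numbers unique to each community.
#'
#' @param taxa_a,taxa_b Character vectors (or sets) of taxon labels.
#' @return Similarity in \[0, 1\].
#' @export
sorensen <- function(taxa_a, taxa_b) {
  taxa_a <- unique(taxa_a[!is.na(taxa_a)])
  taxa_b <- unique(taxa_b[!is.na(taxa_b)])
  if (length(taxa_a) == 0L || length(taxa_b) == 0L) {
    stop("sorensen() requires two non-empty taxon sets")
  }
  a <- length(intersect(taxa_a, taxa_b))
  2 * a / (length(taxa_a) + length(taxa_b))
}

#' Pairwise Sorensen similarity and geographic distance
#'
#' Builds the table of all within-continent plot pairs with their Sorensen
#' similarity (species-level taxa, morphospecies included) and great-circle
#' distance. Plots can be filtered by identification completeness, as the
#' distance-decay analysis restricts itself to well-identified plots.
#'
#' @param stems Stem table (plot_id, taxon, id_level).
#' @param plots Plot table (plot_id, lat, lon, continent).
#' @param min_identified Minimum percentage of stems identified to species
#'   for a plot to enter (default 90, set to 0 to keep all plots).
#' @return data.frame with plot_a, plot_b, continent, sorensen, distance_km.
#' @export
pairwise_similarity <- function(stems, plots, min_identified = 90) {
  pct <- tapply(stems$id_level == "species", stems$plot_id, function(z) 100 * mean(z))
  keep <- names(pct)[pct > min_identified]
  plots <- plots[plots$plot_id %in% keep, ]
  if (nrow(plots) < 2) stop("fewer than two plots pass the identification filter")
  taxa_by_plot <- lapply(split(stems$taxon, stems$plot_id),
                         function(x) unique(x[!is.na(x)]))
  out <- list()
  for (ct in unique(plots$continent)) {
    p <- plots[plots$continent == ct, ]
    if (nrow(p) < 2) next
    cmb <- utils::combn(nrow(p), 2)
    ia <- cmb[1, ]; ib <- cmb[2, ]
    sim <- vapply(seq_along(ia), function(k) {
      sorensen(taxa_by_plot[[as.character(p$plot_id[ia[k]])]],
               taxa_by_plot[[as.character(p$plot_id[ib[k]])]])
    }, numeric(1))
    out[[ct]] <- data.frame(
      plot_a = as.character(p$plot_id[ia]), plot_b = as.character(p$plot_id[ib]),
      continent = ct, sorensen = sim,
      distance_km = haversine_km(p$lat[ia], p$lon[ia], p$lat[ib], p$lon[ib]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Distance decay of community similarity
#'
#' Fits ln(similarity) = alpha + beta * distance with a binomial-family GLM
#' (log link), similarity as the response and distance in km as the
#' predictor. 95% envelopes come from bootstrap resampling *plots* (not
#' pairs) with replacement and rebuilding the pair table, because pairwise
#' rows sharing a plot are not independent.
#'
#' @param pairs Pair table from [pairwise_similarity()] (one continent).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `decay_fit` with elements alpha, beta, ci_alpha,
#'   ci_beta, n_boot, n_plots, n_pairs.
#' @export
fit_distance_decay <- function(pairs, n_boot = 10000, seed = 1) {
  if (nrow(pairs) < 10) stop("need at least 10 plot pairs")
  plot_ids <- unique(c(pairs$plot_a, pairs$plot_b))
  if (length(plot_ids) < 3) stop("pairs must come from at least 3 plots")
  fit1 <- function(d) {
    # quasibinomial: identical point estimates to binomial, no warning for
    # the non-integer (proportion) response
    cf <- tryCatch(
      stats::coef(stats::glm(sorensen ~ distance_km, data = d,
                             family = stats::quasibinomial(link = "log"),
                             start = c(log(max(mean(d$sorensen), 1e-6)), 0))),
      error = function(e) c(NA_real_, NA_real_))
    cf
  }
  cf <- fit1(pairs)
  if (any(is.na(cf))) stop("distance-decay GLM failed to converge")

  key <- paste(pairs$plot_a, pairs$plot_b)
  key2 <- paste(pairs$plot_b, pairs$plot_a)
  lookup <- c(stats::setNames(seq_len(nrow(pairs)), key),
              stats::setNames(seq_len(nrow(pairs)), key2))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    res <- sample(plot_ids, replace = TRUE)
    cmb <- utils::combn(length(res), 2)
    k <- paste(res[cmb[1, ]], res[cmb[2, ]])
    idx <- lookup[k]
    idx <- idx[!is.na(idx)]          # drop self-pairs from duplicated plots
    if (length(idx) >= 10) boot[b, ] <- fit1(pairs[idx, ])
  }
  ok <- stats::complete.cases(boot)
  structure(list(
    alpha = unname(cf[1]), beta = unname(cf[2]),
    ci_alpha = unname(stats::quantile(boot[ok, 1], c(0.025, 0.975))),
    ci_beta = unname(stats::quantile(boot[ok, 2], c(0.025, 0.975))),
    n_boot = n_boot, n_boot_ok = sum(ok),
    n_plots = length(plot_ids), n_pairs = nrow(pairs)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Distance decay of Sorensen similarity\n")
  cat(sprintf("  ln(similarity) = %.4f + %.6f * distance_km\n", x$alpha, x$beta))
  cat(sprintf("  alpha 95%% CI [%.4f, %.4f]; beta 95%% CI [%.6f, %.6f]\n",
              x$ci_alpha[1], x$ci_alpha[2], x$ci_beta[1], x$ci_beta[2]))
  cat(sprintf("  %d plots, %d pairs, %d bootstrap resamples\n",
              x$n_plots, x$n_pairs, x$n_boot))
  invisible(x)
}

#' Expected similarity under a gamma-diversity null
#'
#' For each plot pair, the expected Sorensen similarity when each plot's
#' observed richness is drawn at random (without replacement) from the
#' continental species pool; the statistic returned per pair is observed
#' minus expected similarity, so differences in beta diversity can be
#' compared across continents after removing the effect of pool (gamma)
#' diversity. Uniform sampling uses the closed-form hypergeometric
#' expectation of the number of shared species; frequency-weighted sampling
#' is Monte-Carlo.
#'
#' @param pairs Pair table from [pairwise_similarity()].
#' @param richness Named vector of per-plot species richness (observed
#'   species-level taxa).
#' @param pool_size Number of species in the continental pool (uniform mode),
#'   or a vector of relative frequencies (frequency mode).
#' @param mode "uniform" or "frequency".
#' @param n_rep Monte-Carlo replicates for frequency mode (default 1000).
#' @param seed Integer seed (frequency mode).
#' @return `pairs` with columns expected_sorensen and delta_sorensen added.
#' @export
gamma_null_similarity <- function(pairs, richness, pool_size,
                                  mode = c("uniform", "frequency"),
                                  n_rep = 1000, seed = 1) {
  mode <- match.arg(mode)
  sa <- richness[pairs$plot_a]
  sb <- richness[pairs$plot_b]
  if (mode == "uniform") {
    G <- pool_size
    if (any(c(sa, sb) > G)) stop("pool smaller than a plot's richness")
    # E[shared] = Sa * Sb / G for independent uniform draws without replacement
    esh <- sa * sb / G
    expd <- 2 * esh / (sa + sb)
  } else {
    freq <- pool_size / sum(pool_size)
    G <- length(freq)
    if (any(c(sa, sb) > G)) stop("pool smaller than a plot's richness")
    set.seed(seed)
    # expected shared species for each distinct (Sa, Sb) combination
    combos <- unique(data.frame(sa = pmin(sa, sb), sb = pmax(sa, sb)))
    esh_map <- apply(combos, 1, function(z) {
      mean(vapply(seq_len(n_rep), function(r) {
        A <- sample.int(G, z[1], prob = freq)
        B <- sample.int(G, z[2], prob = freq)
        length(intersect(A, B))
      }, numeric(1)))
    })
    kk <- paste(pmin(sa, sb), pmax(sa, sb))
    esh <- esh_map[match(kk, paste(combos$sa, combos$sb))]
    expd <- 2 * esh / (sa + sb)
  }
  pairs$expected_sorensen <- as.numeric(expd)
  pairs$delta_sorensen <- pairs$sorensen - pairs$expected_sorensen
  pairs
}
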