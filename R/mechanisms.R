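#' Community-weighted trait summaries
#'
#' Per plot or subplot: basal-area-weighted community means (CWM) of wood
#' density and maximum diameter, the (basal-area-weighted) standard
#' deviation of wood density, functional dispersion, and flags for whether
#' any species with a large maximum diameter or dense wood is present.
#' Functional dispersion is the basal-area-weighted mean distance of the
#' species present to the community's weighted centroid in z-scored
#' (wood density, ln maximum diameter) trait space; z-scores are taken over
#' the whole trait table so values are comparable across units.
#'
#' @param stems Stem table (plot_id, subplot_id, taxon, diameter_cm).
#' @param traits Trait table (taxon, wood_density, max_diameter).
#' @param scale "plot" or "subplot".
#' @param large_threshold Maximum-diameter threshold (cm) for `has_large`
#'   (default 70).
#' @param dense_threshold Wood-density threshold (g cm^-3) for `has_dense`
#'   (default 0.8).
#' @param min_trait_ba Minimum fraction of basal area with trait coverage
#'   (default 0.8).
#' @return data.frame keyed by unit_id with cwm_wd, cwm_maxd, sd_wd, fdis,
#'   has_large, has_dense.
#' @export
trait_summaries <- function(stems, traits, scale = c("plot", "subplot"),
                            large_threshold = 70, dense_threshold = 0.8,
                            min_trait_ba = 0.8) {
  scale <- match.arg(scale)
  unit <- if (scale == "plot") as.character(stems$plot_id) else
    paste(stems$plot_id, stems$subplot_id, sep = ":")
  ti <- match(stems$taxon, traits$taxon)
  wd <- traits$wood_density[ti]
  maxd <- traits$max_diameter[ti]
  ba <- stem_basal_area(stems$diameter_cm)
  z_wd <- (traits$wood_density - mean(traits$wood_density)) /
    stats::sd(traits$wood_density)
  z_md <- (log(traits$max_diameter) - mean(log(traits$max_diameter))) /
    stats::sd(log(traits$max_diameter))

  rows <- lapply(split(seq_along(unit), unit), function(idx) {
    ok <- !is.na(wd[idx])
    cover <- sum(ba[idx][ok]) / sum(ba[idx])
    if (!any(ok)) stop("unit with no resolvable traits: ", unit[idx[1]])
    i <- idx[ok]
    w <- ba[i]
    # species-level table: sum basal area over stems of each species
    sp <- tapply(w, stems$taxon[i], sum)
    sidx <- match(names(sp), traits$taxon)
    spw <- as.numeric(sp) / sum(sp)
    zz <- cbind(z_wd[sidx], z_md[sidx])
    centroid <- colSums(spw * zz)
    fdis <- sum(spw * sqrt(rowSums(sweep(zz, 2, centroid)^2)))
    cwm_wd <- sum(w * wd[i]) / sum(w)
    data.frame(
      unit_id = unit[idx[1]],
      plot_id = as.character(stems$plot_id[idx[1]]),
      cwm_wd = cwm_wd,
      cwm_maxd = sum(w * maxd[i]) / sum(w),
      sd_wd = sqrt(sum(w * (wd[i] - cwm_wd)^2) / sum(w)),
      fdis = fdis,
      has_large = any(traits$max_diameter[sidx] >= large_threshold),
      has_dense = any(traits$wood_density[sidx] >= dense_threshold),
      trait_ba_coverage = cover,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (stats::median(out$trait_ba_coverage) < min_trait_ba) {
    warning("trait coverage below ", min_trait_ba, " of basal area for most units")
  }
  out
}

#' Null-model probability of sampling a high-functioning species
#'
#' The expected probability that a community of S species, assembled at
#' random from the continental pool, contains at least one species whose
#' trait exceeds a threshold (e.g. maximum diameter >= 70 cm or wood
#' density >= 0.8 g cm^-3). Uniform sampling (each pool species equally
#' likely, without replacement) is computed exactly from the hypergeometric
#' complement P(S) = 1 - C(G - K, S) / C(G, S); frequency-weighted sampling
#' (species drawn with probability proportional to their occurrence
#' frequency) is Monte-Carlo.
#'
#' @param pool Species pool: data.frame with wood_density, max_diameter and
#'   (for frequency mode) rel_freq columns.
#' @param trait "max_diameter" or "wood_density".
#' @param threshold Trait threshold defining a high-functioning species.
#' @param mode "uniform" or "frequency".
#' @param richness_grid Integer richness values to evaluate.
#' @param n_rep Monte-Carlo replicates per grid point (frequency mode).
#' @param seed Integer seed (frequency mode).
#' @return data.frame of class `null_curve`: richness, p_expected, mode,
#'   trait, threshold.
#' @export
null_sampling_curve <- function(pool, trait = c("max_diameter", "wood_density"),
                                threshold = 70, mode = c("uniform", "frequency"),
                                richness_grid = NULL, n_rep = 10000, seed = 1) {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  qual <- pool[[trait]] >= threshold
  G <- length(qual)
  K <- sum(qual)
  if (K == 0 || K == G) {
    stop("pool must contain species on both sides of the threshold")
  }
  if (is.null(richness_grid)) richness_grid <- seq_len(G)
  if (any(richness_grid > G)) stop("richness exceeds pool size")
  if (mode == "uniform") {
    p <- 1 - exp(lchoose(G - K, richness_grid) - lchoose(G, richness_grid))
    p[richness_grid > G - K] <- 1
  } else {
    freq <- pool$rel_freq
    if (is.null(freq)) stop("frequency mode needs a rel_freq column")
    set.seed(seed)
    p <- vapply(richness_grid, function(S) {
      mean(vapply(seq_len(n_rep), function(r) {
        any(qual[sample.int(G, S, prob = freq)])
      }, logical(1)))
    }, numeric(1))
  }
  out <- data.frame(richness = richness_grid, p_expected = p,
                    mode = mode, trait = trait, threshold = threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("null_curve", "data.frame")
  out
}

#' Occurrence of high-functioning species vs richness
#'
#' Binomial generalised linear mixed model of the presence of a potentially
#' large (or dense-wooded) species in each 0.04 ha subplot on subplot
#' species richness, with a plot random intercept. If the outcome is
#' constant (e.g. every unit contains such a species, as happens at the
#' 1 ha scale) the model is saturated and a flag is returned instead.
#'
#' @param trait_sub Subplot trait summaries from [trait_summaries()].
#' @param diversity_sub Subplot diversity table (unit_id, richness).
#' @param outcome "has_large" or "has_dense".
#' @return List with slope, se, p, saturated flag and the fit.
#' @export
occurrence_glmm <- function(trait_sub, diversity_sub,
                            outcome = c("has_large", "has_dense")) {
  outcome <- match.arg(outcome)
  m <- merge(trait_sub, diversity_sub[, c("unit_id", "richness")], by = "unit_id")
  if (length(unique(m$plot_id)) < 20) stop("need at least 20 plots")
  y <- m[[outcome]]
  if (all(y) || !any(y)) {
    return(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                saturated = TRUE, fit = NULL))
  }
  d <- data.frame(y = y, richness = m$richness, plot = factor(m$plot_id))
  fit <- lme4::glmer(y ~ richness + (1 | plot), data = d, family = stats::binomial)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["richness", "Estimate"]),
       se = unname(sm["richness", "Std. Error"]),
       p = unname(sm["richness", "Pr(>|z|)"]),
       saturated = FALSE, fit = fit)
}

#' Carbon vs community-weighted traits and functional diversity
#'
#' Separate models of ln(carbon) on each of cwm_wd, cwm_maxd, sd_wd and
#' fdis (z-scored). At the subplot scale a linear mixed model with plot
#' random intercept is used; at the plot scale, OLS (optionally per
#' continent).
#'
#' @param carbon Carbon table at the chosen scale.
#' @param trait_summary Trait summaries at the same scale.
#' @param scale "plot" or "subplot".
#' @param continent Optional vector of continent labels per plot (plot
#'   scale): fits one model per continent.
#' @return data.frame with predictor, (continent,) estimate, se, p, n.
#' @export
cwm_fd_regressions <- function(carbon, trait_summary,
                               scale = c("plot", "subplot"),
                               continent = NULL) {
  scale <- match.arg(scale)
  m <- merge(carbon[, c("unit_id", "plot_id", "carbon")], trait_summary,
             by = c("unit_id", "plot_id"))
  m <- m[m$carbon > 0, ]
  preds <- c("cwm_wd", "cwm_maxd", "sd_wd", "fdis")
  rows <- list()
  run_one <- function(d, pred, label) {
    if (stats::sd(d[[pred]]) == 0) return(NULL)
    x <- (d[[pred]] - mean(d[[pred]])) / stats::sd(d[[pred]])
    if (scale == "subplot") {
      fit <- lme4::lmer(log(carbon) ~ x + (1 | plot),
                        data = data.frame(carbon = d$carbon, x = x,
                                          plot = factor(d$plot_id)),
                        REML = FALSE)
      sm <- summary(fit)$coefficients
      tval <- sm["x", "t value"]
      df <- nrow(d) - length(unique(d$plot_id)) - 2
      p <- 2 * stats::pt(-abs(tval), df)
    } else {
      fit <- stats::lm(log(d$carbon) ~ x)
      sm <- summary(fit)$coefficients
      p <- sm["x", "Pr(>|t|)"]
    }
    data.frame(predictor = pred, continent = label,
               estimate = unname(sm["x", "Estimate"]),
               se = unname(sm["x", "Std. Error"]),
               p = unname(p), n = nrow(d), stringsAsFactors = FALSE)
  }
  if (scale == "plot" && !is.null(continent)) {
    cont <- continent[match(m$plot_id, names(continent))]
    for (ct in unique(cont)) {
      for (pred in preds) {
        rows[[paste(ct, pred)]] <- run_one(m[cont == ct, ], pred, ct)
      }
    }
  } else {
    for (pred in preds) rows[[pred]] <- run_one(m, pred, "all")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
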