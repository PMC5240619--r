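#' Kendall's tau correlation
#'
#' Tie-corrected tau-b with a two-sided p-value (exact for small n without
#' ties, normal approximation otherwise), as used for the bivariate
#' diversity-carbon associations among plots.
#'
#' @param x,y Paired numeric vectors without missing values.
#' @return Named vector c(tau, p).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 5) stop("need at least 5 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: tau undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  c(tau = unname(ct$estimate), p = ct$p.value)
}

#' Minimum detectable correlation at a given sample size
#'
#' Power analysis for a bivariate correlation test: the smallest Pearson r
#' detectable with the given power at a two-sided alpha, from the Fisher-z
#' approximation r_min = tanh((z_{1-alpha/2} + z_power) / sqrt(n - 3)), and
#' its Kendall-tau equivalent tau = (2/pi) asin(r) under bivariate
#' normality. An optional Monte-Carlo check simulates the achieved power at
#' r_min.
#'
#' @param n Sample size (> 3).
#' @param alpha_level Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param simulate If TRUE, also estimate empirical power at r_min.
#' @param n_sim Simulation replicates (default 5000).
#' @param seed Seed for the simulation.
#' @return List with n, alpha_level, power, r_min, tau_min (and
#'   empirical_power if simulated).
#' @export
detectable_effect <- function(n, alpha_level = 0.05, power = 0.80,
                              simulate = FALSE, n_sim = 5000, seed = 1) {
  if (n <= 3) stop("n must exceed 3")
  z <- stats::qnorm(1 - alpha_level / 2) + stats::qnorm(power)
  r_min <- tanh(z / sqrt(n - 3))
  out <- list(n = n, alpha_level = alpha_level, power = power,
              r_min = r_min, tau_min = (2 / pi) * asin(r_min))
  if (simulate) {
    set.seed(seed)
    hits <- vapply(seq_len(n_sim), function(i) {
      x <- stats::rnorm(n)
      y <- r_min * x + sqrt(1 - r_min^2) * stats::rnorm(n)
      stats::cor.test(x, y)$p.value < alpha_level
    }, logical(1))
    out$empirical_power <- mean(hits)
  }
  class(out) <- "power_result"
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Detectable effect at n = %d (alpha = %.2f, power = %.2f):\n",
              x$n, x$alpha_level, x$power))
  cat(sprintf("  r = %.3f, tau = %.3f\n", x$r_min, x$tau_min))
  if (!is.null(x$empirical_power)) {
    cat(sprintf("  empirical power at r_min: %.3f\n", x$empirical_power))
  }
  invisible(x)
}

# Small-sample corrected AIC; k = number of estimated parameters incl. sigma
aicc <- function(fit) {
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) stop("n too small for AICc with ", k, " parameters")
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets regression with AICc model averaging
#'
#' Fits ordinary least squares models of (ln-transformed) carbon on every
#' subset of the predictors (intercept always included; 2^p models),
#' computes AICc and Akaike weights, forms the 95% confidence set (models
#' ordered by AICc until their cumulative weight first reaches 0.95), and
#' model-averages coefficients over that set. Averaging is "full-model":
#' a predictor absent from a model contributes a coefficient of zero, which
#' shrinks weakly supported effects toward zero. Unconditional standard
#' errors follow the usual model-averaging variance formula. Predictors are
#' z-scored first so averaged coefficients are comparable across data sets;
#' zero-variance predictors (e.g. cumulative water deficit in a region where
#' no plot experiences a deficit) are dropped with a message.
#'
#' @param data data.frame with the response and predictor columns, complete
#'   cases only.
#' @param response Response column name (default "carbon").
#' @param predictors Character vector of predictor column names.
#' @param log_response ln-transform the response (default TRUE).
#' @param standardize z-score the predictors (default TRUE).
#' @param conf_level Cumulative-weight cutoff for the confidence set.
#' @param averaging "full" (absent predictor counts as zero) or
#'   "conditional" (average only over models containing the predictor).
#' @return Object of class `model_set`: per-model table, averaged
#'   coefficients with SEs, summed weights per predictor.
#' @export
fit_all_subsets <- function(data, response = "carbon",
                            predictors = c("diversity", "cwd", "mat", "map_",
                                           "teb", "cn", "texture"),
                            log_response = TRUE, standardize = TRUE,
                            conf_level = 0.95,
                            averaging = c("full", "conditional")) {
  averaging <- match.arg(averaging)
  stopifnot(all(c(response, predictors) %in% names(data)))
  data <- data[stats::complete.cases(data[, c(response, predictors)]), ]
  # a zero-variance predictor (e.g. cumulative water deficit where no plot
  # experiences a deficit) carries no information: drop it
  zv <- predictors[vapply(predictors, function(v) stats::sd(data[[v]]) == 0,
                          logical(1))]
  if (length(zv)) {
    message("dropping constant predictor(s): ", paste(zv, collapse = ", "))
    predictors <- setdiff(predictors, zv)
  }
  if (length(predictors) == 0) stop("no non-constant predictors")
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 3) stop("too few observations for AICc over the full model")
  y <- data[[response]]
  if (log_response) {
    if (any(y <= 0)) stop("response must be positive for log transform")
    y <- log(y)
  }
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (standardize) X <- scale(X)

  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  names(subsets) <- predictors
  nm <- nrow(subsets)
  fits <- vector("list", nm)
  tab <- data.frame(model = character(nm), k = integer(nm), aicc = numeric(nm),
                    stringsAsFactors = FALSE)
  dd <- data.frame(.y = y, X)
  colnames(dd) <- c(".y", predictors)
  for (m in seq_len(nm)) {
    inc <- predictors[unlist(subsets[m, ])]
    fo <- stats::reformulate(if (length(inc)) inc else "1", response = ".y")
    fit <- stats::lm(fo, data = dd)
    fits[[m]] <- fit
    tab$model[m] <- if (length(inc)) paste(inc, collapse = "+") else "(intercept)"
    tab$k[m] <- length(inc)
    tab$aicc[m] <- aicc(fit)
  }
  delta <- tab$aicc - min(tab$aicc)
  tab$weight <- exp(-delta / 2) / sum(exp(-delta / 2))

  # order by AICc; ties broken by fewer parameters, then model label
  ord <- order(tab$aicc, tab$k, tab$model)
  tab <- tab[ord, ]
  fits <- fits[ord]
  subsets <- subsets[ord, , drop = FALSE]
  cw <- cumsum(tab$weight)
  in_set <- seq_len(which(cw >= conf_level)[1])
  tab$in_confidence_set <- seq_len(nm) %in% in_set

  wset <- tab$weight[in_set] / sum(tab$weight[in_set])
  coef_mat <- matrix(0, length(in_set), p, dimnames = list(NULL, predictors))
  se_mat <- matrix(0, length(in_set), p, dimnames = list(NULL, predictors))
  present <- as.matrix(subsets[in_set, , drop = FALSE])
  for (i in seq_along(in_set)) {
    sm <- summary(fits[[in_set[i]]])$coefficients
    for (v in predictors[present[i, ]]) {
      coef_mat[i, v] <- sm[v, "Estimate"]
      se_mat[i, v] <- sm[v, "Std. Error"]
    }
  }
  if (averaging == "full") {
    avg <- colSums(wset * coef_mat)
    avg_se <- vapply(seq_len(p), function(j) {
      sum(wset * sqrt(se_mat[, j]^2 + (coef_mat[, j] - avg[j])^2))
    }, numeric(1))
  } else {
    avg <- avg_se <- stats::setNames(numeric(p), predictors)
    for (j in seq_len(p)) {
      pj <- present[, j]
      if (!any(pj)) { avg[j] <- NA_real_; avg_se[j] <- NA_real_; next }
      wj <- wset[pj] / sum(wset[pj])
      avg[j] <- sum(wj * coef_mat[pj, j])
      avg_se[j] <- sum(wj * sqrt(se_mat[pj, j]^2 + (coef_mat[pj, j] - avg[j])^2))
    }
  }
  names(avg_se) <- predictors
  sum_w <- vapply(predictors, function(v) {
    sum(tab$weight[vapply(strsplit(tab$model, "\\+"), function(s) v %in% s, logical(1))])
  }, numeric(1))

  structure(list(
    models = tab, averaged_coef = avg, averaged_se = avg_se,
    sum_weights = sum_w, n = n, predictors = predictors,
    dropped = zv, averaging = averaging, conf_level = conf_level
  ), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("AICc all-subsets model set: %d models, n = %d\n",
              nrow(x$models), x$n))
  cat(sprintf("  confidence set (%.0f%%): %d models\n", 100 * x$conf_level,
              sum(x$models$in_confidence_set)))
  out <- data.frame(coef = round(x$averaged_coef, 4),
                    se = round(x$averaged_se, 4),
                    sum_weight = round(x$sum_weights, 3))
  print(out)
  invisible(x)
}

#' Bootstrap continent summaries with Tukey groupings
#'
#' Group means with percentile bootstrap confidence intervals (resampling
#' observations with replacement within groups) and Tukey all-pair
#' comparison letters from a one-way ANOVA at alpha = 0.05. A transform
#' (e.g. log for carbon stocks, sqrt for Fisher's alpha) can be applied for
#' the ANOVA only; means and CIs are reported on the original scale.
#'
#' @param values Numeric vector.
#' @param group Factor of group (continent) labels.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param transform Function applied before the ANOVA (default identity).
#' @return data.frame with group, n, mean, ci_lo, ci_hi, letter.
#' @export
continent_summaries <- function(values, group, n_boot = 10000, seed = 1,
                                transform = identity) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  tabn <- table(group)
  if (any(tabn < 5)) stop("each group needs n >= 5")
  set.seed(seed)
  res <- lapply(levels(group), function(g) {
    v <- values[group == g]
    bm <- vapply(seq_len(n_boot),
                 function(b) mean(sample(v, replace = TRUE)), numeric(1))
    data.frame(group = g, n = length(v), mean = mean(v),
               ci_lo = unname(stats::quantile(bm, 0.025)),
               ci_hi = unname(stats::quantile(bm, 0.975)))
  })
  out <- do.call(rbind, res)
  tv <- transform(values)
  fit <- stats::aov(tv ~ group, data = data.frame(tv = tv, group = group))
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  letters <- multcomp::cld(glt, level = 0.05)$mcletters$Letters
  out$letter <- toupper(letters[out$group])
  rownames(out) <- NULL
  out
}

#' Correlations of carbon and richness with structural attributes
#'
#' Kendall's tau of carbon and of species richness against basal area,
#' basal-area-weighted mean wood density, stem density and stem-size
#' inequality (8 comparisons).
#'
#' @param carbon Carbon-estimate table from [aggregate_carbon()].
#' @param diversity Diversity table from [diversity_profile()].
#' @return data.frame with response, attribute, tau, p.
#' @export
structural_correlates <- function(carbon, diversity) {
  m <- merge(carbon, diversity, by = "unit_id")
  if (nrow(m) == 0) stop("no shared unit_id keys")
  attrs <- c("basal_area", "ba_weighted_wd", "stem_density", "size_inequality")
  rows <- list()
  for (resp in c("carbon", "richness")) {
    for (a in attrs) {
      kt <- kendall_tau(m[[resp]], m[[a]])
      rows[[paste(resp, a)]] <- data.frame(
        response = resp, attribute = a,
        tau = unname(kt["tau"]), p = unname(kt["p"]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
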