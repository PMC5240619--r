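#' Within-plot diversity-carbon slope for one plot
#'
#' Among the 0.04 ha subplots of a single plot, fits
#' ln(carbon) ~ ln(richness) + poly(ln(stems), 2); the second-order stem
#' term allows a saturating effect of stem packing. The coefficient on
#' ln(richness) is the plot's diversity-carbon slope, in units of
#' ln(Mg C ha^-1) per ln(species). Zero-carbon subplots are dropped (the
#' log is undefined) and counted.
#'
#' @param subplots data.frame for one plot with columns carbon, richness,
#'   n_stems.
#' @param min_subplots Minimum usable subplots (default 5).
#' @return Object of class `plot_slope`: beta, se, n_subplots, n_dropped,
#'   sign.
#' @export
fit_plot_slope <- function(subplots, min_subplots = 5) {
  drop <- subplots$carbon <= 0 | subplots$richness < 1 | subplots$n_stems < 1
  n_dropped <- sum(drop)
  if (n_dropped) {
    warning(n_dropped, " subplot(s) with zero carbon or richness dropped")
  }
  d <- subplots[!drop, ]
  if (nrow(d) < min_subplots) stop("fewer than ", min_subplots, " usable subplots")
  if (stats::sd(log(d$richness)) == 0) stop("no variance in ln(richness)")
  ls <- log(d$n_stems)
  dd <- data.frame(lc = log(d$carbon), lr = log(d$richness), ls = ls)
  fo <- if (stats::sd(ls) == 0) lc ~ lr else lc ~ lr + stats::poly(ls, 2)
  fit <- stats::lm(fo, data = dd)
  sm <- summary(fit)$coefficients
  beta <- sm["lr", "Estimate"]
  structure(list(
    beta = unname(beta), se = unname(sm["lr", "Std. Error"]),
    n_subplots = nrow(d), n_dropped = n_dropped,
    sign = if (beta > 0) "+" else if (beta < 0) "-" else "0"
  ), class = "plot_slope")
}

#' Per-plot slopes for all plots
#'
#' Applies [fit_plot_slope()] to every plot in a subplot-scale table built
#' from [aggregate_carbon()] and [diversity_profile()].
#'
#' @param carbon_sub Subplot carbon table (columns unit_id, plot_id, carbon).
#' @param diversity_sub Subplot diversity table (unit_id, richness, n_stems).
#' @param min_subplots Minimum usable subplots per plot (default 5).
#' @return data.frame with plot_id, beta, se, n_subplots, n_dropped, sign.
#' @export
plot_slopes <- function(carbon_sub, diversity_sub, min_subplots = 5) {
  m <- merge(carbon_sub[, c("unit_id", "plot_id", "carbon")],
             diversity_sub[, c("unit_id", "richness", "n_stems")],
             by = "unit_id")
  rows <- lapply(split(m, m$plot_id), function(d) {
    sl <- tryCatch(suppressWarnings(fit_plot_slope(d, min_subplots)),
                   error = function(e) NULL)
    if (is.null(sl)) return(NULL)
    data.frame(plot_id = d$plot_id[1], beta = sl$beta, se = sl$se,
               n_subplots = sl$n_subplots, n_dropped = sl$n_dropped,
               sign = sl$sign, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-plot summary of within-plot slopes
#'
#' Mean slope with standard error, a percentile bootstrap CI over plots,
#' a two-sided one-sample Wilcoxon signed-rank test against zero, sign
#' counts, and the implied percentage change in carbon per doubling of
#' richness, (2^mean_beta - 1) * 100.
#'
#' @param slopes Slope table from [plot_slopes()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return Object of class `slope_summary`.
#' @export
summarize_slopes <- function(slopes, n_boot = 10000, seed = 1) {
  b <- slopes$beta
  if (length(b) < 10) stop("need at least 10 plot slopes")
  set.seed(seed)
  bm <- vapply(seq_len(n_boot), function(i) mean(sample(b, replace = TRUE)),
               numeric(1))
  wp <- if (stats::sd(b) == 0) {
    warning("all slopes identical: Wilcoxon test undefined")
    NA_real_
  } else {
    suppressWarnings(stats::wilcox.test(b, mu = 0)$p.value)
  }
  mb <- mean(b)
  structure(list(
    mean_beta = mb, se_mean = stats::sd(b) / sqrt(length(b)),
    boot_ci = unname(stats::quantile(bm, c(0.025, 0.975))),
    wilcoxon_p = wp,
    n_pos = sum(b > 0), n_neg = sum(b < 0), n_zero = sum(b == 0),
    n_plots = length(b), n_boot = n_boot,
    doubling_pct = (2^mb - 1) * 100
  ), class = "slope_summary")
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf("Within-plot diversity-carbon slopes, %d plots\n", x$n_plots))
  cat(sprintf("  mean beta = %.4f +/- %.4f SE, 95%% CI [%.4f, %.4f]\n",
              x$mean_beta, x$se_mean, x$boot_ci[1], x$boot_ci[2]))
  cat(sprintf("  Wilcoxon P = %.4g; %d positive (%.1f%%), %d negative\n",
              x$wilcoxon_p, x$n_pos, 100 * x$n_pos / x$n_plots, x$n_neg))
  cat(sprintf("  doubling richness changes carbon by %.1f%%\n", x$doubling_pct))
  invisible(x)
}

#' Random-coefficients mixed model across all plots
#'
#' ln(carbon) ~ ln(richness) + poly(ln(stems), 2) with a random intercept
#' and a random ln(richness) slope by plot, fitted by maximum likelihood
#' (lme4). Falls back to a random-intercept model when the random-slope fit
#' does not converge.
#'
#' @param carbon_sub,diversity_sub Subplot-scale tables (see
#'   [plot_slopes()]).
#' @return List with fixed_slope, se, variance components, fallback flag and
#'   the lme4 fit.
#' @export
fit_random_coefficients <- function(carbon_sub, diversity_sub) {
  m <- merge(carbon_sub[, c("unit_id", "plot_id", "carbon")],
             diversity_sub[, c("unit_id", "richness", "n_stems")],
             by = "unit_id")
  m <- m[m$carbon > 0 & m$richness >= 1, ]
  if (length(unique(m$plot_id)) < 20) stop("need at least 20 plots")
  d <- data.frame(lc = log(m$carbon), lr = log(m$richness),
                  ls = log(m$n_stems), plot = factor(m$plot_id))
  fallback <- FALSE
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(lc ~ lr + poly(ls, 2) + (1 + lr | plot), data = d,
                 REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit@optinfo$conv$lme4$code)) fit <- NULL
  if (is.null(fit)) {
    fallback <- TRUE
    fit <- lme4::lmer(lc ~ lr + poly(ls, 2) + (1 | plot), data = d, REML = FALSE)
  }
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    fixed_slope = unname(sm["lr", "Estimate"]),
    se = unname(sm["lr", "Std. Error"]),
    varcomp = vc, fallback = fallback, fit = fit
  )
}
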