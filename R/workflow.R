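#' Validate inventory input tables
#'
#' Checks the stem, plot and trait tables against the study-domain
#' constraints: stems below 10 cm diameter are rejected (row-level issues),
#' plot areas outside {0.96, 1.0} ha, MAT < 20 C, MAP < 1300 mm, altitude
#' above 1217 m, and identification completeness below 80% to genus or 60%
#' to species raise warnings in the issue log but do not reject.
#'
#' @param stems,plots,traits Input tables (synthetic-generator dialect).
#' @return List with the validated tables (offending stem rows removed) and
#'   an `issues` data.frame (table, key, severity, message).
#' @export
validate_inputs <- function(stems, plots, traits) {
  req_stems <- c("plot_id", "subplot_id", "taxon", "family", "genus",
                 "id_level", "diameter_cm")
  req_plots <- c("plot_id", "lat", "lon", "area_ha", "continent")
  req_traits <- c("taxon", "wood_density", "max_diameter")
  for (nm in req_stems) if (!nm %in% names(stems)) stop("stems missing column ", nm)
  for (nm in req_plots) if (!nm %in% names(plots)) stop("plots missing column ", nm)
  for (nm in req_traits) if (!nm %in% names(traits)) stop("traits missing column ", nm)
  if (anyDuplicated(plots$plot_id)) stop("duplicate plot_id in plots")
  if (!is.null(stems$stem_id) &&
      anyDuplicated(stems[, c("plot_id", "subplot_id", "stem_id")])) {
    stop("duplicate (plot, subplot, stem) keys")
  }
  issues <- list()
  add <- function(tab, key, sev, msg) {
    issues[[length(issues) + 1]] <<- data.frame(
      table = tab, key = as.character(key), severity = sev, message = msg,
      stringsAsFactors = FALSE)
  }
  small <- which(stems$diameter_cm < 10)
  for (i in small) add("stems", i, "reject", "diameter below 10 cm minimum")
  if (length(small)) stems <- stems[-small, ]

  bad_area <- which(!plots$area_ha %in% c(0.96, 1.0))
  for (i in bad_area) add("plots", plots$plot_id[i], "warning",
                          "plot area outside {0.96, 1.0} ha")
  if (!is.null(plots$mat)) {
    for (i in which(plots$mat < 20)) add("plots", plots$plot_id[i], "warning",
                                         "MAT below 20 C study domain")
  }
  if (!is.null(plots$map_)) {
    for (i in which(plots$map_ < 1300)) add("plots", plots$plot_id[i], "warning",
                                            "MAP below 1300 mm study domain")
  }
  if (!is.null(plots$altitude_m)) {
    for (i in which(plots$altitude_m > 1217)) {
      add("plots", plots$plot_id[i], "warning", "altitude above 1217 m domain limit")
    }
  }
  pct_gen <- tapply(!is.na(stems$genus), stems$plot_id, mean)
  pct_sp <- tapply(stems$id_level == "species", stems$plot_id, mean)
  for (p in names(pct_gen)[pct_gen < 0.8]) {
    add("stems", p, "warning", "under 80% of stems identified to genus")
  }
  for (p in names(pct_sp)[pct_sp < 0.6]) {
    add("stems", p, "warning", "under 60% of stems identified to species")
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(table = character(), key = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  list(stems = stems, plots = plots, traits = traits, issues = issues)
}

#' Locality clusters of plots
#'
#' Groups plots into localities by single-linkage clustering of
#' great-circle distances cut at `radius_km` (default 5 km): two plots
#' belong to the same locality whenever a chain of plots with consecutive
#' distances below the radius connects them. Labels are stable under plot
#' reordering (localities numbered by their southernmost-then-westernmost
#' member).
#'
#' @param plots Plot table with lat, lon.
#' @param radius_km Linkage distance cap (default 5).
#' @param method "single" (default) or "complete" linkage.
#' @return Integer vector of locality labels, one per plot.
#' @export
locality_clusters <- function(plots, radius_km = 5, method = c("single", "complete")) {
  method <- match.arg(method)
  n <- nrow(plots)
  if (n == 1) return(1L)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(plots$lat[i], plots$lon[i], plots$lat[j], plots$lon[j]))
  hc <- stats::hclust(stats::as.dist(D), method = method)
  raw <- stats::cutree(hc, h = radius_km)
  # renumber clusters by the position of their first member after sorting
  ord <- order(plots$lat, plots$lon)
  first <- tapply(match(seq_len(n), ord), raw, min)
  as.integer(rank(first)[as.character(raw)])
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulation (or input loading), validation, the carbon
#' pipeline, alpha and beta diversity, stand-scale inference, within-plot
#' analysis and mechanism diagnostics, writing all artifacts and a run
#' report to the output directory. Reruns with the same configuration
#' reproduce every stochastic output exactly.
#'
#' @param config A [sim_config()] for the simulation stage.
#' @param out_dir Output directory (created if missing); NULL skips writing.
#' @param stages Character vector of stages to run, any of "carbon",
#'   "diversity", "beta", "stand", "within", "mechanisms".
#' @param n_boot Bootstrap resamples for the decay fit and slope summary
#'   (default 1000; the field default of 10000 can be requested).
#' @return List of class `run_report` with per-stage results and warnings.
#' @export
run_all <- function(config, out_dir = NULL,
                    stages = c("carbon", "diversity", "beta", "stand",
                               "within", "mechanisms"),
                    n_boot = 1000) {
  t0 <- Sys.time()
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  dat <- simulate_inventory(config)
  val <- validate_inputs(dat$stems, dat$plots, dat$traits)
  stems <- resolve_wood_density(val$stems, val$traits)
  plots <- val$plots
  report <- list(config = config, issues = val$issues,
                 n_stems = nrow(stems), n_plots = nrow(plots),
                 stages = stages)

  if ("carbon" %in% stages) {
    report$carbon_plot <- aggregate_carbon(stems, plots, "plot")
    report$carbon_sub <- suppressWarnings(
      aggregate_carbon(stems, plots, "subplot"))
  }
  if ("diversity" %in% stages) {
    report$diversity_plot <- diversity_profile(stems, "plot")
    report$diversity_sub <- diversity_profile(stems, "subplot", correct = FALSE)
  }
  if ("beta" %in% stages) {
    pairs <- pairwise_similarity(stems, plots, min_identified = 90)
    fits <- lapply(split(pairs, pairs$continent), function(pp) {
      tryCatch(fit_distance_decay(pp, n_boot = n_boot,
                                  seed = substream_seed(config$seed, 31)),
               error = function(e) { note("decay fit failed: %s", conditionMessage(e)); NULL })
    })
    report$pairs <- pairs
    report$decay_fits <- fits
  }
  if ("stand" %in% stages && all(c("carbon", "diversity") %in% stages)) {
    cp <- report$carbon_plot
    dp <- report$diversity_plot
    m <- merge(merge(cp, dp, by = c("unit_id", "plot_id")), plots,
               by = "plot_id")
    report$stand <- lapply(split(m, m$continent), function(d) {
      out <- list(
        tau = tryCatch(kendall_tau(d$carbon, d$richness), error = function(e) NULL),
        power = detectable_effect(nrow(d)))
      out$modelset <- tryCatch({
        dd <- data.frame(carbon = d$carbon, diversity = d$fishers_alpha,
                         cwd = d$cwd, mat = d$mat, map_ = d$map_,
                         teb = d$teb, cn = d$cn, texture = d$texture)
        suppressMessages(fit_all_subsets(dd))
      }, error = function(e) { note("subset fit failed: %s", conditionMessage(e)); NULL })
      out$sar <- tryCatch({
        W <- knn_weights(d$lat, d$lon, k = min(8, nrow(d) - 1))
        X0 <- cbind(diversity = d$fishers_alpha, cwd = d$cwd, mat = d$mat,
                    map_ = d$map_, teb = d$teb, cn = d$cn, texture = d$texture)
        X <- scale(X0[, apply(X0, 2, stats::sd) > 0, drop = FALSE])
        fit_sar_error(log(d$carbon), X, W)
      }, error = function(e) { note("SAR fit failed: %s", conditionMessage(e)); NULL })
      out
    })
    report$continent_summaries <- list(
      carbon = continent_summaries(m$carbon, m$continent, n_boot = n_boot,
                                   seed = substream_seed(config$seed, 41),
                                   transform = log),
      fishers_alpha = continent_summaries(m$fishers_alpha, m$continent,
                                          n_boot = n_boot,
                                          seed = substream_seed(config$seed, 42),
                                          transform = sqrt))
    report$structural <- structural_correlates(cp, dp)
  }
  if ("within" %in% stages && all(c("carbon", "diversity") %in% stages)) {
    sl <- plot_slopes(report$carbon_sub, report$diversity_sub)
    report$slopes <- sl
    report$slope_summary <- summarize_slopes(sl, n_boot = n_boot,
                                             seed = substream_seed(config$seed, 51))
  }
  if ("mechanisms" %in% stages && "carbon" %in% stages) {
    ts_sub <- trait_summaries(stems, val$traits, "subplot")
    report$trait_sub <- ts_sub
    report$null_curves <- lapply(names(config$n_plots_per_continent), function(ct) {
      pool <- make_pool(config, ct)
      null_sampling_curve(pool, "max_diameter", 70, "uniform",
                          richness_grid = c(5, 11, 18, 30, 50, 72))
    })
    if ("diversity" %in% stages) {
      report$occurrence <- tryCatch(
        occurrence_glmm(ts_sub, report$diversity_sub),
        error = function(e) { note("occurrence GLMM failed: %s", conditionMessage(e)); NULL })
      report$cwm_models <- tryCatch(
        cwm_fd_regressions(report$carbon_sub, ts_sub, "subplot"),
        error = function(e) { note("CWM models failed: %s", conditionMessage(e)); NULL })
    }
  }
  report$warnings <- warnings_log
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(dat$stems, file.path(out_dir, "stems.csv"), row.names = FALSE)
    utils::write.csv(dat$plots, file.path(out_dir, "plots.csv"), row.names = FALSE)
    utils::write.csv(dat$traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
    if (!is.null(report$carbon_plot)) {
      utils::write.csv(report$carbon_plot, file.path(out_dir, "carbon_plot.csv"),
                       row.names = FALSE)
      utils::write.csv(report$carbon_sub, file.path(out_dir, "carbon_subplot.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$diversity_plot)) {
      utils::write.csv(report$diversity_plot,
                       file.path(out_dir, "diversity_plot.csv"), row.names = FALSE)
    }
    if (!is.null(report$slopes)) {
      utils::write.csv(report$slopes, file.path(out_dir, "slopes.csv"),
                       row.names = FALSE)
      jsonlite::write_json(report$slope_summary[c("mean_beta", "se_mean",
                                                  "boot_ci", "wilcoxon_p",
                                                  "n_pos", "n_neg",
                                                  "doubling_pct")],
                           file.path(out_dir, "slope_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    truth <- config
    class(truth) <- NULL
    truth$baseline_lncarbon <- truth$baseline_lncarbon %||% NA
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %d stems, %d plots; stages: %s (%.1f s)\n",
              x$n_stems, x$n_plots, paste(x$stages, collapse = ", "),
              x$elapsed_s))
  if (nrow(x$issues)) {
    cat(sprintf("  validation issues: %d (%d rejections)\n", nrow(x$issues),
                sum(x$issues$severity == "reject")))
  }
  if (!is.null(x$slope_summary)) print(x$slope_summary)
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
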