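#' Regional height-diameter models
#'
#' Tree height is predicted from diameter with a three-parameter Weibull
#' curve H = a (1 - exp(-b D^c)), fitted separately for each continental
#' region in the literature. The coefficients shipped here are approximate
#' regional fits for lowland moist forest and can be overridden.
#'
#' @param continent Character vector of continent labels.
#' @param coefficients Optional named list of `c(a, b, c)` vectors keyed by
#'   continent, overriding the defaults.
#' @return A data.frame with columns continent, a, b, c.
#' @export
height_models <- function(continent = c("SouthAmerica", "Africa", "Asia"),
                          coefficients = NULL) {
  defaults <- list(
    SouthAmerica = c(a = 42.574, b = 0.0482, c = 0.8307),
    Africa       = c(a = 50.453, b = 0.0471, c = 0.8120),
    Asia         = c(a = 57.122, b = 0.0332, c = 0.8468)
  )
  if (!is.null(coefficients)) defaults[names(coefficients)] <- coefficients
  missing <- setdiff(continent, names(defaults))
  if (length(missing)) {
    stop("no height model for continent(s): ", paste(missing, collapse = ", "))
  }
  out <- do.call(rbind, lapply(continent, function(ct) {
    cf <- defaults[[ct]]
    data.frame(continent = ct, a = cf[["a"]], b = cf[["b"]], c = cf[["c"]])
  }))
  rownames(out) <- NULL
  out
}

#' Estimate tree height from diameter
#'
#' Weibull height-diameter model H = a (1 - exp(-b D^c)). Height saturates
#' at the asymptote `a` for very large stems.
#'
#' @param diameter Stem diameter in cm (>= 10).
#' @param a,b,c Positive Weibull coefficients.
#' @return Height in m.
#' @export
estimate_height <- function(diameter, a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("Weibull coefficients must be positive")
  a * (1 - exp(-b * diameter^c))
}

#' Aboveground biomass of a single stem
#'
#' Moist-forest allometry AGB = 0.0673 (rho D^2 H)^0.976 with wood density
#' rho in g cm^-3, diameter D in cm and height H in m; returns kg.
#'
#' @param rho Wood density (g cm^-3).
#' @param diameter Diameter (cm).
#' @param height Height (m).
#' @return Aboveground biomass in kg (dry mass).
#' @export
stem_agb <- function(rho, diameter, height) {
  if (any(is.na(rho)) || any(is.na(height))) {
    stop("wood density and height must be resolved before computing AGB")
  }
  0.0673 * (rho * diameter^2 * height)^0.976
}

#' Resolve stem wood density from a trait table
#'
#' Each stem receives a wood density by the best available taxonomic match:
#' species-level trait value, else the mean over congeneric species, else the
#' mean over confamilial species, else the mean of all resolved stems in the
#' same plot. The provenance of each value is recorded.
#'
#' @param stems Stem table with columns plot_id, taxon, genus, family,
#'   id_level.
#' @param traits Trait table with columns taxon, wood_density (and typically
#'   max_diameter); genus/family means are derived by joining traits to the
#'   stem table's taxonomy.
#' @return `stems` with columns wood_density and wd_source
#'   (species/genus/family/plot) added.
#' @export
resolve_wood_density <- function(stems, traits) {
  stopifnot(all(c("plot_id", "taxon", "genus", "family") %in% names(stems)),
            all(c("taxon", "wood_density") %in% names(traits)))
  wd_sp <- traits$wood_density[match(stems$taxon, traits$taxon)]

  # genus / family means over trait species; taxonomy from the trait table
  # itself when present, else joined from the stem table
  if (all(c("genus", "family") %in% names(traits))) {
    tr <- traits
  } else {
    taxo <- unique(stems[!is.na(stems$taxon), c("taxon", "genus", "family")])
    tr <- merge(traits[, setdiff(names(traits), c("genus", "family"))],
                taxo, by = "taxon")
  }
  gen_mean <- tapply(tr$wood_density, tr$genus, mean)
  fam_mean <- tapply(tr$wood_density, tr$family, mean)

  wd <- wd_sp
  src <- ifelse(!is.na(wd), "species", NA_character_)
  use_gen <- is.na(wd) & !is.na(stems$genus) &
    stems$genus %in% names(gen_mean)
  wd[use_gen] <- gen_mean[stems$genus[use_gen]]
  src[use_gen] <- "genus"
  use_fam <- is.na(wd) & !is.na(stems$family) &
    stems$family %in% names(fam_mean)
  wd[use_fam] <- fam_mean[stems$family[use_fam]]
  src[use_fam] <- "family"

  # terminal fallback: plot mean of resolved stems
  if (any(is.na(wd))) {
    plot_mean <- tapply(wd, stems$plot_id, mean, na.rm = TRUE)
    bad <- names(plot_mean)[!is.finite(plot_mean)]
    if (length(bad)) {
      stop("plots with zero resolvable stems: ", paste(bad, collapse = ", "))
    }
    idx <- is.na(wd)
    wd[idx] <- plot_mean[as.character(stems$plot_id[idx])]
    src[idx] <- "plot"
  }
  stems$wood_density <- as.numeric(wd)
  stems$wd_source <- src
  stems
}

#' Per-unit-area carbon and structural attributes
#'
#' Aggregates resolved stems to plot or subplot scale: aboveground biomass
#' (allometric, Mg ha^-1), carbon (47.1% of AGB, the mean carbon fraction of
#' tropical angiosperm wood), basal area, basal-area-weighted mean wood
#' density, stem density and the Gini coefficient of stem basal areas
#' (size inequality).
#'
#' @param stems Stem table with wood_density resolved and columns plot_id,
#'   subplot_id, diameter_cm, continent (or supply `height_coefs`).
#' @param plots Plot table with plot_id, area_ha, continent.
#' @param scale "plot" or "subplot".
#' @param height_coefs Optional height-model override passed to
#'   [height_models()].
#' @return data.frame of class `carbon_estimate` keyed by unit_id.
#' @export
aggregate_carbon <- function(stems, plots, scale = c("plot", "subplot"),
                             height_coefs = NULL) {
  scale <- match.arg(scale)
  stopifnot(all(c("plot_id", "diameter_cm", "wood_density") %in% names(stems)))
  if (any(stems$diameter_cm < 10)) stop("all stems must have diameter >= 10 cm")

  continent <- plots$continent[match(stems$plot_id, plots$plot_id)]
  hm <- height_models(unique(continent), coefficients = height_coefs)
  i <- match(continent, hm$continent)
  h <- estimate_height(stems$diameter_cm, hm$a[i], hm$b[i], hm$c[i])
  agb_kg <- stem_agb(stems$wood_density, stems$diameter_cm, h)
  ba <- stem_basal_area(stems$diameter_cm)

  if (scale == "plot") {
    unit <- as.character(stems$plot_id)
    area <- plots$area_ha[match(unique(unit), plots$plot_id)]
    nsub <- 1
  } else {
    if (!"subplot_id" %in% names(stems)) stop("subplot_id required at subplot scale")
    unit <- paste(stems$plot_id, stems$subplot_id, sep = ":")
    pid <- sub(":.*$", "", unique(unit))
    parea <- plots$area_ha[match(pid, plots$plot_id)]
    nsub <- plots$subplots[match(pid, plots$plot_id)] %||% NULL
    if (is.null(nsub) || all(is.na(nsub))) nsub <- rep(25, length(pid))
    area <- parea / nsub
  }
  units <- unique(unit)
  f <- factor(unit, levels = units)
  sum_agb <- tapply(agb_kg, f, sum)
  sum_ba <- tapply(ba, f, sum)
  out <- data.frame(
    unit_id = units,
    plot_id = if (scale == "plot") units else sub(":.*$", "", units),
    area = as.numeric(area),
    agb = as.numeric(sum_agb) / 1000 / area,       # Mg ha^-1
    basal_area = as.numeric(sum_ba) / area,        # m^2 ha^-1
    ba_weighted_wd = as.numeric(tapply(ba * stems$wood_density, f, sum) / sum_ba),
    stem_density = as.numeric(tapply(ba, f, length)) / area,
    size_inequality = as.numeric(tapply(ba, f, gini)),
    stringsAsFactors = FALSE
  )
  out$carbon <- 0.471 * out$agb
  out$flag_empty <- FALSE

  if (scale == "subplot") {
    # complete the subplot grid: stemless subplots carry zero carbon, flagged
    nsub_all <- plots$subplots %||% rep(25, nrow(plots))
    full <- data.frame(
      plot_id = rep(as.character(plots$plot_id), nsub_all),
      subplot_id = unlist(lapply(nsub_all, seq_len)),
      stringsAsFactors = FALSE
    )
    full$unit_id <- paste(full$plot_id, full$subplot_id, sep = ":")
    miss <- setdiff(full$unit_id, out$unit_id)
    if (length(miss)) {
      warning(length(miss), " subplot(s) contain no stems; carbon set to 0")
      pid <- sub(":.*$", "", miss)
      zero <- data.frame(
        unit_id = miss, plot_id = pid,
        area = plots$area_ha[match(pid, plots$plot_id)] /
          nsub_all[match(pid, plots$plot_id)],
        agb = 0, basal_area = 0, ba_weighted_wd = NA_real_,
        stem_density = 0, size_inequality = NA_real_, carbon = 0,
        flag_empty = TRUE, stringsAsFactors = FALSE
      )
      out <- rbind(out, zero)
      out <- out[match(intersect(full$unit_id, out$unit_id), out$unit_id), ]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("carbon_estimate", "data.frame")
  out
}
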