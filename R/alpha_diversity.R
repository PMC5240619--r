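#' Taxon richness corrected for unidentified stems
#'
#' Observed richness counts identified species plus morphospecies as distinct
#' taxa. Stems that carry no taxon at all are assumed to contain new taxa at
#' the same taxa-per-stem rate as the identified stems:
#' S = S_obs + round(U * S_obs / N_identified), with U the number of
#' unidentified stems. The correction can be switched off.
#'
#' @param taxa Character vector of stem-level taxon labels; NA marks a fully
#'   unidentified stem.
#' @param correct Apply the unidentified-stem correction (default TRUE).
#' @return Integer richness estimate.
#' @export
corrected_richness <- function(taxa, correct = TRUE) {
  u <- sum(is.na(taxa))
  ident <- taxa[!is.na(taxa)]
  if (length(ident) == 0L) {
    stop("all stems unidentified: richness-per-stem ratio undefined")
  }
  s_obs <- length(unique(ident))
  if (!correct || u == 0L) return(as.integer(s_obs))
  as.integer(s_obs + round(u * s_obs / length(ident)))
}

#' Individual-based rarefaction
#'
#' Expected number of taxa in a random subsample of `n` stems drawn without
#' replacement, computed with the exact hypergeometric formula
#' E\[S_n\] = sum_i (1 - C(N - N_i, n) / C(N, n)) in log-gamma arithmetic.
#' Returns NA when n exceeds the total count (no extrapolation).
#'
#' @param abundances Non-negative integer abundances per taxon.
#' @param n Subsample size.
#' @return Expected richness (numeric), or NA if n > sum(abundances).
#' @export
rarefied_richness <- function(abundances, n) {
  abundances <- abundances[abundances > 0]
  N <- sum(abundances)
  if (length(abundances) == 0L) stop("empty community")
  if (n < 1) stop("n must be >= 1")
  if (n > N) return(NA_real_)
  # log C(N - Ni, n) - log C(N, n), guarding Ni > N - n where the term is 0
  ldenom <- lchoose(N, n)
  p_absent <- ifelse(N - abundances >= n,
                     exp(lchoose(N - abundances, n) - ldenom), 0)
  sum(1 - p_absent)
}

#' Fisher's alpha from richness and abundance
#'
#' The log-series diversity index alpha solves S = alpha * log(1 + N/alpha).
#' Solved by bracketed root-finding (uniroot) to relative tolerance 1e-10.
#'
#' @param S Number of taxa (>= 1).
#' @param N Number of stems (>= S).
#' @return Positive alpha; +Inf when S == N (every stem its own taxon).
#' @export
fishers_alpha <- function(S, N) {
  if (S <= 0) stop("S must be positive")
  if (S > N) stop("S cannot exceed N")
  if (S == N) return(Inf)
  fn <- function(a) a * log1p(N / a) - S
  # S = a log(1 + N/a) is increasing in a from 0 (limit) to N (a -> Inf)
  lo <- 1e-12
  hi <- 1
  while (fn(hi) < 0) hi <- hi * 2
  stats::uniroot(fn, c(lo, hi), tol = 1e-12)$root
}

#' Shannon and Gini-Simpson diversity
#'
#' Shannon entropy -sum p log p and the Gini-Simpson index 1 - sum p^2.
#'
#' @param abundances Non-negative abundances per taxon.
#' @return Named numeric vector c(shannon, simpson).
#' @export
shannon_simpson <- function(abundances) {
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0L || sum(abundances) == 0) {
    stop("zero total abundance")
  }
  p <- abundances / sum(abundances)
  c(shannon = -sum(p * log(p)), simpson = 1 - sum(p^2))
}

#' Per-unit diversity profiles
#'
#' Computes, for each plot (or subplot), stem counts, corrected taxon
#' richness, expected richness per `rarefy_to` stems, Fisher's alpha,
#' genus and family richness, Shannon and Gini-Simpson diversity, and the
#' percentage of stems identified to species.
#'
#' Fisher's alpha and the abundance-based metrics are computed on the
#' identified (species + morphospecies) taxa; rarefied richness is NA for
#' units with fewer than `rarefy_to` identified stems.
#'
#' @param stems Stem table with plot_id, subplot_id, taxon, genus, family,
#'   id_level.
#' @param scale "plot" or "subplot".
#' @param rarefy_to Rarefaction depth in stems (default 300).
#' @param correct Apply the unidentified-taxon correction to richness.
#' @return data.frame keyed by unit_id.
#' @export
diversity_profile <- function(stems, scale = c("plot", "subplot"),
                              rarefy_to = 300, correct = TRUE) {
  scale <- match.arg(scale)
  unit <- if (scale == "plot") as.character(stems$plot_id) else
    paste(stems$plot_id, stems$subplot_id, sep = ":")
  units <- unique(unit)
  idx_list <- split(seq_len(nrow(stems)), factor(unit, levels = units))
  rows <- lapply(units, function(u) {
    i <- idx_list[[u]]
    taxa <- stems$taxon[i]
    ident <- taxa[!is.na(taxa)]
    ab <- as.integer(table(ident))
    S_obs <- length(ab)
    N_id <- sum(ab)
    ss <- shannon_simpson(ab)
    data.frame(
      unit_id = u,
      plot_id = as.character(stems$plot_id[i[1]]),
      n_stems = length(i),
      richness = corrected_richness(taxa, correct = correct),
      richness_rarefied = if (N_id >= rarefy_to) rarefied_richness(ab, rarefy_to) else NA_real_,
      fishers_alpha = if (S_obs >= 1 && N_id >= 1) fishers_alpha(S_obs, N_id) else NA_real_,
      genus_richness = length(unique(stems$genus[i][!is.na(stems$genus[i])])),
      family_richness = length(unique(stems$family[i][!is.na(stems$family[i])])),
      shannon = unname(ss["shannon"]),
      simpson = unname(ss["simpson"]),
      pct_identified = 100 * mean(stems$id_level[i] == "species"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
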