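#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Inputs are decimal degrees (WGS84); vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.195 km, one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitudes must lie in [-90, 90]")
  }
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("longitudes must lie in [-180, 180]")
  }
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Gini coefficient of a non-negative vector
#'
#' Used as the stem-size inequality metric (on stem basal areas). Returns 0
#' for a constant vector and approaches 1 when one element dominates.
#'
#' @param x Non-negative numeric vector.
#' @return Gini coefficient in \[0, 1\].
#' @export
gini <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x < 0)) stop("gini() requires non-negative values")
  n <- length(x)
  if (n == 1L || sum(x) == 0) return(0)
  x <- sort(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

# Deterministic substream seed derived from a master seed.  Keeps results
# reproducible while letting independent stages use independent streams.
# Always < 2^31 so it is a valid R integer seed.
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# basal area (m^2) of a stem from diameter in cm
stem_basal_area <- function(diameter_cm) pi * (diameter_cm / 200)^2
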