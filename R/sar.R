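#' Row-standardized k-nearest-neighbour spatial weights
#'
#' Builds the spatial weights matrix W used by the SAR error model: each
#' plot's k nearest neighbours (great-circle distance) receive equal weight
#' 1/k; all other entries are zero. Alternatively a distance band can be
#' used (all neighbours within `band_km`).
#'
#' @param lat,lon Plot coordinates in decimal degrees.
#' @param k Number of nearest neighbours (default 8).
#' @param band_km If non-NULL, use all neighbours within this distance
#'   instead of k-nearest.
#' @return n x n row-standardized weights matrix.
#' @export
knn_weights <- function(lat, lon, k = 8, band_km = NULL) {
  n <- length(lat)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(lat[i], lon[i], lat[j], lon[j]))
  diag(D) <- Inf
  W <- matrix(0, n, n)
  if (is.null(band_km)) {
    if (k >= n) stop("k must be smaller than the number of plots")
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[seq_len(k)]
      W[i, nb] <- 1 / k
    }
  } else {
    for (i in seq_len(n)) {
      nb <- which(D[i, ] <= band_km)
      if (length(nb) == 0) {
        warning("plot ", i, " has no neighbour within the band; graph disconnected")
        next
      }
      W[i, nb] <- 1 / length(nb)
    }
  }
  W
}

#' Simultaneous autoregressive error model
#'
#' Maximum-likelihood fit of y = X beta + u with spatially autocorrelated
#' errors u = lambda W u + e, e ~ N(0, sigma^2 I). The likelihood is
#' profiled: for fixed lambda the transformed regression
#' (I - lambda W) y = (I - lambda W) X beta + e is OLS, and the
#' log-determinant term ln|I - lambda W| is evaluated from the (possibly
#' complex) eigenvalues of W. With lambda fixed at 0 the fit reduces
#' exactly to OLS.
#'
#' @param y Response vector (typically ln carbon).
#' @param X Predictor matrix or data.frame (intercept added automatically).
#' @param W Row-standardized spatial weights matrix (see [knn_weights()]).
#' @param lambda Fix lambda at this value instead of estimating it
#'   (e.g. 0 for the OLS special case); NULL (default) estimates it by ML.
#' @return Object of class `sar_fit`: coefficients, se, lambda, sigma2,
#'   logLik, logLik_ols.
#' @export
fit_sar_error <- function(y, X, W, lambda = NULL) {
  X <- as.matrix(cbind(`(Intercept)` = 1, as.matrix(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(W) == n, ncol(W) == n)
  if (qr(X)$rank < ncol(X)) stop("singular predictor matrix")
  ev <- eigen(W, only.values = TRUE)$values

  profile_ll <- function(lam) {
    A <- diag(n) - lam * W
    ys <- A %*% y
    Xs <- A %*% X
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    s2 <- rss / n
    ldet <- sum(log(Mod(1 - lam * ev)))
    ldet - n / 2 * (log(2 * pi * s2) + 1)
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(profile_ll, interval = c(-0.999, 0.999), maximum = TRUE,
                           tol = 1e-8)
    lam <- opt$maximum
    ll <- opt$objective
  } else {
    lam <- lambda
    ll <- profile_ll(lam)
  }
  A <- diag(n) - lam * W
  ys <- drop(A %*% y)
  Xs <- A %*% X
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  s2 <- rss / n
  XtXinv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(diag(XtXinv) * rss / (n - ncol(X)))
  names(se) <- names(beta)
  structure(list(
    coefficients = beta, se = se, lambda = lam, sigma2 = s2,
    logLik = ll, logLik_ols = profile_ll(0), n = n
  ), class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR error model (ML): lambda = %.3f, logLik = %.2f (OLS %.2f)\n",
              x$lambda, x$logLik, x$logLik_ols))
  print(data.frame(estimate = round(x$coefficients, 4), se = round(x$se, 4)))
  invisible(x)
}
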