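#' Per-subject ROI time-series container
#'
#' Bundles the extracted ROI time series with the nuisance regressors used
#' for confound removal: 6 rigid-body motion parameters, and mean
#' white-matter and CSF signals.
#'
#' @param data Numeric timepoints x ROI matrix (column names = ROI labels).
#' @param motion Numeric timepoints x 6 matrix of motion parameters.
#' @param wm,csf Numeric vectors of length timepoints.
#' @param tr Repetition time in seconds.
#' @return An object of class `roi_timeseries`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(400), 100, 4), matrix(0, 100, 6),
#'                      rnorm(100), rnorm(100))
#' @export
roi_timeseries <- function(data, motion, wm, csf, tr = 1) {
  data <- as.matrix(data)
  motion <- as.matrix(motion)
  n_t <- nrow(data)
  if (anyNA(data) || anyNA(motion) || anyNA(wm) || anyNA(csf)) {
    stop("ROI time series and nuisance regressors must not contain missing values")
  }
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (nrow(motion) != n_t || length(wm) != n_t || length(csf) != n_t) {
    stop("all nuisance regressors must have the same number of timepoints as the data")
  }
  if (is.null(colnames(data))) colnames(data) <- sprintf("ROI%03d", seq_len(ncol(data)))
  if (n_t < 2L * ncol(data)) {
    warning("fewer than 2 timepoints per ROI; connectivity estimates will be unstable")
  }
  structure(list(data = data, motion = motion, wm = as.numeric(wm),
                 csf = as.numeric(csf), roi_labels = colnames(data), tr = tr),
            class = "roi_timeseries")
}

#' Estimate per-ROI lag-1 autoregression coefficients
#'
#' The AR(1) coefficient of each column is its lag-1 sample autocorrelation
#' (autocovariance at lag 1 over variance, both about the column mean).
#'
#' @param residual_series Numeric timepoints x ROI matrix, typically
#'   motion-regression residuals.
#' @return Named numeric vector of per-ROI coefficients, all in `(-1, 1)`.
#' @examples
#' x <- matrix(rnorm(2000), 500, 4)
#' estimate_ar1(x)
#' @export
estimate_ar1 <- function(residual_series) {
  x <- as.matrix(residual_series)
  n_t <- nrow(x)
  if (n_t < 3L) stop("need at least 3 timepoints to estimate an AR(1) coefficient")
  labels <- colnames(x)
  if (is.null(labels)) labels <- sprintf("ROI%03d", seq_len(ncol(x)))
  xc <- sweep(x, 2L, colMeans(x))
  denom <- colSums(xc^2)
  zero <- denom <= .Machine$double.eps * n_t
  if (any(zero)) {
    stop("zero-variance ROI column(s): ", paste(labels[zero], collapse = ", "))
  }
  rho <- colSums(xc[-1L, , drop = FALSE] * xc[-n_t, , drop = FALSE]) / denom
  names(rho) <- labels
  rho
}

# Whiten columns of a matrix with a single AR(1) coefficient:
# a*_t = a_t - rho * a_{t-1}, dropping the first timepoint.
whiten_ar1 <- function(a, rho) {
  a <- as.matrix(a)
  a[-1L, , drop = FALSE] - rho * a[-nrow(a), , drop = FALSE]
}

#' Two-step GLM pre-whitening and confound removal
#'
#' Step 1: each ROI column is OLS-residualized on an intercept and the 6
#' motion parameters; the residuals give the per-ROI AR(1) coefficient,
#' which is used to whiten the raw data (`x*_t = x_t - rho x_{t-1}`, first
#' timepoint dropped). Step 2: the whitened data are residualized on an
#' intercept, the motion parameters, and the white-matter and CSF signals,
#' each regressor whitened with the same per-ROI coefficient so the AR(1)
#' model stays coherent within each ROI's regression.
#'
#' @param ts A [roi_timeseries()] object.
#' @return Numeric (timepoints - 1) x ROI matrix of cleaned residuals.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(800), 200, 4), matrix(rnorm(1200), 200, 6),
#'                      rnorm(200), rnorm(200))
#' cleaned <- preprocess_subject(ts)
#' dim(cleaned)
#' @export
preprocess_subject <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_t <- nrow(ts$data)
  x1 <- cbind(1, ts$motion)
  qr1 <- qr(x1)
  if (qr1$rank < ncol(x1)) stop("motion regressor matrix is rank deficient")
  res1 <- qr.resid(qr1, ts$data)
  rho <- estimate_ar1(res1)
  if (any(abs(rho) >= 1)) {
    stop("nonstationary AR(1) estimate (|rho| >= 1) for ROI: ",
         paste(ts$roi_labels[abs(rho) >= 1], collapse = ", "))
  }
  x2 <- cbind(1, ts$motion, ts$wm, ts$csf)
  out <- matrix(NA_real_, n_t - 1L, ncol(ts$data),
                dimnames = list(NULL, ts$roi_labels))
  for (j in seq_len(ncol(ts$data))) {
    yw <- whiten_ar1(ts$data[, j, drop = FALSE], rho[j])
    zw <- whiten_ar1(x2, rho[j])
    qr2 <- qr(zw)
    if (qr2$rank < ncol(zw)) {
      stop("confound regressor matrix is rank deficient after whitening")
    }
    out[, j] <- qr.resid(qr2, yw)
  }
  out
}
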