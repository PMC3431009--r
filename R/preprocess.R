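# Temporal preprocessing of voxel time series. All three operations are
# linear projections / linear filters applied column-wise to a T x V matrix
# (time in rows).

as_ts_matrix <- function(ts) {
  if (is.null(dim(ts))) ts <- matrix(ts, ncol = 1L)
  storage.mode(ts) <- "double"
  if (!all(is.finite(ts))) stop("time series contain non-finite values")
  ts
}

copy_ts_attrs <- function(res, ts) {
  for (a in c("voxel_index", "tr")) {
    v <- attr(ts, a)
    if (!is.null(v)) attr(res, a) <- v
  }
  res
}

#' Polynomial detrending
#'
#' Removes the least-squares fit on `{1, t, ..., t^order}` from each column;
#' the residuals are exactly orthogonal to the polynomial regressors.
#'
#' @param ts numeric vector or T x V matrix (time in rows).
#' @param order polynomial order (default 2: linear and quadratic, plus
#'   intercept).
#' @return Matrix of residuals with the input's attributes preserved.
#' @export
detrend_poly <- function(ts, order = 2L) {
  x <- as_ts_matrix(ts)
  T <- nrow(x)
  if (T <= order + 1L) {
    stop("need more than order+1 = ", order + 1L, " timepoints, got ", T)
  }
  X <- cbind(1, stats::poly(seq_len(T), degree = order))
  Q <- qr.Q(qr(X))
  res <- x - Q %*% crossprod(Q, x)
  copy_ts_attrs(res, x)
}

#' Ideal band-pass filter
#'
#' Discrete-Fourier mask: frequency components with `f_lo <= |f| <= f_hi`
#' are kept unchanged, all others (including DC when `f_lo > 0`) are zeroed;
#' the output is the real part of the inverse transform.
#'
#' @param ts numeric vector or T x V matrix (time in rows).
#' @param tr repetition time in seconds (sampling interval).
#' @param f_lo,f_hi band edges in Hz; must satisfy
#'   `0 <= f_lo < f_hi <= 1/(2 tr)`. Defaults 0.01-0.1 Hz, the conventional
#'   resting-state band.
#' @return Filtered matrix.
#' @export
bandpass_filter <- function(ts, tr, f_lo = 0.01, f_hi = 0.1) {
  x <- as_ts_matrix(ts)
  T <- nrow(x)
  nyq <- 1 / (2 * tr)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyq + 1e-12)) {
    stop("invalid band: need 0 <= f_lo < f_hi <= Nyquist (", signif(nyq, 4), " Hz)")
  }
  k <- 0:(T - 1L)
  freq <- pmin(k, T - k) / (T * tr)
  keep <- freq >= f_lo - 1e-12 & freq <= f_hi + 1e-12
  F <- stats::mvfft(x)
  F[!keep, ] <- 0
  res <- Re(stats::mvfft(F, inverse = TRUE)) / T
  copy_ts_attrs(res, x)
}

#' Nuisance regression
#'
#' Least-squares residual of each column of `ts` on an intercept plus the
#' confound columns (e.g. motion parameters, white-matter and CSF grand
#' means). Rank-deficient confound sets are handled by dropping linearly
#' dependent columns with a warning.
#'
#' @param ts numeric vector or T x V matrix (time in rows).
#' @param confounds T x C matrix of confound series.
#' @return Residual matrix, orthogonal to every retained confound.
#' @export
nuisance_regress <- function(ts, confounds) {
  x <- as_ts_matrix(ts)
  C <- as_ts_matrix(confounds)
  if (nrow(C) != nrow(x)) stop("confounds must have the same number of rows as ts")
  X <- cbind(1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("confound matrix rank-deficient: dropping ",
            ncol(X) - qrX$rank, " dependent column(s)")
  }
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  res <- x - Q %*% crossprod(Q, x)
  copy_ts_attrs(res, x)
}

#' Full temporal preprocessing of a scan
#'
#' Applies, in order: polynomial detrend, ideal band-pass, and nuisance
#' regression on the scan's motion parameters plus the CSF grand-mean
#' series, over the masked voxel matrix.
#'
#' @param scan a `scan4d`.
#' @param template the matching `brain_template`.
#' @param detrend_order polynomial detrend order.
#' @param band length-2 band edges in Hz, or `NULL` to skip filtering.
#' @param use_motion,use_csf include motion parameters / CSF grand mean in
#'   the nuisance set.
#' @return A `scan4d` with preprocessed data.
#' @export
preprocess_scan <- function(scan, template, detrend_order = 2L,
                            band = c(0.01, 0.1), use_motion = TRUE,
                            use_csf = TRUE) {
  mat <- scan_matrix(scan, template)
  mat <- detrend_poly(mat, order = detrend_order)
  if (!is.null(band)) {
    mat <- bandpass_filter(mat, tr = scan$tr, f_lo = band[1], f_hi = band[2])
  }
  conf <- NULL
  if (use_motion && !is.null(scan$motion_params)) conf <- scan$motion_params
  if (use_csf && sum(template$csf_region) > 0) {
    csf_cols <- match(which(template$csf_region), attr(mat, "voxel_index"))
    csf_mean <- rowMeans(mat[, csf_cols, drop = FALSE])
    conf <- cbind(conf, csf = csf_mean)
  }
  if (!is.null(conf)) mat <- nuisance_regress(mat, conf)
  matrix_to_scan(mat, template, scan)
}
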