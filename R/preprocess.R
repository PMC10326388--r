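# Scan preprocessing: motion-outlier detection, detrending, smoothing,
# band-pass filtering, slice-timing correction and nuisance regression.

#' Flag motion-corrupted acquisitions
#'
#' Computes the global in-mask mean signal per acquisition and flags those
#' whose robust z-score (median/MAD) exceeds `threshold`. New flags are
#' unioned with any pre-existing flags on the scan.
#'
#' @param scan A [bold_scan()] with at least 10 acquisitions.
#' @param threshold Robust z-score cutoff (default 5).
#' @return The scan with updated `outlier_flags`.
#' @export
detect_motion_outliers <- function(scan, threshold = 5) {
  if (sum(scan$mask) == 0) abort("empty mask.")
  if (n_acquisitions(scan) < 10L) abort("need at least 10 acquisitions.")
  g <- colMeans(flatten_scan(scan))
  s <- mad(g)
  z <- if (s > 0) (g - median(g)) / s else rep(0, length(g))
  scan$outlier_flags <- scan$outlier_flags | (abs(z) > threshold)
  scan
}

#' Remove the least-squares linear trend
#'
#' Works on a numeric vector, a matrix with time in rows (each column
#' detrended), or a 4D array (each voxel series detrended along the fourth
#' dimension). The result has zero mean and zero slope per series;
#' detrending is idempotent.
#'
#' @param x Vector, matrix (t x series) or 4D array.
#' @return Same shape as `x`.
#' @export
detrend <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) {
    d <- dim(x)
    m <- t(matrix(x, ncol = d[4])) # t x voxels
    return(array(t(detrend(m)), dim = d))
  }
  v <- is.null(dim(x))
  m <- if (v) matrix(x, ncol = 1) else x
  nt <- nrow(m)
  if (nt < 3L) abort("need at least 3 timepoints to detrend.")
  tc <- seq_len(nt) - (nt + 1) / 2
  beta <- crossprod(tc, m) / sum(tc^2) # 1 x series slopes
  out <- sweep(m, 2, colMeans(m)) - outer(tc, as.numeric(beta))
  if (v) as.numeric(out) else out
}

# extract / assign slabs along one axis of an array
.axis_index <- function(x, axis, i) {
  idx <- lapply(dim(x), seq_len)
  idx[[axis]] <- i
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# separable 1D Gaussian convolution along `axis`, kernel renormalised at the
# boundary so constant inputs are exactly preserved
.gauss_axis <- function(x, sigma, axis) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  n <- dim(x)[axis]
  out <- array(0, dim(x))
  norm <- numeric(n)
  for (j in seq_along(w)) {
    o <- j - r - 1L
    dst <- seq.int(max(1L, 1L - o), min(n, n - o))
    if (!length(dst)) next
    src <- dst + o
    idx <- lapply(dim(x), seq_len)
    idx[[axis]] <- dst
    piece <- w[j] * .axis_index(x, axis, src)
    out <- do.call(`[<-`, c(list(out), idx, list(
      do.call(`[`, c(list(out), idx, list(drop = FALSE))) + piece
    )))
    norm[dst] <- norm[dst] + w[j]
  }
  shape <- rep(1L, length(dim(x)))
  shape[axis] <- n
  sweep(out, axis, norm, `/`)
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` in
#' voxel units on each axis. `fwhm_mm = 0` returns the input unchanged. For
#' 4D input each volume is smoothed independently.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm Full width at half maximum, mm (>= 0).
#' @param voxel_size mm per axis (length 3).
#' @return Array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size = c(1, 1, 1)) {
  if (fwhm_mm < 0) abort("`fwhm_mm` must be >= 0.")
  if (fwhm_mm == 0) return(volume)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  nd <- length(dim(volume))
  if (nd == 3L) {
    for (a in 1:3) volume <- .gauss_axis(volume, sig[a], a)
    return(volume)
  }
  if (nd != 4L) abort("`volume` must be 3D or 4D.")
  for (t in seq_len(dim(volume)[4])) {
    v <- volume[, , , t]
    for (a in 1:3) v <- .gauss_axis(v, sig[a], a)
    volume[, , , t] <- v
  }
  volume
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass of order 4, the
#' standard choice for isolating the 0.01--0.1 Hz band of spontaneous BOLD
#' fluctuations while removing slow drift and high-frequency noise without
#' shifting event timing.
#'
#' @param x Numeric vector or matrix with time in rows.
#' @param tr_seconds Sampling interval (s).
#' @param low_hz,high_hz Passband edges; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr_seconds)`.
#' @param order Butterworth order (applied twice by filtering both ways).
#' @return Filtered data, same shape.
#' @export
bandpass_filter <- function(x, tr_seconds, low_hz = 0.01, high_hz = 0.1,
                            order = 4L) {
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) abort("need 0 < low_hz < high_hz.")
  if (high_hz >= nyq) abort("`high_hz` must be below the Nyquist frequency.")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  v <- is.null(dim(x))
  m <- if (v) matrix(x, ncol = 1) else x
  out <- apply(m, 2, function(col) signal::filtfilt(bf, col))
  out <- matrix(out, nrow = nrow(m))
  if (v) as.numeric(out) else out
}

#' Slice-timing correction by temporal interpolation
#'
#' Shifts each axial slice's time series to a common reference slice time by
#' linear interpolation between neighbouring acquisitions, assuming an
#' interleaved (odd slices first) acquisition order within each TR. Off by
#' default in the pipelines: the synthetic generator does not simulate slice
#' offsets.
#'
#' @param scan A [bold_scan()].
#' @param ref_slice Reference slice (1-based, third axis).
#' @return The scan with interpolated data.
#' @export
slice_timing_correct <- function(scan, ref_slice = 1L) {
  d <- dim(scan$data)
  nz <- d[3]
  nt <- d[4]
  order_acq <- c(seq(1, nz, by = 2), seq(2, nz, by = 2)) # interleaved
  slice_time <- (match(seq_len(nz), order_acq) - 1) / nz # fraction of TR
  shift <- slice_time - slice_time[ref_slice]
  tt <- seq_len(nt)
  for (z in seq_len(nz)) {
    if (shift[z] == 0) next
    src <- tt + shift[z]
    src <- pmin(pmax(src, 1), nt)
    i0 <- pmin(floor(src), nt - 1)
    f <- src - i0
    sl <- scan$data[, , z, , drop = FALSE]
    m <- matrix(sl, ncol = nt) # voxels x t
    scan$data[, , z, ] <- array(
      m[, i0] * rep(1 - f, each = nrow(m)) + m[, i0 + 1] * rep(f, each = nrow(m)),
      dim = d[c(1, 2, 4)]
    )
  }
  scan
}

#' Nuisance regression
#'
#' Regresses every in-mask voxel series on an intercept, the six motion
#' parameters, one indicator column per flagged motion outlier, and the mean
#' white-matter and CSF series, and keeps the residuals. Outliers are
#' absorbed by their indicator columns (spike regression) rather than
#' deleted, so the time axis stays intact for filtering. Collinear design
#' columns are dropped with a warning.
#'
#' @param scan A [bold_scan()] with motion parameters and tissue means.
#' @return The scan with `data` replaced by the residual 4D array.
#' @export
nuisance_regress <- function(scan) {
  nt <- n_acquisitions(scan)
  cols <- list(intercept = rep(1, nt))
  if (!is.null(scan$motion_params)) cols$motion <- scan$motion_params
  if (any(scan$outlier_flags)) {
    flags <- which(scan$outlier_flags)
    ind <- matrix(0, nt, length(flags))
    ind[cbind(flags, seq_along(flags))] <- 1
    cols$outliers <- ind
  }
  if (!is.null(scan$tissue_means)) {
    cols$wm <- scan$tissue_means$white_matter
    cols$csf <- scan$tissue_means$csf
  }
  X <- do.call(cbind, cols)
  if (nt <= ncol(X) + 2L) abort("too few acquisitions for the design.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warn(sprintf(
      "design is rank-deficient (%d of %d columns kept); collinear columns dropped",
      qrX$rank, ncol(X)
    ))
  }
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  Y <- flatten_scan(scan) # voxel x t
  resid <- Y - (Y %*% Q) %*% t(Q)
  scan$data <- unflatten_scan(resid, scan)
  scan
}
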