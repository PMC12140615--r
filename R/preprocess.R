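## Preprocessing: outlier interpolation -> Wiener deconvolution with the
## canonical HRF -> z-scoring -> smoothed forward-difference training pairs.
## The pipeline order is fixed; each step runs per run, runs are pooled only
## when pairs are concatenated.

#' Linearly interpolate outlier frames
#'
#' Per column, frames deviating from the column mean by more than
#' \code{zThresh} standard deviations are replaced by linear interpolation
#' between the nearest non-outlier neighbours; outliers at the ends are
#' clamped to the nearest valid value. The mean and sd are computed once from
#' the raw column (not re-estimated iteratively). All other frames are
#' returned bit-identical.
#'
#' @param ts A \linkS4class{ParcelTimeseries}.
#' @param zThresh Outlier threshold in standard deviations (default 5).
#' @return A \linkS4class{ParcelTimeseries} with outliers replaced.
#' @export
interpolateOutliers <- function(ts, zThresh = 5) {
  stopifnot(is(ts, "ParcelTimeseries"), zThresh > 0)
  x <- ts@data
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    s <- stats::sd(v)
    if (s == 0) stop("column ", j, " has zero variance")
    out <- abs(v - mean(v)) > zThresh * s
    if (!any(out)) next
    if (all(out)) stop("column ", j, " is entirely outliers")
    idx <- which(!out)
    x[out, j] <- stats::approx(idx, v[idx], xout = which(out),
                               rule = 2)$y
  }
  initialize(ts, data = x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The community-standard canonical HRF: a difference of gamma densities with
#' response delay 6 s, undershoot delay 16 s, unit dispersions and
#' response-to-undershoot ratio 6, sampled every \code{tr} seconds at
#' \code{length} points and scaled to unit peak. The continuous form peaks
#' near 5 s.
#'
#' @param tr Sampling interval in seconds.
#' @param length Number of kernel samples (default 30).
#' @return Numeric vector of \code{length} samples with maximum 1.
#' @examples
#' h <- canonicalHrf(0.72)
#' (which.max(h) - 1) * 0.72   # peak time in seconds, ~5 s
#' @export
canonicalHrf <- function(tr, length = 30L) {
  stopifnot(tr > 0, length >= 2)
  t <- (seq_len(length) - 1) * tr
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Wiener deconvolution
#'
#' Frequency-domain deconvolution with the filter
#' \eqn{\hat X(f) = \overline{H(f)}\, Y(f) / (|H(f)|^2 + \mathrm{nsr})},
#' where \eqn{H} is the transform of the kernel zero-padded to a common
#' length; the estimate is truncated back to \code{length(y)}. The
#' noise-to-signal power ratio \code{nsr} regularizes frequencies where the
#' kernel has little power.
#'
#' @param y Numeric vector (observed signal).
#' @param kernel Convolution kernel, shorter than \code{y}.
#' @param nsr Noise-power to signal-power ratio (default 0.02).
#' @return Numeric vector of \code{length(y)}: the deconvolved estimate.
#' @export
wienerDeconvolve <- function(y, kernel, nsr = 0.02) {
  stopifnot(is.numeric(y), is.numeric(kernel), nsr >= 0)
  if (length(kernel) >= length(y))
    stop("kernel must be shorter than the signal")
  if (all(kernel == 0)) stop("kernel must not be all zero")
  L <- length(y) + length(kernel) - 1L
  Y <- stats::fft(c(y, rep(0, L - length(y))))
  H <- stats::fft(c(kernel, rep(0, L - length(kernel))))
  Xhat <- Conj(H) * Y / (Mod(H)^2 + nsr)
  Re(stats::fft(Xhat, inverse = TRUE))[seq_along(y)] / L
}

#' Z-score each parcel timeseries
#'
#' Centers and scales each column (within each run) to mean 0, sd 1. The
#' applied per-run centering and scaling are recorded in \code{meta$zscore}
#' so ground-truth states can be mapped into the standardized coordinates.
#'
#' @param ts A \linkS4class{ParcelTimeseries}.
#' @return A standardized \linkS4class{ParcelTimeseries}.
#' @export
zscoreColumns <- function(ts) {
  stopifnot(is(ts, "ParcelTimeseries"))
  x <- ts@data
  zs <- list()
  for (r in seq_along(ts@runBoundaries)) {
    rows <- runRows(ts, r)
    mu <- colMeans(x[rows, , drop = FALSE])
    sdv <- apply(x[rows, , drop = FALSE], 2, stats::sd)
    if (any(sdv == 0))
      stop("zero-variance parcel: ",
           paste(ts@parcelIds[sdv == 0], collapse = ", "))
    x[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, mu), 2, sdv, "/")
    zs[[r]] <- list(center = mu, scale = sdv)
  }
  meta <- ts@meta
  meta$zscore <- zs
  initialize(ts, data = x, meta = meta)
}

## frame indices of run r
runRows <- function(ts, r) {
  rb <- ts@runBoundaries
  from <- rb[r]
  to <- if (r < length(rb)) rb[r + 1] - 1L else nrow(ts@data)
  seq.int(from, to)
}

#' Build derivative training pairs
#'
#' Pairs each state \eqn{x_n} with the smoothed forward difference
#' \eqn{\hat\Delta x_n = (x_{n+2} - x_n)/2} (two-point moving average of the
#' forward differences, suppressing Nyquist-frequency noise), or with the
#' plain forward difference \eqn{x_{n+1} - x_n} when \code{smooth = FALSE}.
#' Pairs never cross a run boundary; runs are concatenated afterwards.
#'
#' @param ts A (preprocessed) \linkS4class{ParcelTimeseries}.
#' @param smooth Apply two-point smoothing (default TRUE).
#' @return A \linkS4class{DerivativeSamples} object.
#' @export
buildTrainingPairs <- function(ts, smooth = TRUE) {
  stopifnot(is(ts, "ParcelTimeseries"))
  lag <- if (smooth) 2L else 1L
  states <- targets <- NULL
  idx <- integer(0)
  for (r in seq_along(ts@runBoundaries)) {
    rows <- runRows(ts, r)
    if (length(rows) < lag + 1L)
      stop("run ", r, " has ", length(rows),
           " frames; need at least ", lag + 1L)
    x <- ts@data[rows, , drop = FALSE]
    m <- nrow(x) - lag
    s <- x[seq_len(m), , drop = FALSE]
    tg <- if (smooth) (x[seq_len(m) + 2L, , drop = FALSE] - s) / 2
          else x[seq_len(m) + 1L, , drop = FALSE] - s
    states <- rbind(states, s)
    targets <- rbind(targets, tg)
    idx <- c(idx, rows[seq_len(m)])
  }
  new("DerivativeSamples", states = states, targets = targets,
      sampleIndex = as.integer(idx), smoothed = smooth)
}

#' Full preprocessing pipeline
#'
#' Applies, in fixed order: outlier interpolation, per-run Wiener
#' deconvolution of each parcel with the canonical HRF, per-run z-scoring,
#' and derivative-pair construction. The deconvolution estimates the hidden
#' neural states from the BOLD-like observation.
#'
#' @param ts Raw \linkS4class{ParcelTimeseries}.
#' @param zThresh Outlier threshold (sd units), default 5.
#' @param nsr Wiener noise-to-signal ratio, default 0.02.
#' @param hrfLength HRF kernel length in samples, default 30.
#' @param deconvolve Apply hemodynamic deconvolution (default TRUE); disable
#'   for data already expressed as neural states.
#' @param smooth Two-point derivative smoothing (default TRUE).
#' @return List with elements \code{ts} (the standardized
#'   \linkS4class{ParcelTimeseries}) and \code{samples}
#'   (\linkS4class{DerivativeSamples} ready for \code{\link{fitMindy}}).
#' @export
preprocessTimeseries <- function(ts, zThresh = 5, nsr = 0.02,
                                 hrfLength = 30L, deconvolve = TRUE,
                                 smooth = TRUE) {
  ts <- interpolateOutliers(ts, zThresh)
  if (deconvolve) {
    h <- canonicalHrf(ts@tr, hrfLength)
    x <- ts@data
    for (r in seq_along(ts@runBoundaries)) {
      rows <- runRows(ts, r)
      for (j in seq_len(ncol(x)))
        x[rows, j] <- wienerDeconvolve(x[rows, j], h, nsr)
    }
    ts <- initialize(ts, data = x)
  }
  ts <- zscoreColumns(ts)
  list(ts = ts, samples = buildTrainingPairs(ts, smooth))
}
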