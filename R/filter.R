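#' @include AllClasses.R
NULL

# Zero-phase band-pass of a channels x samples matrix.
#
# The filter is applied in the frequency domain: each channel is multiplied
# by the squared magnitude response of an order-`order` Butterworth high-pass
# cascaded with an order-`order` Butterworth low-pass. The squared magnitude
# is exactly the transfer function of a forward-backward (filtfilt) pass, so
# the result is zero-phase with doubled effective roll-off. A time-domain
# IIR recursion is avoided deliberately: at a 0.05 Hz cutoff and typical EEG
# sampling rates the poles sit so close to z = 1 that the recursion acts as
# a near-double-integrator of rounding noise and corrupts the passband.
#
# Before transforming, the least-squares linear trend is removed (the
# high-pass discards it by construction) and the signal is zero-padded by
# ten high-pass time constants on each side so that the long tail of the
# high-pass kernel never wraps data around the circular convolution.
.bandpassMatrix <- function(dat, fs, hpHz, lpHz, order) {
  if (!is.null(lpHz) && !is.null(hpHz) && lpHz <= hpHz)
    stop("bandpass: low-pass cutoff must exceed high-pass cutoff")
  if (!is.null(lpHz) && lpHz >= fs / 2)
    stop("bandpass: low-pass cutoff must lie below the Nyquist frequency")
  hasHp <- !is.null(hpHz) && hpHz > 0
  if (!hasHp && is.null(lpHz)) return(dat)
  n <- ncol(dat)
  refHz <- if (hasHp) hpHz else lpHz
  npad <- as.integer(ceiling(10 * fs / (2 * pi * refHz)))
  m <- stats::nextn(n + 2L * npad, c(2, 3, 5))
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  af <- abs(f)
  h <- rep(1, m)
  if (hasHp) {
    r <- (af / hpHz)^(2 * order)
    h <- h * r / (1 + r)
  }
  if (!is.null(lpHz))
    h <- h / (1 + (af / lpHz)^(2 * order))
  idx <- seq_len(n)
  cx <- idx - mean(idx)
  sxx <- sum(cx * cx)
  for (i in seq_len(nrow(dat))) {
    x <- dat[i, ]
    if (hasHp) {
      x <- x - mean(x) - (sum(cx * x) / sxx) * cx
    } else {
      # keep the mean/trend when only low-passing
      base <- mean(x) + (sum(cx * x) / sxx) * cx
      x <- x - base
    }
    y <- c(rep(0, npad), x, rep(0, m - n - npad))
    out <- Re(stats::fft(stats::fft(y) * h, inverse = TRUE)) / m
    x <- out[(npad + 1):(npad + n)]
    if (!hasHp) x <- x + base
    dat[i, ] <- x
  }
  dat
}

#' @rdname bandpass
#' @export
setMethod("bandpass", "ContinuousRecording",
  function(x, hpHz = 0.05, lpHz = 60, order = 4L) {
    x@data <- .bandpassMatrix(x@data, x@fsHz, hpHz, lpHz, order)
    x
  })

#' @rdname bandpass
#' @export
setMethod("bandpass", "EpochSet",
  function(x, hpHz = 0.05, lpHz = 60, order = 4L) {
    d <- x@data
    for (e in seq_len(dim(d)[1])) {
      m <- d[e, , , drop = FALSE]
      dim(m) <- dim(d)[2:3]
      d[e, , ] <- .bandpassMatrix(m, x@fsHz, hpHz, lpHz, order)
    }
    x@data <- d
    x
  })
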