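#' Detection metrics for ZRA records
#'
#' Four candidate metrics quantify the fluctuation content of a recording:
#' \describe{
#'   \item{`rms`}{RMS of the mean-subtracted trace.}
#'   \item{`ma_rms`}{RMS of the centered 1 s moving average (mean
#'     subtracted) — the slow component.}
#'   \item{`resid_rms`}{RMS of the trace minus its moving average, which
#'     effectively isolates frequencies above 1 Hz.}
#'   \item{`cheb_power`}{Chebyshev noise spectroscopy: root-sum-square of
#'     the order 2-5 discrete Chebyshev coefficients on consecutive 4 s
#'     windows, averaged across windows — power on the 0.4-2 s timescale.}
#' }
#' All metrics are offset-invariant and scale linearly with amplitude.
#'
#' @param trace a [zra_trace()] or numeric vector.
#' @param kinds which metrics to compute.
#' @param window moving-average window, s.
#' @param cheb_orders Chebyshev orders to aggregate.
#' @param cheb_window Chebyshev analysis window, s.
#' @param fs sampling rate, Hz (for bare numeric input).
#' @return `signal_metrics()`: a tibble with columns `metric` and `value`
#'   (trace units). `compute_metric()`: a single numeric value.
#' @export
signal_metrics <- function(trace, kinds = c("rms", "ma_rms", "resid_rms", "cheb_power"),
                           window = 1, cheb_orders = 2:5, cheb_window = 4,
                           fs = NULL) {
  vals <- vapply(kinds, function(k) {
    compute_metric(trace, k, window = window, cheb_orders = cheb_orders,
                   cheb_window = cheb_window, fs = fs)
  }, 0)
  tibble(metric = kinds, value = vals)
}

#' @rdname signal_metrics
#' @param kind one of `"rms"`, `"ma_rms"`, `"resid_rms"`, `"cheb_power"`.
#' @export
compute_metric <- function(trace, kind = c("rms", "ma_rms", "resid_rms", "cheb_power"),
                           window = 1, cheb_orders = 2:5, cheb_window = 4,
                           fs = NULL) {
  kind <- match.arg(kind)
  if (is.numeric(trace)) {
    x <- trace
    if (is.null(fs)) abort("`fs` is required for a bare numeric trace.")
  } else {
    x <- trace_samples(trace); fs <- trace_fs(trace)
  }
  if (kind %in% c("ma_rms", "resid_rms") && length(x) <= window * fs) {
    abort("trace is shorter than the moving-average window.")
  }
  rms <- function(v) sqrt(mean((v - mean(v))^2))
  switch(kind,
    rms = rms(x),
    ma_rms = rms(moving_average(x, fs, window)),
    resid_rms = rms(x - moving_average(x, fs, window)),
    cheb_power = cheb_power(x, fs, cheb_orders, cheb_window)
  )
}

#' Centered moving average with reflective edge padding
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param window window length, s (rounded to an odd number of samples).
#' @return numeric vector of the same length.
#' @export
moving_average <- function(x, fs, window = 1) {
  w <- as.integer(round(window * fs))
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  if (half >= n) abort("moving-average window longer than the trace.")
  xp <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  cs <- cumsum(c(0, xp))
  (cs[(w + 1):(n + w)] - cs[1:n]) / w
}

#' Discrete Chebyshev (Gram) polynomial coefficients
#'
#' Least-squares projection of a window onto the orthonormal discrete
#' Chebyshev polynomial basis on its sample grid. The basis is built by QR
#' orthonormalization of the Vandermonde matrix, which is exact and
#' numerically stable for the low orders used here; signs are fixed so each
#' basis vector has a positive leading coefficient.
#'
#' @param x numeric window.
#' @param max_order highest polynomial order (window must have at least
#'   `max_order + 1` samples).
#' @return numeric vector of coefficients for orders `0:max_order`.
#' @export
chebyshev_coeffs <- function(x, max_order = 5) {
  m <- length(x)
  if (m < max_order + 1) abort("window shorter than max_order + 1 samples.")
  Q <- cheb_basis(m, max_order)
  as.numeric(crossprod(Q, x))
}

cheb_basis <- function(m, max_order) {
  t <- seq(-1, 1, length.out = m)
  V <- outer(t, 0:max_order, `^`)
  qrd <- qr(V)
  Q <- qr.Q(qrd)
  ## fix signs: make the highest-degree (leading) coefficient positive
  R <- qr.R(qrd)
  s <- sign(diag(R)); s[s == 0] <- 1
  sweep(Q, 2, s, `*`)
}

## Chebyshev noise-spectroscopy metric: RSS of orders `orders` per
## consecutive `window_s` window, averaged across complete windows.
cheb_power <- function(x, fs, orders = 2:5, window_s = 4) {
  m <- as.integer(floor(window_s * fs))
  if (m < max(orders) + 1) abort("Chebyshev window too short for the requested orders.")
  k <- length(x) %/% m
  if (k < 1) abort("trace shorter than one Chebyshev window.")
  Q <- cheb_basis(m, max(orders))[, orders + 1L, drop = FALSE]
  vals <- vapply(seq_len(k), function(i) {
    xi <- x[((i - 1) * m + 1):(i * m)]
    sqrt(sum(crossprod(Q, xi)^2))
  }, 0)
  mean(vals)
}

#' Welch power spectral density
#'
#' One-sided PSD estimate by Welch's method: Hann window, 50% segment
#' overlap, per-segment mean removal (constant detrend) and no further
#' detrending.
#'
#' @param trace a [zra_trace()] or numeric vector.
#' @param segment_length segment length in samples (default: 8 segments).
#' @param overlap fractional overlap between segments.
#' @param fs sampling rate, Hz (for bare numeric input).
#' @return a tibble of class `zra_psd` with columns `freq` (Hz) and `psd`
#'   (units^2 / Hz).
#' @export
welch_psd <- function(trace, segment_length = NULL, overlap = 0.5, fs = NULL) {
  if (is.numeric(trace)) {
    x <- trace
    if (is.null(fs)) abort("`fs` is required for a bare numeric trace.")
  } else {
    x <- trace_samples(trace); fs <- trace_fs(trace)
  }
  n <- length(x)
  if (is.null(segment_length)) segment_length <- max(8L, 2L * (n %/% 9L))
  L <- as.integer(segment_length)
  if (L > n) abort("`segment_length` exceeds the trace length.")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))  # Hann
  norm <- fs * sum(w^2)
  nfreq <- L %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / norm
    acc <- acc + P[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  ## one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (L %% 2L == 0L) dbl[nfreq] <- 1
  psd <- psd * dbl
  out <- tibble(freq = (seq_len(nfreq) - 1L) * fs / L, psd = psd)
  class(out) <- c("zra_psd", class(out))
  attr(out, "fs") <- fs
  out
}
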