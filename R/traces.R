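#' Uniformly sampled signal traces
#'
#' A `zra_trace` is a tibble with columns `time` (seconds) and `current`
#' (or `voltage`), carrying the sampling rate, unit and a component label as
#' attributes. All generators in the package return this shape so traces can
#' be manipulated with ordinary dplyr/tidyr verbs and plotted with
#' [ggplot2::autoplot()].
#'
#' @param samples numeric vector of sample values.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample, seconds.
#' @param label component label (e.g. `"corrosion"`, `"ecg"`).
#' @param units `"A"` for current traces, `"V"` for voltage traces.
#' @return a tibble of class `zra_trace` with columns `time` and `current`
#'   (for `units = "A"`) or `voltage` (for `units = "V"`).
#' @export
zra_trace <- function(samples, fs, t0 = 0, label = "signal", units = "A") {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.")
  }
  if (any(!is.finite(samples))) abort("trace samples must be finite.")
  col <- if (units == "V") "voltage" else "current"
  out <- list(time = t0 + (seq_along(samples) - 1) / fs)
  out[[col]] <- as.numeric(samples)
  new_tibble(out, nrow = length(samples),
             fs = fs, t0 = t0, label = label, units = units,
             class = "zra_trace")
}

#' @export
print.zra_trace <- function(x, ...) {
  cat(sprintf("# zra_trace: %s [%s], fs = %g Hz, n = %d (%.4g s)\n",
              attr(x, "label") %||% "signal", attr(x, "units") %||% "A",
              trace_fs(x), nrow(x), nrow(x) / trace_fs(x)))
  NextMethod()
}

#' Trace accessors
#'
#' @param x a `zra_trace` (or any tibble with a `time` column).
#' @return `trace_fs()` the sampling rate in Hz; `trace_samples()` the bare
#'   numeric sample vector.
#' @export
trace_fs <- function(x) {
  fs <- attr(x, "fs")
  if (!is.null(fs)) return(fs)
  if (!is.null(x$time) && nrow(x) > 1) return(1 / stats::median(diff(x$time)))
  abort("cannot determine the sampling rate of this trace.")
}

#' @rdname trace_fs
#' @export
trace_samples <- function(x) {
  if (!is.null(x[["current"]])) return(x[["current"]])
  if (!is.null(x[["voltage"]])) return(x[["voltage"]])
  abort("trace has neither a `current` nor a `voltage` column.")
}

## ---- frequency-domain filtering ------------------------------------------

.zra_grid_cache <- new.env(parent = emptyenv())

## Two-sided frequency grid of the reflectively padded signal (cached:
## every component of a record reuses the same grid).
freq_grid <- function(n, fs, pad_s = 1) {
  key <- paste(n, fs, pad_s, sep = "_")
  hit <- .zra_grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  npad <- min(n - 1L, as.integer(round(pad_s * fs)))
  m <- n + 2L * npad
  f <- seq_len(m) - 1L
  neg <- f > m / 2
  f[neg] <- f[neg] - m
  f <- f * fs / m
  ## |f| with the DC bin evaluated in its low-frequency limit
  out <- list(m = m, npad = npad, f = f, fa = pmax(abs(f), 1e-9), neg = neg)
  if (length(.zra_grid_cache) > 16) rm(list = ls(.zra_grid_cache), envir = .zra_grid_cache)
  .zra_grid_cache[[key]] <- out
  out
}

## Turn a gain evaluated at the grid's |f| values into the full two-sided
## complex gain (conjugate at negative frequencies keeps the output real).
two_sided_gain <- function(g, grid) {
  g[!is.finite(g)] <- 0
  g[grid$neg] <- Conj(g[grid$neg])
  g
}

## Apply a complex frequency-domain gain to a real signal by FFT
## multiplication. `gain` is either a function of frequency (vectorised over
## f >= 0, conjugated internally for negative frequencies) or a precomputed
## two-sided complex vector on the grid returned by freq_grid(). Edge
## effects of the implicit circular convolution are suppressed by
## reflective padding (default 1 s on each side).
apply_freq_gain <- function(x, fs, gain, pad_s = 1) {
  n <- length(x)
  grid <- freq_grid(n, fs, pad_s)
  npad <- grid$npad
  xp <- if (npad > 0) c(x[(npad + 1):2], x, x[(n - 1):(n - npad)]) else x
  g <- if (is.function(gain)) two_sided_gain(gain(grid$fa), grid) else gain
  if (length(g) != grid$m) abort("precomputed gain does not match the FFT grid.")
  y <- Re(fft(fft(xp) * g, inverse = TRUE)) / grid$m
  y[(npad + 1):(npad + n)]
}

## Filtered sum of several sources: one inverse FFT for
## sum_i fft(x_i) * g_i. All x_i share the length of the first source;
## gains are precomputed two-sided vectors on the common grid.
apply_freq_gain_multi <- function(xs, gains, fs, pad_s = 1) {
  n <- length(xs[[1]])
  grid <- freq_grid(n, fs, pad_s)
  npad <- grid$npad
  acc <- complex(real = rep(0, grid$m))
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    xp <- if (npad > 0) c(x[(npad + 1):2], x, x[(n - 1):(n - npad)]) else x
    acc <- acc + fft(xp) * gains[[i]]
  }
  y <- Re(fft(acc, inverse = TRUE)) / grid$m
  y[(npad + 1):(npad + n)]
}

## ---- deterministic seed substreams ---------------------------------------

## Named per-component substreams derived from one master seed, so toggling
## one component never changes another's realisation.
.substream_offsets <- c(
  "pitting-bare" = 11L, "pitting-coated" = 12L,
  "bubbles-bare" = 21L, "bubbles-coated" = 22L,
  "ecg" = 31L, "emg" = 32L,
  "amp" = 41L, "johnson" = 42L, "mains" = 43L
)

substream_seed <- function(master, name) {
  off <- .substream_offsets[[name]]
  if (is.null(off)) abort(paste0("unknown substream '", name, "'"))
  s <- (as.double(master) %% 2147483647) * 48271 + off * 9973
  as.integer(s %% 2147483647) + 1L
}

## Stable string hash (djb2, mod 2^31-1) used to give every Monte-Carlo
## realization its own seed as a pure function of (master seed, condition),
## so grid subsets reproduce the identical realizations as the full grid.
hash_seed <- function(master, ...) {
  key <- paste(format(list(...), digits = 12), collapse = "|")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.double(master) %% 2147483647 * 7919) %% 2147483647) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
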