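#' Instrument and ADC specifications
#'
#' `instrument_spec()` describes the analogue front end: amplifier input
#' current noise (white, RMS over the internal bandwidth), optional mains
#' hum, and the temperature entering the Johnson-Nyquist noise of the loop.
#' `adc_spec()` describes digitization: output rate, quantization step and
#' the resampling strategy used to get from the internal rate to the output
#' rate.
#'
#' @param amp_noise_rms amplifier current-noise RMS, A (over the internal
#'   bandwidth).
#' @param mains_freq mains frequency, 50 or 60 Hz; `NULL` disables hum.
#' @param mains_amp mains hum amplitude, A.
#' @param temperature temperature, K.
#' @param fs_internal internal (generation) sampling rate, Hz.
#' @return `instrument_spec()`: an object of class `zra_instrument`.
#' @export
instrument_spec <- function(amp_noise_rms = 0.05e-6, mains_freq = NULL,
                            mains_amp = 0, temperature = 310,
                            fs_internal = 10000) {
  if (amp_noise_rms < 0 || mains_amp < 0) abort("noise amplitudes must be >= 0.")
  if (!is.null(mains_freq) && !mains_freq %in% c(50, 60)) {
    abort("`mains_freq` must be 50 or 60 Hz (or NULL).")
  }
  .check_pos(temperature, "temperature"); .check_pos(fs_internal, "fs_internal")
  structure(list(amp_noise_rms = amp_noise_rms, mains_freq = mains_freq,
                 mains_amp = mains_amp, temperature = temperature,
                 fs_internal = fs_internal),
            class = "zra_instrument")
}

#' @rdname instrument_spec
#' @param fs_out ADC output sampling rate, Hz.
#' @param delta_lsb quantization step, A (0 disables quantization).
#' @param strategy resampling strategy: `"sinc"` (ideal brick-wall low pass),
#'   `"antialias_decimate"` (FIR low pass at 0.45 fs_out, then integer
#'   decimation) or `"naive_subsample"` (every k-th sample, no filtering).
#' @return `adc_spec()`: an object of class `zra_adc`.
#' @export
adc_spec <- function(fs_out, delta_lsb = 0.05e-6,
                     strategy = c("antialias_decimate", "sinc", "naive_subsample")) {
  .check_pos(fs_out, "fs_out")
  if (delta_lsb < 0) abort("`delta_lsb` must be >= 0.")
  strategy <- match.arg(strategy)
  structure(list(fs_out = fs_out, delta_lsb = delta_lsb, strategy = strategy),
            class = "zra_adc")
}

#' Instrumental noise current
#'
#' Sum of (a) amplifier white noise with the configured RMS over the
#' internal bandwidth, (b) optional mains hum, and (c) Johnson-Nyquist
#' current noise with one-sided PSD `S_I(f) = 4 kB T Re(1/Zloop(f))`
#' (current-noise formulation of the fluctuation-dissipation theorem),
#' shaped in the frequency domain.
#'
#' @param inst an [instrument_spec()].
#' @param loop a [loop_spec()] (for the Johnson term).
#' @param duration record length, s.
#' @param seed integer master seed (split into amp/johnson/mains streams).
#' @param decompose return per-component columns instead of the sum.
#' @return a current [zra_trace()] at `fs_internal`; with
#'   `decompose = TRUE` a long tibble `time, component, current`.
#' @export
instrument_noise <- function(inst, loop, duration, seed = 1, decompose = FALSE) {
  fs <- inst$fs_internal
  n <- as.integer(round(duration * fs))
  amp <- if (inst$amp_noise_rms > 0) {
    with_seed(substream_seed(seed, "amp"), rnorm(n, sd = inst$amp_noise_rms))
  } else rep(0, n)
  johnson <- johnson_noise(inst, loop, n, substream_seed(seed, "johnson"))
  mains <- if (!is.null(inst$mains_freq) && inst$mains_amp > 0) {
    ph <- with_seed(substream_seed(seed, "mains"), runif(1, 0, 2 * pi))
    inst$mains_amp * sin(2 * pi * inst$mains_freq * (seq_len(n) - 1) / fs + ph)
  } else rep(0, n)
  if (decompose) {
    t <- (seq_len(n) - 1) / fs
    out <- dplyr::bind_rows(
      tibble(time = t, component = "amplifier", current = amp),
      tibble(time = t, component = "johnson", current = johnson),
      tibble(time = t, component = "mains", current = mains)
    )
    attr(out, "fs") <- fs
    return(out)
  }
  zra_trace(amp + johnson + mains, fs, label = "instrument")
}

## Evaluate all per-source transfer gains once on the padded FFT grid of an
## n-sample record: zone impedances are computed a single time and reused
## for the corrosion dividers, 1/Zloop and the Johnson shaping gain.
precompute_loop_gains <- function(loop, n, fs, instrument) {
  grid <- freq_grid(n, fs, pad_s = 1)
  zones <- electrode_zones(loop$electrode)
  zi <- lapply(zones, function(z) ckt_impedance(z$circuit, grid$fa))
  ytot <- complex(real = rep(0, grid$m))
  for (z in zi) {
    y <- 1 / z
    y[is.infinite(Mod(z))] <- 0
    ytot <- ytot + y
  }
  ze <- 1 / ytot
  zloop <- loop$Rs + 2 * ze + loop$Rshunt
  yext <- 1 / (loop$Rs + loop$Rshunt + ze)
  out <- list(bio_voltage = two_sided_gain(1 / zloop, grid))
  gz <- two_sided_gain(yext / (ytot + yext), grid)
  for (nm in names(zi)) out[[paste0("corrosion_", nm)]] <- gz
  sj <- 4 * .const$k_B * instrument$temperature * Re(1 / zloop)
  out$johnson <- two_sided_gain(complex(real = sqrt(pmax(sj, 0) * fs / 2)), grid)
  out
}

## Johnson-Nyquist current noise shaped to S_I(f) = 4 kB T Re(1/Zloop(f)).
## Unit-variance white noise at rate fs has one-sided PSD 2/fs, so the
## shaping gain is sqrt(S_I(f) fs / 2).
johnson_noise <- function(inst, loop, n, seed) {
  fs <- inst$fs_internal
  w <- with_seed(seed, rnorm(n))
  gain <- function(f) {
    y <- Re(1 / loop_impedance(loop, f))
    sqrt(pmax(4 * .const$k_B * inst$temperature * y, 0) * fs / 2)
  }
  apply_freq_gain(w, fs, gain)
}

#' Resample a trace to the ADC output rate
#'
#' Three strategies: `"sinc"` applies an ideal brick-wall low-pass at
#' `fs_out / 2` in the frequency domain before taking every k-th sample;
#' `"antialias_decimate"` applies a windowed-sinc FIR low-pass with cutoff
#' `0.45 fs_out` (zero phase, reflective padding) before integer decimation;
#' `"naive_subsample"` keeps every k-th sample with no filtering, so
#' out-of-band components alias. All strategies require the rates to be
#' commensurate (integer `k = fs_in / fs_out`).
#'
#' @param trace a [zra_trace()] (or numeric vector with `fs_in` given).
#' @param adc an [adc_spec()].
#' @param fs_in input rate, Hz (only needed for a bare numeric `trace`).
#' @return a [zra_trace()] at `fs_out`.
#' @export
resample_trace <- function(trace, adc, fs_in = NULL) {
  if (is.numeric(trace)) {
    x <- trace
    if (is.null(fs_in)) abort("`fs_in` is required for a bare numeric trace.")
    lab <- "signal"
  } else {
    x <- trace_samples(trace); fs_in <- trace_fs(trace)
    lab <- attr(trace, "label") %||% "signal"
  }
  fs_out <- adc$fs_out
  if (fs_out > fs_in) abort("`fs_out` must not exceed the input rate.")
  k <- fs_in / fs_out
  if (abs(k - round(k)) > 1e-9) {
    abort("resampling requires commensurate rates (integer fs_in / fs_out).")
  }
  k <- as.integer(round(k))
  if (k == 1L) return(zra_trace(x, fs_out, label = lab))
  y <- switch(adc$strategy,
    sinc = sinc_lowpass(x, fs_in, fs_out / 2)[seq(1, length(x), by = k)],
    antialias_decimate = fir_lowpass(x, fs_in, 0.45 * fs_out)[seq(1, length(x), by = k)],
    naive_subsample = x[seq(1, length(x), by = k)]
  )
  zra_trace(y, fs_out, label = lab)
}

## Ideal brick-wall low-pass via FFT bin zeroing.
sinc_lowpass <- function(x, fs, cutoff) {
  apply_freq_gain(x, fs, function(f) as.numeric(f <= cutoff) + 0i)
}

## Zero-phase windowed-sinc (Hamming) FIR low-pass applied by FFT
## convolution with reflective padding. Tap count scales with the ratio of
## the input rate to the cutoff so the transition band stays a fixed
## fraction of the cutoff.
fir_lowpass <- function(x, fs, cutoff) {
  ntaps <- min(length(x) - 1L, as.integer(2 * ceiling(8 * fs / cutoff / 2)) + 1L)
  h <- signal::fir1(ntaps - 1L, cutoff / (fs / 2), type = "low")
  n <- length(x); half <- (ntaps - 1L) %/% 2L
  npad <- min(n - 1L, half + 8L)
  xp <- c(x[(npad + 1):2], x, x[(n - 1):(n - npad)])
  m <- stats::nextn(length(xp) + ntaps - 1L, c(2, 3, 5))
  H <- fft(c(h, rep(0, m - ntaps)))
  X <- fft(c(xp, rep(0, m - length(xp))))
  y <- Re(fft(X * H, inverse = TRUE)) / m
  y[(npad + half + 1):(npad + half + n)]
}

#' ADC quantization
#'
#' `Q(x) = delta * round(x / delta)` with round-half-to-even (avoids DC bias
#' at quantizer ties). `delta = 0` disables quantization. Quantization is
#' idempotent and its error is bounded by `delta / 2`.
#'
#' @param trace a [zra_trace()] or numeric vector.
#' @param delta_lsb quantization step, A.
#' @return same shape as the input.
#' @export
quantize_trace <- function(trace, delta_lsb) {
  if (delta_lsb < 0) abort("`delta_lsb` must be >= 0.")
  if (delta_lsb == 0) return(trace)
  if (is.numeric(trace)) return(delta_lsb * round(trace / delta_lsb))
  q <- delta_lsb * round(trace_samples(trace) / delta_lsb)
  zra_trace(q, trace_fs(trace), label = attr(trace, "label") %||% "signal")
}

#' Assemble a full synthetic ZRA measurement
#'
#' Implements the complete measurement model: all components are generated
#' at the internal rate, corrosion fluctuations are filtered through their
#' zone-specific transfer paths and bioelectric voltages through `1/Zloop`,
#' instrumental noise is added directly, and the sum is resampled and
#' quantized by the ADC model,
#' \deqn{I_{measured}(t) = Q_{ADC}[I^{loop}_{corr}(t) + I^{loop}_{bio}(t) +
#'   I_{sensor}(t)].}
#'
#' The master seed is split deterministically into named per-component
#' substreams, so toggling one component never changes another's
#' realization, and the pre-quantization total is exactly the sum of the
#' individually exported components.
#'
#' @param electrode an [electrode_spec()].
#' @param duration record length, s.
#' @param seed integer master seed.
#' @param corrosion a [corrosion_config()].
#' @param bio a [bio_config()], or `NULL` to disable bioelectric sources.
#' @param phantom a [mouse_phantom()].
#' @param instrument an [instrument_spec()].
#' @param adc an [adc_spec()]; defaults to a 10 Hz anti-aliasing ADC with a
#'   0.05 uA step.
#' @param loop a [loop_spec()]; `NULL` builds one from the electrode with
#'   tissue spreading resistance and an ideal ZRA (`Rshunt = 0`).
#' @param site electrode site on the phantom.
#' @param include character vector of components to generate (subset of
#'   `"corrosion"`, `"ecg"`, `"emg"`, `"johnson"`, `"amplifier"`,
#'   `"mains"`).
#' @param decompose if `TRUE`, return a long tibble with the resampled
#'   per-component currents (unquantized) alongside the quantized total.
#' @param .gains precomputed transfer gains from `precompute_loop_gains()`;
#'   used internally by the Monte-Carlo drivers to share gain evaluations
#'   across realizations of the same configuration.
#' @return a current [zra_trace()] at the ADC output rate, with the
#'   configuration echoed in attributes `seed` and `icorr`; or, with
#'   `decompose = TRUE`, a long tibble `time, component, current`.
#' @export
assemble_measurement <- function(electrode, duration = 30, seed = 1,
                                 corrosion = corrosion_config(),
                                 bio = bio_config(),
                                 phantom = mouse_phantom(),
                                 instrument = instrument_spec(),
                                 adc = adc_spec(10),
                                 loop = NULL, site = "femoral",
                                 include = c("corrosion", "ecg", "emg",
                                             "johnson", "amplifier", "mains"),
                                 decompose = FALSE, .gains = NULL) {
  if (is.null(loop)) loop <- loop_spec(electrode)
  fs <- instrument$fs_internal
  if (fs < 2 * adc$fs_out) abort("`fs_internal` must be at least 2 * fs_out.")
  n <- as.integer(round(duration * fs))
  gains <- .gains %||% precompute_loop_gains(loop, n, fs, instrument)

  ## raw sources that pass through a frequency-domain transfer path,
  ## grouped under the component name they are reported as
  src <- list(); sgain <- list(); scomp <- character()
  if ("corrosion" %in% include) {
    zc <- electrode_current(electrode, corrosion, duration, fs, seed)
    for (zn in unique(zc$zone)) {
      src[[length(src) + 1]] <- zc$current[zc$zone == zn]
      sgain[[length(sgain) + 1]] <- gains[[paste0("corrosion_", zn)]]
      scomp <- c(scomp, "corrosion")
    }
  }
  if (!is.null(bio)) {
    if ("ecg" %in% include && bio$ecg_surface_amp > 0) {
      v_ecg <- ecg_pair_voltage(phantom, bio, duration, fs,
                                substream_seed(seed, "ecg"), site)
      src[[length(src) + 1]] <- trace_samples(v_ecg)
      sgain[[length(sgain) + 1]] <- gains$bio_voltage
      scomp <- c(scomp, "ecg")
    }
    if ("emg" %in% include && bio$emg_rate > 0) {
      ## amplitude convention: burst RMS = ECG pair voltage peak-to-peak / 4
      ## (bursts "comparable to ECG")
      amp_v <- bio$emg_amp %||% (ecg_pair_pkpk(phantom, bio, site) / 4)
      v_emg <- emg_bursts(bio, duration, fs, substream_seed(seed, "emg"), amp = amp_v)
      src[[length(src) + 1]] <- trace_samples(v_emg)
      sgain[[length(sgain) + 1]] <- gains$bio_voltage
      scomp <- c(scomp, "emg")
    }
  }
  if ("johnson" %in% include) {
    src[[length(src) + 1]] <- with_seed(substream_seed(seed, "johnson"), rnorm(n))
    sgain[[length(sgain) + 1]] <- gains$johnson
    scomp <- c(scomp, "johnson")
  }
  ## components added directly, without impedance filtering
  direct <- list()
  if ("amplifier" %in% include && instrument$amp_noise_rms > 0) {
    direct$amplifier <- with_seed(substream_seed(seed, "amp"),
                                  rnorm(n, sd = instrument$amp_noise_rms))
  }
  if ("mains" %in% include && !is.null(instrument$mains_freq) &&
      instrument$mains_amp > 0) {
    ph <- with_seed(substream_seed(seed, "mains"), runif(1, 0, 2 * pi))
    direct$mains <- instrument$mains_amp *
      sin(2 * pi * instrument$mains_freq * (seq_len(n) - 1) / fs + ph)
  }

  comps <- list()
  if (decompose) {
    for (i in seq_along(src)) {
      y <- apply_freq_gain(src[[i]], fs, sgain[[i]])
      comps[[scomp[i]]] <- if (is.null(comps[[scomp[i]]])) y else comps[[scomp[i]]] + y
    }
    for (nm in names(direct)) comps[[nm]] <- direct[[nm]]
    total <- rep(0, n)
    for (x in comps) total <- total + x
  } else {
    total <- if (length(src) > 0) apply_freq_gain_multi(src, sgain, fs) else rep(0, n)
    for (x in direct) total <- total + x
  }
  out_total <- quantize_trace(resample_trace(total, adc, fs_in = fs), adc$delta_lsb)

  if (!decompose) {
    res <- zra_trace(trace_samples(out_total), adc$fs_out, label = "measured")
    attr(res, "seed") <- seed
    zc <- zone_currents(electrode, corrosion)
    attr(res, "icorr") <- stats::setNames(zc$icorr, zc$zone)
    return(res)
  }
  t_out <- out_total$time
  rows <- list(tibble(time = t_out, component = "total",
                      current = trace_samples(out_total)))
  for (nm in names(comps)) {
    y <- resample_trace(comps[[nm]], adc, fs_in = fs)
    rows[[length(rows) + 1]] <- tibble(time = t_out, component = nm,
                                       current = trace_samples(y))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fs") <- adc$fs_out
  attr(out, "seed") <- seed
  out
}
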