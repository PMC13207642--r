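#' Factorial design for the coating-breach detection study
#'
#' The default grids reproduce the full study conditions: 11 breach
#' fractions from intact film to 50% degradation, five practical implant
#' areas, two sampling rates, 30 seeds of 30 s each — 3300 realizations —
#' with the worst-case chitosan-like coating (`Rf_sp` 100 Ohm cm^2).
#'
#' @param theta_grid breach fractions.
#' @param area_grid electrode areas, cm^2.
#' @param fs_grid ADC output rates, Hz.
#' @param n_seeds Monte-Carlo realizations per (area, theta, fs) cell.
#' @param duration recording length, s.
#' @param Rf_sp,Cf_sp coating parameters (Ohm cm^2, F/cm^2).
#' @param Rct_sp,Cdl_sp interface parameters (Ohm cm^2, F/cm^2).
#' @return an object of class `zra_design`.
#' @export
factorial_design <- function(theta_grid = c(0, 0.01, 0.02, 0.05, 0.08, 0.10,
                                            0.15, 0.20, 0.30, 0.40, 0.50),
                             area_grid = c(0.05, 0.10, 0.20, 0.50, 1.0),
                             fs_grid = c(10, 100),
                             n_seeds = 30, duration = 30,
                             Rf_sp = 100, Cf_sp = 800e-6,
                             Rct_sp = 300, Cdl_sp = 25e-6) {
  if (length(theta_grid) == 0 || length(area_grid) == 0 || length(fs_grid) == 0) {
    abort("all design grids must be non-empty.")
  }
  if (n_seeds < 2) abort("`n_seeds` must be at least 2.")
  structure(list(theta_grid = theta_grid, area_grid = area_grid,
                 fs_grid = fs_grid, n_seeds = n_seeds, duration = duration,
                 Rf_sp = Rf_sp, Cf_sp = Cf_sp,
                 Rct_sp = Rct_sp, Cdl_sp = Cdl_sp),
            class = "zra_design")
}

#' Number of realizations a design enumerates
#' @param design a [factorial_design()].
#' @return integer count `|areas| x |thetas| x |fs| x n_seeds`.
#' @export
n_realizations <- function(design) {
  length(design$area_grid) * length(design$theta_grid) *
    length(design$fs_grid) * design$n_seeds
}

#' @export
print.zra_design <- function(x, ...) {
  cat(sprintf(paste0("<zra_design> %d areas x %d thetas x %d rates x %d seeds",
                     " = %d realizations of %g s\n"),
              length(x$area_grid), length(x$theta_grid), length(x$fs_grid),
              x$n_seeds, n_realizations(x), x$duration))
  invisible(x)
}

## Enumerate the design as a tibble of conditions with per-realization seeds
## derived from the master seed, so any subset of the grid reproduces the
## identical realizations as the full grid.
design_conditions <- function(design, master_seed) {
  g <- tidyr::expand_grid(area = design$area_grid, theta = design$theta_grid,
                          fs = design$fs_grid, seed_idx = seq_len(design$n_seeds))
  g$seed <- purrr::pmap_int(g, function(area, theta, fs, seed_idx) {
    hash_seed(master_seed, area, theta, fs, seed_idx)
  })
  g
}

## Simulate one realization and return the four metrics (in uA). The
## electrode/loop/gain objects are shared across the seeds of one
## configuration through `ctx`.
realize_metrics <- function(ctx, fs, seed,
                            metrics = c("rms", "ma_rms", "resid_rms", "cheb_power"),
                            duration = 30) {
  tr <- assemble_measurement(ctx$spec, duration = duration, seed = seed,
                             adc = adc_spec(fs), loop = ctx$loop,
                             .gains = ctx$gains)
  signal_metrics(trace_samples(tr) * 1e6, kinds = metrics, fs = fs)
}

config_context <- function(area, theta, design, instrument = instrument_spec()) {
  spec <- electrode_spec(area, Rct_sp = design$Rct_sp, Cdl_sp = design$Cdl_sp,
                         Rf_sp = design$Rf_sp, Cf_sp = design$Cf_sp,
                         theta = theta)
  loop <- loop_spec(spec)
  n <- as.integer(round(design$duration * instrument$fs_internal))
  list(spec = spec, loop = loop,
       gains = precompute_loop_gains(loop, n, instrument$fs_internal, instrument))
}

#' Run the coating-breach factorial study
#'
#' For every (area, theta, fs, seed) cell, simulates one full-model
#' recording through [assemble_measurement()] (two-zone impedance model,
#' all interference and instrument sources, anti-aliasing ADC), computes
#' the four detection metrics in microamperes, fits the sensitivity
#' regression per (area, fs, metric), and evaluates the detection threshold
#' `theta_det(N)`.
#'
#' @param design a [factorial_design()].
#' @param master_seed integer master seed; every realization derives its own
#'   seed from it deterministically.
#' @param metrics metric kinds to compute.
#' @param N_detect recording counts at which to tabulate the threshold.
#' @param progress print progress every completed condition block.
#' @return an object of class `zra_breach_study`: list with `realizations`
#'   (long tibble `area, fs, theta, seed_idx, metric, value`), `summary`
#'   (per-configuration `b1, sigma, nsr, theta_det_*`), `design`,
#'   `master_seed` and `failures`.
#' @export
run_breach_factorial <- function(design = factorial_design(), master_seed = 1,
                                 metrics = c("rms", "ma_rms", "resid_rms", "cheb_power"),
                                 N_detect = c(10, 30, 100), progress = FALSE) {
  conds <- design_conditions(design, master_seed)
  rows <- vector("list", nrow(conds))
  failures <- list()
  ctx <- NULL; ctx_key <- ""
  for (i in seq_len(nrow(conds))) {
    ci <- conds[i, ]
    key <- paste(ci$area, ci$theta)
    if (key != ctx_key) {
      ctx <- config_context(ci$area, ci$theta, design)
      ctx_key <- key
    }
    res <- tryCatch(
      realize_metrics(ctx, ci$fs, ci$seed, metrics, design$duration),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble(
        area = ci$area, theta = ci$theta, fs = ci$fs, seed_idx = ci$seed_idx,
        message = conditionMessage(res))
      next
    }
    rows[[i]] <- tibble(area = ci$area, fs = ci$fs, theta = ci$theta,
                        seed_idx = ci$seed_idx, metric = res$metric,
                        value = res$value)
    if (progress && i %% 50 == 0) {
      message(sprintf("  realization %d / %d", i, nrow(conds)))
    }
  }
  realizations <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(failures)
  if (nrow(failures) > 0) {
    rlang::warn(sprintf("%d realization(s) failed; see $failures.", nrow(failures)))
  }
  summary <- summarize_breach_study(realizations, N_detect)
  structure(list(realizations = realizations, summary = summary,
                 design = design, master_seed = master_seed,
                 failures = failures),
            class = "zra_breach_study")
}

summarize_breach_study <- function(realizations, N_detect = c(10, 30, 100)) {
  realizations |>
    dplyr::group_by(.data$area, .data$fs, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      fit <- tryCatch(fit_sensitivity(theta = d$theta, value = d$value),
                      error = function(e) NULL)
      out <- if (is.null(fit)) {
        tibble(b1 = NA_real_, intercept = NA_real_, sigma = NA_real_,
               nsr = NA_real_, n_points = nrow(d), r.squared = NA_real_)
      } else glance(fit)
      for (N in N_detect) {
        out[[paste0("theta_det_", N)]] <- if (!is.null(fit) &&
                                              is.finite(fit$nsr) && fit$b1 > 0) {
          theta_det(fit, N)
        } else NA_real_
      }
      out
    }) |>
    dplyr::ungroup()
}

#' @export
print.zra_breach_study <- function(x, ...) {
  cat(sprintf("<zra_breach_study> %d realizations, master seed %d\n",
              nrow(x$realizations) / max(1, length(unique(x$realizations$metric))),
              x$master_seed))
  print(x$summary, n = 20)
  invisible(x)
}

#' @export
tidy.zra_breach_study <- function(x, ...) x$summary

#' Operating-window (SNR phase diagram) study
#'
#' For each (electrode area, coating resistance) cell, simulates the
#' corrosion loop current of the intact electrode at the internal rate and
#' compares its RMS against the ECG-induced loop current and the amplifier
#' noise floor:
#' `SNR = median corrosion RMS / max(ECG RMS, amplifier floor)`.
#' EMG is excluded: the window is evaluated for a restrained (anesthetized)
#' animal, where the cardiac rhythm is the irreducible background.
#' `Rf_sp = 0` rows model the bare, uncoated electrode.
#'
#' @param area_grid electrode areas, cm^2.
#' @param rf_grid area-specific coating resistances, Ohm cm^2 (0 = bare).
#' @param n_real stochastic realizations per cell.
#' @param duration realization length, s.
#' @param master_seed integer master seed.
#' @param instrument an [instrument_spec()] (supplies the internal rate and
#'   the amplifier floor).
#' @param bio a [bio_config()]; `phantom` a [mouse_phantom()].
#' @param phantom anatomical phantom.
#' @param corrosion a [corrosion_config()].
#' @return a tibble of class `zra_window_study` with columns `area`,
#'   `rf_sp`, `corr_rms` (A), `ecg_rms` (A), `snr`, `log10_snr`.
#' @export
run_operating_window <- function(area_grid = 10^seq(-2.5, 0, length.out = 6),
                                 rf_grid = c(0, 35, 100, 300, 1000, 3000, 5000),
                                 n_real = 15, duration = 10, master_seed = 1,
                                 instrument = instrument_spec(),
                                 bio = bio_config(), phantom = mouse_phantom(),
                                 corrosion = corrosion_config()) {
  fs <- instrument$fs_internal
  cells <- tidyr::expand_grid(area = area_grid, rf_sp = rf_grid)
  out <- purrr::pmap(cells, function(area, rf_sp) {
    spec <- if (rf_sp > 0) {
      electrode_spec(area, Rf_sp = rf_sp, Cf_sp = 800e-6, theta = 0)
    } else {
      electrode_spec(area, Rf_sp = NULL, Cf_sp = NULL, theta = 0)
    }
    loop <- loop_spec(spec)
    paths <- transfer_paths(loop)
    zone <- names(electrode_zones(spec))[1]
    gain <- paths[[paste0("corrosion_", zone)]]
    rmss <- vapply(seq_len(n_real), function(i) {
      sd0 <- hash_seed(master_seed, area, rf_sp, i)
      zc <- electrode_current(spec, corrosion, duration, fs, sd0)
      x <- apply_freq_gain(zc$current, fs, gain)
      sqrt(mean((x - mean(x))^2))
    }, 0)
    v <- ecg_pair_voltage(phantom, bio, duration, fs,
                          substream_seed(hash_seed(master_seed, area, rf_sp, 0), "ecg"))
    iecg <- trace_samples(bio_to_loop_current(v, loop))
    ecg_rms <- sqrt(mean((iecg - mean(iecg))^2))
    corr_rms <- stats::median(rmss)
    snr <- corr_rms / max(ecg_rms, instrument$amp_noise_rms)
    tibble(area = area, rf_sp = rf_sp, corr_rms = corr_rms,
           ecg_rms = ecg_rms, snr = snr, log10_snr = log10(snr))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("zra_window_study", class(out))
  attr(out, "master_seed") <- master_seed
  out
}

#' Coating-resistance sweep of the detection threshold
#'
#' Detection threshold `theta_det(N)` for the residual-RMS metric as a
#' function of the area-specific coating resistance and electrode area:
#' for each (Rf_sp, area) pair the full breach factorial is run over the
#' theta grid and the threshold evaluated at `N` recordings.
#'
#' @param rf_grid coating resistances, Ohm cm^2.
#' @param area_grid electrode areas, cm^2.
#' @param n_seeds realizations per (theta) cell.
#' @param N recording count for the threshold.
#' @param fs ADC output rate, Hz.
#' @param duration recording length, s.
#' @param master_seed integer master seed.
#' @param metric metric used for detection (residual RMS by default).
#' @param theta_grid breach-fraction grid for the sensitivity fit.
#' @param progress print progress per cell.
#' @return tibble with columns `rf_sp`, `area`, `b1`, `sigma`, `nsr`,
#'   `theta_det` (fraction) and `theta_det_pct` (%).
#' @export
rf_threshold_sweep <- function(rf_grid, area_grid, n_seeds = 30, N = 30,
                               fs = 10, duration = 30, master_seed = 1,
                               metric = "resid_rms",
                               theta_grid = c(0, 0.01, 0.02, 0.05, 0.08, 0.10,
                                              0.15, 0.20, 0.30, 0.40, 0.50),
                               progress = FALSE) {
  cells <- tidyr::expand_grid(rf_sp = rf_grid, area = area_grid)
  out <- purrr::pmap(cells, function(rf_sp, area) {
    design <- factorial_design(theta_grid = theta_grid, area_grid = area,
                               fs_grid = fs, n_seeds = n_seeds,
                               duration = duration, Rf_sp = rf_sp)
    st <- run_breach_factorial(design, master_seed, metrics = metric,
                               N_detect = N)
    s <- st$summary
    if (progress) message(sprintf("  rf_sp = %g, area = %g done", rf_sp, area))
    tibble(rf_sp = rf_sp, area = area, b1 = s$b1, sigma = s$sigma,
           nsr = s$nsr, theta_det = s[[paste0("theta_det_", N)]],
           theta_det_pct = 100 * s[[paste0("theta_det_", N)]])
  })
  dplyr::bind_rows(out)
}
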