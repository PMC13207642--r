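#' Run configuration files
#'
#' Simulations can be described by a YAML document with sections
#' `electrode`, `coating`, `corrosion`, `phantom`, `bio`, `instrument`,
#' `adc` and `study`, plus a `master_seed` and an `output_dir`. External
#' units follow bench conventions — cm^2, Ohm cm^2, uF/cm^2, uA, Hz,
#' seconds — and are converted to SI at this boundary. Absent keys take the
#' documented defaults; unknown keys and out-of-range values are rejected
#' with the offending key named.
#'
#' @param path file path.
#' @return `load_config()` / `default_config()`: a validated nested list of
#'   class `zra_config`. `save_config()` writes YAML and returns `path`
#'   invisibly.
#' @export
default_config <- function() {
  cfg <- list(
    master_seed = 1L,
    output_dir = ".",
    electrode = list(area = 0.5, Rct_sp = 300, Cdl_sp_uF = 25, theta = 0.1),
    coating = list(enabled = TRUE, Rf_sp = 100, Cf_sp_uF = 800),
    corrosion = list(B = 0.03, pitting_fraction = 0.10, r_bub_um = 20,
                     tau_pulse_ms = 7.5, corner_f = 0.1,
                     temperature = 310, pressure = 1),
    phantom = list(conductivity = 1.0, site = "femoral"),
    bio = list(enabled = TRUE, heart_rate = 400, ecg_surface_amp_mV = 1.5,
               emg_rate = 0.3, emg_burst_duration = 0.5),
    instrument = list(amp_noise_rms_uA = 0.05, mains_freq = 0, mains_amp_uA = 0,
                      temperature = 310, fs_internal = 10000),
    adc = list(fs_out = 10, delta_lsb_uA = 0.05, strategy = "antialias_decimate"),
    study = list(duration = 30, n_seeds = 30)
  )
  class(cfg) <- "zra_config"
  cfg
}

.range_rules <- list(
  "electrode.area" = c(1e-6, Inf), "electrode.Rct_sp" = c(1e-9, Inf),
  "electrode.Cdl_sp_uF" = c(1e-9, Inf), "electrode.theta" = c(0, 1),
  "coating.Rf_sp" = c(0, Inf), "coating.Cf_sp_uF" = c(1e-9, Inf),
  "corrosion.B" = c(1e-9, Inf), "corrosion.pitting_fraction" = c(1e-9, 1),
  "corrosion.r_bub_um" = c(1e-3, Inf), "corrosion.tau_pulse_ms" = c(1e-6, Inf),
  "corrosion.corner_f" = c(1e-9, Inf), "corrosion.temperature" = c(1, Inf),
  "corrosion.pressure" = c(1e-3, Inf),
  "phantom.conductivity" = c(1e-9, Inf),
  "bio.heart_rate" = c(300, 600), "bio.ecg_surface_amp_mV" = c(0, Inf),
  "bio.emg_rate" = c(0, Inf), "bio.emg_burst_duration" = c(1e-6, Inf),
  "instrument.amp_noise_rms_uA" = c(0, Inf), "instrument.mains_amp_uA" = c(0, Inf),
  "instrument.temperature" = c(1, Inf), "instrument.fs_internal" = c(1, Inf),
  "adc.fs_out" = c(1e-6, Inf), "adc.delta_lsb_uA" = c(0, Inf),
  "study.duration" = c(0.1, Inf), "study.n_seeds" = c(1, Inf)
)

#' @rdname default_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) abort(paste0("unknown config section: ", sec))
    if (!is.list(cfg[[sec]])) { cfg[[sec]] <- user[[sec]]; next }
    if (!is.list(user[[sec]])) abort(paste0("section `", sec, "` must be a mapping."))
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]])) {
        abort(paste0("unknown config key: ", sec, ".", key))
      }
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  validate_config(cfg)
  class(cfg) <- "zra_config"
  cfg
}

validate_config <- function(cfg) {
  for (nm in names(.range_rules)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    rng <- .range_rules[[nm]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) ||
        val < rng[1] || val > rng[2]) {
      bound <- if (is.finite(rng[2])) {
        sprintf("must lie in [%g, %g]", rng[1], rng[2])
      } else if (rng[1] > 0) "must be > 0" else "must be >= 0"
      abort(paste0("`", nm, "` ", bound, "."))
    }
  }
  if (!cfg$adc$strategy %in% c("antialias_decimate", "sinc", "naive_subsample")) {
    abort("`adc.strategy` must be one of antialias_decimate, sinc, naive_subsample.")
  }
  if (!cfg$instrument$mains_freq %in% c(0, 50, 60)) {
    abort("`instrument.mains_freq` must be 0 (off), 50 or 60.")
  }
  invisible(cfg)
}

#' @rdname default_config
#' @param cfg a `zra_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## Build simulation objects from a validated config (external units -> SI).
config_objects <- function(cfg) {
  el <- cfg$electrode; co <- cfg$coating
  spec <- if (isTRUE(co$enabled)) {
    electrode_spec(el$area, el$Rct_sp, el$Cdl_sp_uF * 1e-6,
                   Rf_sp = co$Rf_sp, Cf_sp = co$Cf_sp_uF * 1e-6,
                   theta = el$theta)
  } else {
    electrode_spec(el$area, el$Rct_sp, el$Cdl_sp_uF * 1e-6,
                   Rf_sp = NULL, Cf_sp = NULL, theta = 0)
  }
  corr <- corrosion_config(B = cfg$corrosion$B,
                           pitting_fraction = cfg$corrosion$pitting_fraction,
                           r_bub = cfg$corrosion$r_bub_um * 1e-6,
                           tau_pulse = cfg$corrosion$tau_pulse_ms * 1e-3,
                           corner_f = cfg$corrosion$corner_f,
                           temperature = cfg$corrosion$temperature,
                           pressure = cfg$corrosion$pressure)
  bio <- if (isTRUE(cfg$bio$enabled)) {
    bio_config(heart_rate = cfg$bio$heart_rate,
               ecg_surface_amp = cfg$bio$ecg_surface_amp_mV * 1e-3,
               emg_rate = cfg$bio$emg_rate,
               emg_burst_duration = cfg$bio$emg_burst_duration)
  } else NULL
  inst <- instrument_spec(amp_noise_rms = cfg$instrument$amp_noise_rms_uA * 1e-6,
                          mains_freq = if (cfg$instrument$mains_freq > 0)
                            cfg$instrument$mains_freq else NULL,
                          mains_amp = cfg$instrument$mains_amp_uA * 1e-6,
                          temperature = cfg$instrument$temperature,
                          fs_internal = cfg$instrument$fs_internal)
  adc <- adc_spec(cfg$adc$fs_out, cfg$adc$delta_lsb_uA * 1e-6, cfg$adc$strategy)
  phantom <- mouse_phantom(cfg$phantom$conductivity)
  list(electrode = spec, corrosion = corr, bio = bio, instrument = inst,
       adc = adc, phantom = phantom, site = cfg$phantom$site,
       duration = cfg$study$duration, seed = cfg$master_seed)
}
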