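#' Equivalent-circuit elements and composition
#'
#' Circuits are algebraic trees of standard electrochemical impedance
#' elements — resistor, capacitor, constant phase element (CPE), Warburg
#' diffusion element and inductor — combined in series or parallel.
#' [ckt_impedance()] evaluates the complex impedance of a tree at arbitrary
#' frequencies.
#'
#' Element laws: \eqn{Z_R = R}, \eqn{Z_C = 1/(j 2\pi f C)},
#' \eqn{Z_{CPE} = 1/(Q (j 2\pi f)^n)}, \eqn{Z_W = \sigma_w (1-j)/\sqrt{2\pi f}},
#' \eqn{Z_L = j 2\pi f L}. Series composition sums impedances; parallel
#' composition sums admittances.
#'
#' @param R resistance, Ohm.
#' @param C capacitance, F.
#' @param Q CPE coefficient, S s^n.
#' @param n CPE exponent in (0, 1]; `n = 1` is an ideal capacitor with
#'   `C = Q`.
#' @param sigma_w Warburg coefficient, Ohm s^-1/2.
#' @param L inductance, H.
#' @param ... child nodes for `ckt_series()` / `ckt_parallel()`.
#' @return an object of class `zra_circuit`.
#' @examples
#' ze <- ckt_series(ckt_parallel(ckt_resistor(100), ckt_capacitor(8e-4)),
#'                  ckt_parallel(ckt_resistor(300), ckt_capacitor(25e-6)))
#' ckt_impedance(ze, c(0.1, 1, 10, 100))
#' @name circuit
NULL

new_ckt <- function(kind, params = list(), children = list()) {
  structure(list(kind = kind, params = params, children = children),
            class = "zra_circuit")
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(paste0("circuit parameter `", name, "` must be a positive number."))
  }
  x
}

#' @rdname circuit
#' @export
ckt_resistor <- function(R) new_ckt("resistor", list(R = .check_pos(R, "R")))

#' @rdname circuit
#' @export
ckt_capacitor <- function(C) new_ckt("capacitor", list(C = .check_pos(C, "C")))

#' @rdname circuit
#' @export
ckt_cpe <- function(Q, n) {
  .check_pos(Q, "Q")
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n > 1) {
    abort("CPE exponent `n` must lie in (0, 1].")
  }
  new_ckt("cpe", list(Q = Q, n = n))
}

#' @rdname circuit
#' @export
ckt_warburg <- function(sigma_w) {
  new_ckt("warburg", list(sigma_w = .check_pos(sigma_w, "sigma_w")))
}

#' @rdname circuit
#' @export
ckt_inductor <- function(L) new_ckt("inductor", list(L = .check_pos(L, "L")))

collect_children <- function(...) {
  ch <- list(...)
  if (length(ch) == 0) abort("series/parallel composition needs at least one child.")
  for (c in ch) if (!inherits(c, "zra_circuit")) {
    abort("all children of a composition must be circuit nodes.")
  }
  ch
}

#' @rdname circuit
#' @export
ckt_series <- function(...) new_ckt("series", children = collect_children(...))

#' @rdname circuit
#' @export
ckt_parallel <- function(...) new_ckt("parallel", children = collect_children(...))

#' @export
print.zra_circuit <- function(x, ...) {
  fmt <- function(node) {
    switch(node$kind,
      resistor  = sprintf("R(%g)", node$params$R),
      capacitor = sprintf("C(%g)", node$params$C),
      cpe       = sprintf("CPE(Q=%g, n=%g)", node$params$Q, node$params$n),
      warburg   = sprintf("W(%g)", node$params$sigma_w),
      inductor  = sprintf("L(%g)", node$params$L),
      series    = paste0("(", paste(vapply(node$children, fmt, ""), collapse = " + "), ")"),
      parallel  = paste0("(", paste(vapply(node$children, fmt, ""), collapse = " || "), ")")
    )
  }
  cat("<zra_circuit> ", fmt(x), "\n", sep = "")
  invisible(x)
}

#' Complex impedance of a circuit tree
#'
#' @param node a `zra_circuit`.
#' @param f frequency or vector of frequencies, Hz. `f = 0` is allowed for
#'   trees whose DC limit is defined (resistors, inductors, ideal capacitors,
#'   `n = 1` CPEs); it is a domain error for CPEs with `n < 1` and Warburg
#'   elements, which are singular at DC.
#' @return complex impedance, Ohm (same length as `f`; may be `Inf` at DC for
#'   purely capacitive branches).
#' @export
ckt_impedance <- function(node, f) {
  if (!inherits(node, "zra_circuit")) abort("`node` must be a zra_circuit.")
  if (!is.numeric(f) || any(f < 0)) abort("frequencies must be >= 0.")
  zimp(node, f)
}

zimp <- function(node, f) {
  switch(node$kind,
    resistor  = rep(complex(real = node$params$R), length(f)),
    capacitor = {
      z <- complex(real = rep(Inf, length(f)))
      nz <- f > 0
      z[nz] <- 1 / (2i * pi * f[nz] * node$params$C)
      z
    },
    cpe = {
      if (node$params$n < 1 && any(f == 0)) {
        abort("a CPE with n < 1 is singular at f = 0.")
      }
      z <- complex(real = rep(Inf, length(f)))
      nz <- f > 0
      z[nz] <- 1 / (node$params$Q * (2i * pi * f[nz])^node$params$n)
      z
    },
    warburg = {
      if (any(f == 0)) abort("a Warburg element is singular at f = 0.")
      node$params$sigma_w * (1 - 1i) / sqrt(2 * pi * f)
    },
    inductor = complex(imaginary = 2 * pi * f * node$params$L),
    series   = {
      z <- complex(real = rep(0, length(f)))
      for (ch in node$children) z <- z + zimp(ch, f)
      z
    },
    parallel = {
      y <- complex(real = rep(0, length(f)))
      for (ch in node$children) {
        zc <- zimp(ch, f)
        yc <- 1 / zc
        yc[is.infinite(Re(zc)) | is.infinite(Im(zc))] <- 0
        y <- y + yc
      }
      z <- 1 / y
      z[Mod(y) == 0] <- complex(real = Inf)
      z
    },
    abort(paste0("unknown circuit node kind '", node$kind, "'"))
  )
}

## ---- electrode, loop, transfer paths -------------------------------------

#' Electrode interface specification (two-zone coating-breach model)
#'
#' Describes one implant electrode by its total area, area-specific
#' metal/electrolyte interface parameters, optional coating-film parameters,
#' and the coating breach fraction `theta`. A breached electrode is modelled
#' as two parallel zones: a coated zone of area `A (1 - theta)` whose
#' impedance is the film (Rf || Cf) in series with the interface
#' (Rct || Cdl), and a bare zone of area `A theta` carrying only the
#' interface impedance. Area-specific parameters are converted to absolute
#' element values by the zone area (R = Rsp / area, C = Csp * area).
#'
#' Defaults are the AZ91-in-SBF early-exposure values used throughout the
#' Monte-Carlo studies: `Rct_sp` 300 Ohm cm^2, `Cdl_sp` 25 uF/cm^2, coating
#' `Rf_sp` 100 Ohm cm^2, `Cf_sp` 800 uF/cm^2 (a deliberately weak,
#' hydrogel-like worst case). Interface and film capacitances are ideal
#' (CPE exponent 1) by default; set `n_dl` / `n_f` below 1 for distributed
#' relaxation.
#'
#' @param area electrode area, cm^2.
#' @param Rct_sp area-specific charge-transfer resistance, Ohm cm^2.
#' @param Cdl_sp area-specific double-layer capacitance, F/cm^2.
#' @param Rf_sp,Cf_sp area-specific coating film resistance (Ohm cm^2) and
#'   capacitance (F/cm^2); both present or both `NULL` (uncoated).
#' @param theta coating breach fraction in `[0, 1]`.
#' @param n_dl,n_f CPE exponents for the double layer and film (1 = ideal).
#' @return an object of class `zra_electrode`.
#' @export
electrode_spec <- function(area, Rct_sp = 300, Cdl_sp = 25e-6,
                           Rf_sp = 100, Cf_sp = 800e-6, theta = 0,
                           n_dl = 1, n_f = 1) {
  .check_pos(area, "area"); .check_pos(Rct_sp, "Rct_sp"); .check_pos(Cdl_sp, "Cdl_sp")
  coated <- !is.null(Rf_sp) || !is.null(Cf_sp)
  if (coated && (is.null(Rf_sp) || is.null(Cf_sp))) {
    abort("coating parameters `Rf_sp` and `Cf_sp` must be given together.")
  }
  if (coated) { .check_pos(Rf_sp, "Rf_sp"); .check_pos(Cf_sp, "Cf_sp") }
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1) {
    abort("`theta` must be a breach fraction in [0, 1].")
  }
  if (!coated && theta > 0) {
    abort("`theta` > 0 requires coating parameters (`Rf_sp`, `Cf_sp`).")
  }
  structure(list(area = area, Rct_sp = Rct_sp, Cdl_sp = Cdl_sp,
                 Rf_sp = if (coated) Rf_sp else NULL,
                 Cf_sp = if (coated) Cf_sp else NULL,
                 theta = theta, n_dl = n_dl, n_f = n_f, coated = coated),
            class = "zra_electrode")
}

#' @export
print.zra_electrode <- function(x, ...) {
  cat(sprintf("<zra_electrode> A = %g cm^2, Rct_sp = %g Ohm cm^2, Cdl_sp = %g F/cm^2\n",
              x$area, x$Rct_sp, x$Cdl_sp))
  if (x$coated) {
    cat(sprintf("  coating: Rf_sp = %g Ohm cm^2, Cf_sp = %g F/cm^2, breach theta = %g\n",
                x$Rf_sp, x$Cf_sp, x$theta))
  } else cat("  uncoated\n")
  invisible(x)
}

cap_element <- function(C, n) if (n >= 1) ckt_capacitor(C) else ckt_cpe(C, n)

interface_circuit <- function(spec, zone_area) {
  ckt_parallel(ckt_resistor(spec$Rct_sp / zone_area),
               cap_element(spec$Cdl_sp * zone_area, spec$n_dl))
}

coated_zone_circuit <- function(spec, zone_area) {
  ckt_series(ckt_parallel(ckt_resistor(spec$Rf_sp / zone_area),
                          cap_element(spec$Cf_sp * zone_area, spec$n_f)),
             interface_circuit(spec, zone_area))
}

## Zone areas and circuits; empty zones are dropped.
electrode_zones <- function(spec) {
  zones <- list()
  if (!spec$coated || spec$theta == 1) {
    zones$bare <- list(area = spec$area,
                       circuit = interface_circuit(spec, spec$area))
  } else if (spec$theta == 0) {
    zones$coated <- list(area = spec$area,
                         circuit = coated_zone_circuit(spec, spec$area))
  } else {
    zones$coated <- list(area = spec$area * (1 - spec$theta),
                         circuit = coated_zone_circuit(spec, spec$area * (1 - spec$theta)))
    zones$bare <- list(area = spec$area * spec$theta,
                       circuit = interface_circuit(spec, spec$area * spec$theta))
  }
  zones
}

#' Electrode impedance
#'
#' Complex impedance of a (possibly breached) electrode: the parallel
#' combination of the coated- and bare-zone impedances.
#'
#' @param spec a [electrode_spec()].
#' @param f frequency vector, Hz.
#' @return complex impedance, Ohm.
#' @export
electrode_impedance <- function(spec, f) {
  zones <- electrode_zones(spec)
  if (length(zones) == 1) return(ckt_impedance(zones[[1]]$circuit, f))
  ckt_impedance(do.call(ckt_parallel, lapply(zones, `[[`, "circuit")), f)
}

#' Measurement loop
#'
#' The symmetric two-electrode ZRA loop: electrolyte spreading resistance
#' `Rs`, two identical electrodes, and the ammeter input resistance
#' `Rshunt`. The loop impedance is `Zloop(f) = Rs + 2 Ze(f) + Rshunt`.
#' When `Rs = NULL` it is estimated from tissue resistivity and electrode
#' geometry as twice the per-electrode disk spreading resistance
#' [spreading_resistance()].
#'
#' @param electrode a [electrode_spec()] (symmetric pair).
#' @param Rs electrolyte spreading resistance of the whole loop, Ohm;
#'   `NULL` to estimate from `resistivity`.
#' @param Rshunt ZRA input resistance, Ohm (0 = ideal ZRA).
#' @param resistivity tissue resistivity, Ohm cm (100 Ohm cm is a
#'   conductivity of 1 S/m).
#' @return an object of class `zra_loop`.
#' @export
loop_spec <- function(electrode, Rs = NULL, Rshunt = 0, resistivity = 100) {
  if (!inherits(electrode, "zra_electrode")) abort("`electrode` must be an electrode_spec().")
  if (is.null(Rs)) Rs <- 2 * spreading_resistance(electrode$area, resistivity)
  if (!is.numeric(Rs) || Rs < 0) abort("`Rs` must be >= 0.")
  if (!is.numeric(Rshunt) || Rshunt < 0) abort("`Rshunt` must be >= 0.")
  structure(list(electrode = electrode, Rs = Rs, Rshunt = Rshunt),
            class = "zra_loop")
}

#' Loop impedance
#' @param loop a [loop_spec()].
#' @param f frequency vector, Hz.
#' @return complex impedance `Rs + 2 Ze(f) + Rshunt`, Ohm.
#' @export
loop_impedance <- function(loop, f) {
  if (!inherits(loop, "zra_loop")) abort("`loop` must be a loop_spec().")
  loop$Rs + 2 * electrode_impedance(loop$electrode, f) + loop$Rshunt
}

#' Disk-electrode spreading resistance
#'
#' Per-electrode constriction resistance of a disk of the same area in a
#' half-space of the given resistivity, `rho / (4 r)` with
#' `r = sqrt(A / pi)`. The loop sees twice this value (two electrodes).
#'
#' @param area electrode area, cm^2.
#' @param resistivity medium resistivity, Ohm cm.
#' @return resistance in Ohm (per electrode).
#' @export
spreading_resistance <- function(area, resistivity = 100) {
  .check_pos(area, "area")
  if (!is.numeric(resistivity) || resistivity < 0) abort("`resistivity` must be >= 0.")
  resistivity / (4 * sqrt(area / pi))
}

#' Per-source transfer paths through the measurement loop
#'
#' Each signal source sees a different transfer path through the loop
#' circuit. Bioelectric voltage sources are converted to loop current via
#' `1/Zloop(f)`. A corrosion noise current source in zone *i* of the working
#' electrode sits in parallel with its own zone impedance; the other zone and
#' the external branch (`Rs + Rshunt` plus the counter-electrode impedance)
#' complete the circuit, so the fraction of source current reaching the
#' ammeter follows from nodal analysis:
#' \deqn{G_i(f) = \frac{Y_{ext}}{Y_{bare} + Y_{coated} + Y_{ext}},\qquad
#'       Y_{ext} = \frac{1}{R_s + R_{shunt} + Z_e(f)}.}
#' For a single-zone electrode this reduces exactly to `Ze/Zloop`.
#'
#' @param loop a [loop_spec()].
#' @return a named list of vectorised gain functions of frequency:
#'   `bio_voltage` (1/Ohm) and one dimensionless `corrosion_<zone>` entry per
#'   populated zone.
#' @export
transfer_paths <- function(loop) {
  if (!inherits(loop, "zra_loop")) abort("`loop` must be a loop_spec().")
  spec <- loop$electrode
  zones <- electrode_zones(spec)
  paths <- list(bio_voltage = function(f) 1 / loop_impedance(loop, f))
  for (zn in names(zones)) {
    paths[[paste0("corrosion_", zn)]] <- local({
      zone_name <- zn
      function(f) {
        y_tot <- complex(real = rep(0, length(f)))
        for (z in zones) {
          zi <- ckt_impedance(z$circuit, f)
          yi <- 1 / zi
          yi[is.infinite(Mod(zi))] <- 0
          y_tot <- y_tot + yi
        }
        zext <- loop$Rs + loop$Rshunt + electrode_impedance(spec, f)
        yext <- 1 / zext
        yext / (y_tot + yext)
      }
    })
  }
  paths
}
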