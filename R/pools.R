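#' Two-pool spin system parameters
#'
#' Defines the water pool and a single exchanging solute pool (the glutamate
#' amine protons, resonating downfield of water) for Bloch-McConnell
#' simulation. Defaults are literature-informed 7T gray-matter values; the
#' solute fraction corresponds to 10 mM glutamate (3 amine protons against
#' the 111 M water proton pool).
#'
#' @param t1_water,t2_water Water longitudinal/transverse relaxation times (s).
#' @param t1_solute,t2_solute Solute relaxation times (s).
#' @param exchange_rate Solute-to-water proton exchange rate (1/s).
#' @param solute_fraction Solute proton population relative to water
#'   (dimensionless, in `[0, 0.1)`). See [glu_fraction()].
#' @param solute_shift Solute resonance offset from water (ppm, positive =
#'   downfield).
#' @return An object of class `pool_system`.
#' @seealso [glu_fraction()], [simulate_zspectrum()]
#' @export
pool_system <- function(t1_water = 1.8, t2_water = 0.04,
                        t1_solute = 1.0, t2_solute = 0.008,
                        exchange_rate = 5500,
                        solute_fraction = glu_fraction(10),
                        solute_shift = 3.0) {
  p <- list(t1_water = t1_water, t2_water = t2_water,
            t1_solute = t1_solute, t2_solute = t2_solute,
            exchange_rate = exchange_rate,
            solute_fraction = solute_fraction,
            solute_shift = solute_shift)
  validate_pool_system(p)
  structure(p, class = "pool_system")
}

validate_pool_system <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("t1_water", "t2_water", "t1_solute", "t2_solute")) {
    if (!num1(p[[f]]) || p[[f]] <= 0)
      stop("pool_system: '", f, "' must be a single positive number", call. = FALSE)
  }
  if (!num1(p$exchange_rate) || p$exchange_rate < 0)
    stop("pool_system: 'exchange_rate' must be >= 0", call. = FALSE)
  if (!num1(p$solute_fraction) || p$solute_fraction < 0 || p$solute_fraction >= 0.1)
    stop("pool_system: 'solute_fraction' must lie in [0, 0.1)", call. = FALSE)
  if (!num1(p$solute_shift))
    stop("pool_system: 'solute_shift' must be finite", call. = FALSE)
  invisible(p)
}

#' Solute proton fraction for a glutamate concentration
#'
#' Glutamate contributes three exchangeable amine protons per molecule;
#' water contributes 2 x 55,500 mM protons.
#'
#' @param glu_mM Glutamate concentration (mM). May be a vector.
#' @return Dimensionless proton-population ratio.
#' @export
glu_fraction <- function(glu_mM) {
  if (any(glu_mM < 0)) stop("glu_mM must be >= 0", call. = FALSE)
  3 * glu_mM / 111000
}

#' Saturation scheme
#'
#' RF saturation parameters for a z-spectrum acquisition. Saturation is
#' modeled as continuous-wave at `b1_rms` for `duration` seconds; when
#' `spoiling = TRUE` the block is split into `duration / pulse_length`
#' sub-pulses with ideal spoiling of transverse magnetization between them
#' (as vendor saturation modules do). High-duty-cycle trains are treated as
#' one CW block.
#'
#' @param b1_rms Root-mean-square saturation amplitude (microtesla).
#' @param duration Total saturation length (s).
#' @param pulse_length Sub-pulse length (s); with `spoiling = TRUE` it sets
#'   the spoiling interval.
#' @param duty_cycle RF duty cycle, in (0, 1].
#' @param field_strength Static field (T).
#' @param gyromagnetic_ratio Proton gyromagnetic ratio (Hz/T).
#' @param spoiling Spoil transverse magnetization between sub-pulses?
#' @return An object of class `saturation_scheme`.
#' @export
saturation_scheme <- function(b1_rms, duration, pulse_length = duration,
                              duty_cycle = 1, field_strength = 6.99,
                              gyromagnetic_ratio = 42.577e6,
                              spoiling = FALSE) {
  s <- list(b1_rms = b1_rms, duration = duration, pulse_length = pulse_length,
            duty_cycle = duty_cycle, field_strength = field_strength,
            gyromagnetic_ratio = gyromagnetic_ratio, spoiling = spoiling)
  validate_saturation_scheme(s)
  structure(s, class = "saturation_scheme")
}

validate_saturation_scheme <- function(s) {
  if (!is.numeric(s$b1_rms) || s$b1_rms < 0)
    stop("saturation_scheme: 'b1_rms' must be >= 0", call. = FALSE)
  if (s$duty_cycle <= 0 || s$duty_cycle > 1)
    stop("saturation_scheme: 'duty_cycle' must lie in (0, 1]", call. = FALSE)
  if (s$duration < s$pulse_length)
    stop("saturation_scheme: 'duration' must be >= 'pulse_length'", call. = FALSE)
  if (s$field_strength <= 0 || s$gyromagnetic_ratio <= 0)
    stop("saturation_scheme: field and gyromagnetic ratio must be > 0", call. = FALSE)
  invisible(s)
}

#' Default CEST saturation scheme (7T protocol)
#'
#' 3.06 uT RMS, 800 ms saturation (100 ms pulse train at 99% duty cycle,
#' modeled as continuous-wave).
#' @return A [saturation_scheme()].
#' @export
cest_scheme <- function() {
  saturation_scheme(b1_rms = 3.06, duration = 0.8, pulse_length = 0.1,
                    duty_cycle = 0.99, spoiling = FALSE)
}

#' Default WASSR saturation scheme
#'
#' 0.29 uT RMS, 200 ms, modeled as a train of 5 ms sub-pulses with
#' inter-pulse spoiling. Spoiling suppresses the coherent nutation ripples a
#' single near-resonance CW block would imprint on the dip, which real
#' multi-pulse saturation modules do not show.
#' @return A [saturation_scheme()].
#' @export
wassr_scheme <- function() {
  saturation_scheme(b1_rms = 0.29, duration = 0.2, pulse_length = 0.005,
                    duty_cycle = 1, spoiling = TRUE)
}

#' Hz per ppm for a saturation scheme
#' @param sat A [saturation_scheme()].
#' @return Scalar Hz/ppm conversion at the scheme's field strength.
#' @export
hz_per_ppm <- function(sat) {
  sat$gyromagnetic_ratio * sat$field_strength * 1e-6
}

#' @export
print.pool_system <- function(x, ...) {
  cat("Two-pool system (water + solute)\n")
  cat(sprintf("  water : T1 %.3g s, T2 %.3g s\n", x$t1_water, x$t2_water))
  cat(sprintf("  solute: T1 %.3g s, T2 %.3g s, shift %+.2f ppm\n",
              x$t1_solute, x$t2_solute, x$solute_shift))
  cat(sprintf("  exchange %.4g 1/s, fraction %.3g\n",
              x$exchange_rate, x$solute_fraction))
  invisible(x)
}

#' @export
print.saturation_scheme <- function(x, ...) {
  cat(sprintf("Saturation: %.3g uT RMS, %.3g s (%s), %.4g T\n",
              x$b1_rms, x$duration,
              if (x$spoiling) sprintf("spoiled %g ms sub-pulses", 1000 * x$pulse_length)
              else "continuous-wave",
              x$field_strength))
  invisible(x)
}
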