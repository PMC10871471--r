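#' Simulate a z-spectrum for a two-pool system
#'
#' Propagates the 6-state Bloch-McConnell system (transverse and longitudinal
#' magnetization of water and solute) under constant-amplitude saturation via
#' the matrix exponential of the constant generator, and returns the
#' normalized water longitudinal magnetization at each saturation offset.
#' Deterministic; no noise is added here.
#'
#' Offsets are interpreted relative to the nominal water frequency (positive
#' ppm = downfield). A nonzero `b0_shift` displaces the water line, so the
#' spectrum satisfies `Z(offset; b0) = Z(offset - b0; 0)`.
#'
#' @param pools A [pool_system()].
#' @param sat A [saturation_scheme()].
#' @param offsets Saturation offsets (ppm). Need not be sorted; the returned
#'   spectrum is sorted ascending.
#' @param b0_shift Water-line displacement (ppm).
#' @param b1_scale Relative B1 factor kappa (>= 0); the effective saturation
#'   amplitude is `b1_rms * b1_scale`.
#' @return An object of class `zspectrum`: list with `offsets` (ppm,
#'   ascending) and `z` (normalized water Mz).
#' @examples
#' z <- simulate_zspectrum(pool_system(), cest_scheme(), c(-3, 3))
#' 100 * (z$z[1] - z$z[2]) / z$z[1]  # GluCEST percent at +/-3 ppm
#' @export
simulate_zspectrum <- function(pools, sat, offsets, b0_shift = 0, b1_scale = 1) {
  validate_pool_system(pools)
  validate_saturation_scheme(sat)
  if (!is.numeric(offsets) || length(offsets) == 0L || any(!is.finite(offsets)))
    stop("offsets must be finite numbers", call. = FALSE)
  if (!is.numeric(b1_scale) || length(b1_scale) != 1L || b1_scale < 0)
    stop("b1_scale must be a single number >= 0", call. = FALSE)
  if (!is.finite(b0_shift)) stop("b0_shift must be finite", call. = FALSE)

  ord <- order(offsets)
  off <- offsets[ord]
  hpp <- hz_per_ppm(sat)
  n_sub <- if (sat$spoiling) max(1L, as.integer(round(sat$duration / sat$pulse_length))) else 1L
  z <- bm_z_cpp(off * hpp, b0_shift * hpp,
                sat$gyromagnetic_ratio * 1e-6 * sat$b1_rms * b1_scale,
                sat$duration, n_sub, sat$spoiling,
                1 / pools$t1_water, 1 / pools$t2_water,
                1 / pools$t1_solute, 1 / pools$t2_solute,
                pools$exchange_rate, pools$solute_fraction,
                pools$solute_shift * hpp)
  structure(list(offsets = off, z = as.numeric(z)), class = "zspectrum")
}

# Vectorized z-spectra for many voxels sharing one scheme. b0/kappa/fb are
# per-voxel vectors; returns an n_voxel x n_offset matrix. Offsets must be
# ascending.
bm_z_voxels <- function(pools, sat, offsets, b0_ppm, kappa, fb) {
  hpp <- hz_per_ppm(sat)
  n_sub <- if (sat$spoiling) max(1L, as.integer(round(sat$duration / sat$pulse_length))) else 1L
  bm_z_batch_cpp(offsets * hpp, b0_ppm * hpp,
                 sat$gyromagnetic_ratio * 1e-6 * sat$b1_rms * kappa, fb,
                 sat$duration, n_sub, sat$spoiling,
                 1 / pools$t1_water, 1 / pools$t2_water,
                 1 / pools$t1_solute, 1 / pools$t2_solute,
                 pools$exchange_rate, pools$solute_shift * hpp)
}

#' GluCEST percent contrast of a simulated spectrum
#'
#' `100 * (Z(-shift) - Z(+shift)) / Z(-shift)` with both points simulated
#' directly.
#'
#' @inheritParams simulate_zspectrum
#' @param shift Label offset magnitude (ppm); defaults to the pool shift.
#' @return Percent contrast (scalar).
#' @export
simulate_glucest <- function(pools, sat, b0_shift = 0, b1_scale = 1,
                             shift = pools$solute_shift) {
  zs <- simulate_zspectrum(pools, sat, c(-shift, shift), b0_shift, b1_scale)
  100 * (zs$z[1] - zs$z[2]) / zs$z[1]
}

#' B1 calibration curve for lookup-based correction
#'
#' Simulates the GluCEST percent contrast as a function of the relative B1
#' factor kappa. The resulting table is the lookup used by [correct_b1()]:
#' a voxel with relative B1 kappa is rescaled by
#' `curve(1) / curve(kappa)`.
#'
#' @inheritParams simulate_zspectrum
#' @param kappa_grid Relative-B1 grid, values in (0, 2].
#' @return A `data.frame` with columns `kappa` and `glucest_percent`.
#' @export
b1_calibration_curve <- function(pools = pool_system(), sat = cest_scheme(),
                                 kappa_grid = seq(0.5, 1.5, by = 0.01)) {
  if (length(kappa_grid) == 0L) stop("kappa_grid must be nonempty", call. = FALSE)
  if (any(kappa_grid <= 0) || any(kappa_grid > 2))
    stop("kappa_grid values must lie in (0, 2]", call. = FALSE)
  kappa_grid <- sort(kappa_grid)
  pct <- vapply(kappa_grid, function(k) simulate_glucest(pools, sat, b1_scale = k),
                numeric(1))
  data.frame(kappa = kappa_grid, glucest_percent = pct)
}

#' Write a B1 calibration curve as CSV
#' @param curve Output of [b1_calibration_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(curve, path) {
  utils::write.csv(curve[, c("kappa", "glucest_percent")], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("z-spectrum: %d offsets in [%.3g, %.3g] ppm, Z in [%.4f, %.4f]\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              min(x$z), max(x$z)))
  invisible(x)
}
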