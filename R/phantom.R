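#' Offset image stack
#'
#' One 2D frame per saturation offset, plus acquisition metadata.
#'
#' @param frames Numeric array `nx x ny x n_offsets`.
#' @param offsets Saturation offsets (ppm), one per frame. Frames are
#'   reordered so offsets come out ascending.
#' @param scheme The [saturation_scheme()] used.
#' @param mask Optional logical `nx x ny` foreground mask.
#' @return An object of class `offset_stack`.
#' @export
offset_stack <- function(frames, offsets, scheme, mask = NULL) {
  if (length(dim(frames)) != 3L)
    stop("frames must be an nx x ny x n_offsets array", call. = FALSE)
  if (dim(frames)[3] != length(offsets))
    stop(sprintf("frame count (%d) does not match offset count (%d)",
                 dim(frames)[3], length(offsets)), call. = FALSE)
  if (anyDuplicated(offsets)) stop("offsets must be unique", call. = FALSE)
  ord <- order(offsets)
  structure(list(frames = frames[, , ord, drop = FALSE],
                 offsets = offsets[ord], scheme = scheme, mask = mask),
            class = "offset_stack")
}

#' @export
print.offset_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("offset_stack: %d x %d, %d offsets in [%.3g, %.3g] ppm\n",
              d[1], d[2], d[3], min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Standard acquisition offsets
#'
#' CEST: +/-1.8 to +/-4.2 ppm in 0.3 ppm steps (18 frames). WASSR: 0 and
#' +/-0.15 to +/-1.5 ppm in 0.15 ppm steps (21 frames).
#' @return Ascending numeric vector of offsets (ppm).
#' @export
cest_offsets <- function() {
  c(seq(-4.2, -1.8, by = 0.3), seq(1.8, 4.2, by = 0.3))
}

#' @rdname cest_offsets
#' @export
wassr_offsets <- function() {
  seq(-1.5, 1.5, by = 0.15)
}

#' Phantom configuration
#'
#' Settings for the synthetic single-slice acquisition. The default grid is
#' 96 x 64; the acquisition-matched 240 x 168 grid is available via
#' `full_size = TRUE`. Glutamate defaults are tissue-like (10 mM gray
#' matter, 6 mM white matter, per-region values near 10 mM).
#'
#' @param nx,ny Grid size (voxels).
#' @param full_size Use the 240 x 168 acquisition matrix instead of `nx,ny`.
#' @param glu_gm,glu_wm Gray/white-matter glutamate (mM).
#' @param glu_regions Named vector of per-region glutamate (mM) for the
#'   seven cortical patches.
#' @param b0_amplitude Max |B0| of the smooth field (ppm).
#' @param kappa_range Range of the smooth relative-B1 field.
#' @param noise_sd Frame noise SD relative to unit equilibrium signal.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param b1_angles Nominal flip angles (degrees) of the three
#'   B1-calibration images.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(nx = 96, ny = 64, full_size = FALSE,
                           glu_gm = 10, glu_wm = 6,
                           glu_regions = c(CG = 9.5, JLC = 9.8, ParaG = 10.5,
                                           FP = 10.2, MFG = 10.8, PreG = 9.2,
                                           PostG = 8.8),
                           b0_amplitude = 0.3, kappa_range = c(0.8, 1.2),
                           noise_sd = 0.005,
                           noise_model = c("gaussian", "rician"),
                           b1_angles = c(20, 40, 80)) {
  if (full_size) { nx <- 240; ny <- 168 }
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(length(glu_regions) == 7L,
            identical(sort(names(glu_regions)), sort(region_names()[-(1:3)])))
  structure(list(nx = nx, ny = ny, glu_gm = glu_gm, glu_wm = glu_wm,
                 glu_regions = glu_regions, b0_amplitude = b0_amplitude,
                 kappa_range = kappa_range, noise_sd = noise_sd,
                 noise_model = noise_model, b1_angles = b1_angles),
            class = "phantom_config")
}

# Elliptical brain with a white-matter core, a gray-matter band, and seven
# disjoint cortical patches inside the band. Returns the integer label map
# (0 background, 1 GM, 2 WM, 3..9 the cortical regions).
phantom_labels <- function(nx, ny) {
  x <- (seq_len(nx) - (nx + 1) / 2) / (0.45 * nx)
  y <- (seq_len(ny) - (ny + 1) / 2) / (0.42 * ny)
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  r2 <- X^2 + Y^2
  brain <- r2 <= 1
  wm <- r2 <= 0.55^2
  lab <- matrix(0L, nx, ny)
  lab[brain] <- 1L
  lab[wm] <- 2L
  ang <- 2 * pi * (0:6) / 7 + pi / 7
  rad <- 0.78
  prad <- 0.30 * min(0.45 * nx, 0.42 * ny) # patch radius, voxels
  px <- (seq_len(nx) - (nx + 1) / 2)
  py <- (seq_len(ny) - (ny + 1) / 2)
  PX <- matrix(px, nx, ny)
  PY <- matrix(py, nx, ny, byrow = TRUE)
  for (k in 1:7) {
    cx <- rad * cos(ang[k]) * 0.45 * nx
    cy <- rad * sin(ang[k]) * 0.42 * ny
    disc <- (PX - cx)^2 + (PY - cy)^2 <= prad^2
    lab[disc & lab == 1L] <- 2L + k
  }
  lab
}

# Smooth seeded random 2D field: random low-order polynomial surface in
# normalized coordinates, rescaled to max-abs 1. Zero-mean-ish but not
# exactly; callers rescale.
smooth_field <- function(nx, ny, rng) {
  x <- seq(-1, 1, length.out = nx)
  y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  cf <- rng(6)
  f <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * (X^2 - 0.5) +
    cf[5] * (Y^2 - 0.5) + cf[6] * X^2 * Y
  f / max(abs(f))
}

add_noise <- function(frames, sd, model) {
  if (sd == 0) return(frames)
  n <- length(frames)
  if (model == "rician") {
    sqrt((frames + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
  } else {
    frames + stats::rnorm(n, 0, sd)
  }
}

#' Generate a synthetic single-slice acquisition with known ground truth
#'
#' Builds the ground-truth maps (glutamate, B0, relative B1, labels), then
#' simulates the CEST stack, the WASSR stack, and the three flip-angle
#' B1-calibration images (`S = S0 * cos(kappa * alpha)`), adding acquisition
#' noise to every frame. Saturation frames are magnitude images (the
#' simulated water magnetization is recorded as `|Mz|`); the flip-angle
#' images keep the signed cosine of the calibration model.
#'
#' @param config A [phantom_config()].
#' @param pools A [pool_system()]; its solute fraction is replaced per voxel
#'   by the truth glutamate map.
#' @param cest_sat,wassr_sat Saturation schemes for the two stacks.
#' @param seed Integer seed; fully determines the phantom.
#' @param b0_map,kappa_map,glu_map Optional truth overrides (matrices of the
#'   configured grid size). Defaults are seeded smooth fields / the
#'   tissue-dependent glutamate assignment.
#' @param engine `"exact"` (per-voxel Bloch-McConnell propagation) or
#'   `"dictionary"` (trilinear lookup; pass `dicts`).
#' @param dicts Dictionaries from [default_dictionaries()] (dictionary
#'   engine only).
#' @return List with `truth` (glu/b0/kappa/label maps and brain mask),
#'   `cest` and `wassr` ([offset_stack()]s), `b1_images` (nx x ny x 3 array)
#'   and `b1_angles` (degrees).
#' @export
make_phantom <- function(config = phantom_config(), pools = pool_system(),
                         cest_sat = cest_scheme(), wassr_sat = wassr_scheme(),
                         seed = 1L, b0_map = NULL, kappa_map = NULL,
                         glu_map = NULL, engine = c("exact", "dictionary"),
                         dicts = NULL) {
  engine <- match.arg(engine)
  if (engine == "dictionary" && is.null(dicts))
    stop("dictionary engine requires 'dicts'", call. = FALSE)
  nx <- config$nx; ny <- config$ny
  set.seed(seed)

  lab <- phantom_labels(nx, ny)
  brain <- lab > 0L
  if (is.null(glu_map)) {
    glu_map <- matrix(0, nx, ny)
    glu_map[lab == 1L] <- config$glu_gm
    glu_map[lab == 2L] <- config$glu_wm
    for (k in 1:7) glu_map[lab == 2L + k] <- config$glu_regions[[k]]
  }
  if (is.null(b0_map))
    b0_map <- config$b0_amplitude * smooth_field(nx, ny, function(n) stats::rnorm(n))
  if (is.null(kappa_map)) {
    f <- smooth_field(nx, ny, function(n) stats::rnorm(n))
    kr <- config$kappa_range
    kappa_map <- mean(kr) + diff(kr) / 2 * f
  }
  truth <- list(glu_map = glu_map, b0_map = b0_map, kappa_map = kappa_map,
                label_map = lab, brain_mask = brain)

  b0v <- b0_map[brain]; kv <- kappa_map[brain]; fbv <- glu_fraction(glu_map[brain])

  sim_stack <- function(sat, offs, dict) {
    z <- matrix(0, sum(brain), length(offs))
    if (engine == "exact") {
      z <- bm_z_voxels(pools, sat, offs, b0v, kv, fbv)
    } else {
      for (j in seq_along(offs))
        z[, j] <- dict_z(dict, glu_map[brain], kv, offs[j] - b0v)
    }
    frames <- array(0, dim = c(nx, ny, length(offs)))
    for (j in seq_along(offs)) {
      fr <- matrix(0, nx, ny)
      fr[brain] <- abs(z[, j])
      frames[, , j] <- fr
    }
    offset_stack(add_noise(frames, config$noise_sd, config$noise_model),
                 offs, sat)
  }

  cest <- sim_stack(cest_sat, cest_offsets(), dicts$cest)
  wassr <- sim_stack(wassr_sat, wassr_offsets(), dicts$wassr)

  ang <- config$b1_angles * pi / 180
  b1_images <- array(0, dim = c(nx, ny, 3))
  for (j in 1:3) {
    fr <- matrix(0, nx, ny)
    fr[brain] <- cos(kappa_map[brain] * ang[j])
    b1_images[, , j] <- fr
  }
  b1_images <- add_noise(b1_images, config$noise_sd, config$noise_model)

  list(truth = truth, cest = cest, wassr = wassr,
       b1_images = b1_images, b1_angles = config$b1_angles)
}
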