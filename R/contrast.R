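#' B0-corrected z values at the label offsets
#'
#' Interpolates each voxel's CEST spectrum separately on the negative and
#' positive offset branches with natural cubic splines and evaluates them at
#' `(-3.0 + b0)` and `(+3.0 + b0)`, i.e. at the voxel's displaced water
#' frame. Voxels whose evaluation point leaves the sampled branch range
#' (|b0| > 1.2 ppm for the standard +/-1.8..4.2 ppm stack) are invalidated;
#' no extrapolation is ever performed.
#'
#' @param cest An [offset_stack()] containing both offset branches.
#' @param b0 B0 map (ppm matrix) from [fit_b0_wassr()].
#' @param mask Logical foreground matrix; defaults to B0 validity.
#' @param label_offset Label offset magnitude (ppm).
#' @return List with `z_neg`, `z_pos` (matrices) and `valid`.
#' @export
correct_b0 <- function(cest, b0, mask = NULL, label_offset = 3.0) {
  offs <- cest$offsets
  neg <- offs[offs < 0]
  pos <- offs[offs > 0]
  if (length(neg) < 4 || length(pos) < 4)
    stop("CEST stack must sample both offset branches", call. = FALSE)
  d <- dim(cest$frames)
  if (!all(dim(b0) == d[1:2])) stop("b0 map shape mismatch", call. = FALSE)
  if (is.null(mask)) mask <- is.finite(b0)

  valid <- mask & is.finite(b0)
  xn <- -label_offset + b0
  xp <- label_offset + b0
  valid <- valid & xn >= min(neg) & xn <= max(neg) &
    xp >= min(pos) & xp <= max(pos)

  Y <- matrix(cest$frames, d[1] * d[2], d[3])
  eval_branch <- function(branch_idx, xq) {
    knots <- offs[branch_idx]
    out <- rep(NA_real_, length(xq))
    sel <- which(as.vector(valid))
    if (!length(sel)) return(matrix(out, d[1], d[2]))
    # cardinal-spline evaluation: per-knot natural splines at the query
    # points, then a weighted sum of each voxel's samples
    W <- vapply(seq_along(knots), function(j) {
      y <- numeric(length(knots)); y[j] <- 1
      stats::spline(knots, y, xout = xq[sel], method = "natural")$y
    }, numeric(length(sel)))
    out[sel] <- rowSums(W * Y[sel, branch_idx, drop = FALSE])
    matrix(out, d[1], d[2])
  }
  z_neg <- eval_branch(which(offs < 0), as.vector(xn))
  z_pos <- eval_branch(which(offs > 0), as.vector(xp))
  list(z_neg = z_neg, z_pos = z_pos, valid = valid)
}

#' GluCEST percent contrast (asymmetry) map
#'
#' `100 * (z_neg - z_pos) / z_neg` per valid voxel, following the
#' negative-offset normalization convention of GluCEST. Voxels with
#' `z_neg <= 0` are invalid.
#'
#' @param z_neg,z_pos Matrices from [correct_b0()].
#' @param valid Logical validity matrix.
#' @return An object of class `glucest_map`: list with `percent` (matrix,
#'   `NA` where invalid), `valid`, and `meta`.
#' @export
compute_glucest <- function(z_neg, z_pos, valid = NULL) {
  if (!all(dim(z_neg) == dim(z_pos))) stop("map shape mismatch", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(z_neg) & is.finite(z_pos)
  valid <- valid & is.finite(z_neg) & is.finite(z_pos) & z_neg > 0
  pct <- matrix(NA_real_, nrow(z_neg), ncol(z_neg))
  pct[valid] <- 100 * (z_neg[valid] - z_pos[valid]) / z_neg[valid]
  structure(list(percent = pct, valid = valid,
                 meta = list(b1_corrected = FALSE)),
            class = "glucest_map")
}

#' B1 (kappa) correction of a GluCEST map
#'
#' Rescales each voxel by `C(1) / C(kappa)`, with `C` linearly interpolated
#' from a simulation-derived calibration table ([b1_calibration_curve()]).
#' Voxels whose kappa falls outside the calibration span are invalidated.
#'
#' @param map A [compute_glucest()] map.
#' @param kappa Relative-B1 matrix from [fit_b1_multiflip()].
#' @param calibration Data frame with columns `kappa`, `glucest_percent`,
#'   monotone over its span, which must include 1.
#' @return A corrected `glucest_map`.
#' @export
correct_b1 <- function(map, kappa, calibration = b1_calibration_curve()) {
  stopifnot(inherits(map, "glucest_map"))
  if (!all(dim(kappa) == dim(map$percent)))
    stop("kappa map shape mismatch", call. = FALSE)
  kr <- range(calibration$kappa)
  if (kr[1] > 1 || kr[2] < 1)
    stop("calibration table must span kappa = 1", call. = FALSE)
  valid <- map$valid & is.finite(kappa) & kappa >= kr[1] & kappa <= kr[2]
  c1 <- stats::approx(calibration$kappa, calibration$glucest_percent, xout = 1)$y
  pct <- matrix(NA_real_, nrow(kappa), ncol(kappa))
  ck <- stats::approx(calibration$kappa, calibration$glucest_percent,
                      xout = kappa[valid])$y
  pct[valid] <- map$percent[valid] * c1 / ck
  structure(list(percent = pct, valid = valid,
                 meta = list(b1_corrected = TRUE,
                             calibration_span = kr)),
            class = "glucest_map")
}

#' Full corrected GluCEST map for one subject
#'
#' Runs B0 correction, asymmetry computation and B1 correction. Either
#' correction can be ablated; with `b0_correction = FALSE` the acquired
#' +/-3 ppm frames are used directly, with `b1_correction = FALSE` the raw
#' asymmetry is returned.
#'
#' @param bundle A [make_phantom()] bundle.
#' @param fieldmaps A [fit_field_maps()] result.
#' @param calibration Calibration table for [correct_b1()].
#' @param b0_correction,b1_correction Toggles.
#' @return A `glucest_map`.
#' @export
glucest_pipeline_map <- function(bundle, fieldmaps,
                                 calibration = b1_calibration_curve(),
                                 b0_correction = TRUE, b1_correction = TRUE) {
  b0 <- if (b0_correction) fieldmaps$b0 else {
    z <- fieldmaps$b0; z[] <- 0; z[!fieldmaps$valid] <- NA_real_; z
  }
  zz <- correct_b0(bundle$cest, b0, mask = fieldmaps$valid)
  map <- compute_glucest(zz$z_neg, zz$z_pos, zz$valid)
  if (b1_correction) map <- correct_b1(map, fieldmaps$kappa, calibration)
  map$meta$b0_corrected <- b0_correction
  map
}

#' @export
print.glucest_map <- function(x, ...) {
  v <- x$percent[x$valid]
  cat(sprintf("glucest_map: %d valid voxels, mean %.3f%%, sd %.3f%%\n",
              sum(x$valid), mean(v), stats::sd(v)))
  invisible(x)
}
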