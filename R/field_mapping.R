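#' Brain mask from an offset stack
#'
#' Voxels whose mean signal across frames falls below 5% of the stack's
#' 99th-percentile intensity are background.
#'
#' @param stack An [offset_stack()].
#' @param threshold Fraction of the 99th percentile.
#' @return Logical matrix.
#' @export
compute_brain_mask <- function(stack, threshold = 0.05) {
  m <- apply(stack$frames, c(1, 2), mean)
  m >= threshold * stats::quantile(stack$frames, 0.99, names = FALSE)
}

# Natural-cubic-spline evaluation is linear in the sampled values, so for a
# fixed knot set the interpolant on a fixed output grid is a matrix product
# with the "cardinal" spline basis (one natural spline per unit vector).
.spline_basis <- function(knots, xout) {
  vapply(seq_along(knots), function(j) {
    y <- numeric(length(knots)); y[j] <- 1
    stats::spline(knots, y, xout = xout, method = "natural")$y
  }, numeric(length(xout)))
}

#' Per-voxel B0 map from a WASSR stack
#'
#' Each foreground voxel's WASSR spectrum is interpolated with a natural
#' cubic spline and the per-voxel water-line displacement is estimated by
#' one of two rules:
#'
#' * `"mscf"` (default): maximum-symmetry center frequency, the WASSR
#'   reference algorithm — the center `c` minimizing the symmetry error
#'   `sum_d (Z(c+d) - Z(c-d))^2` over mirrored evaluation points of the
#'   interpolant, with parabolic refinement. Uses the whole dip, so it
#'   stays well-conditioned when strong direct saturation flattens the dip
#'   bottom.
#' * `"spline_min"`: the offset minimizing the interpolant on a
#'   `grid_step` ppm grid (coarse-to-fine search over the same grid).
#'   Adequate for shallow smooth dips; noise-sensitive when the dip bottom
#'   is flat.
#'
#' All-zero or non-finite spectra are marked invalid rather than raising.
#'
#' @param wassr An [offset_stack()] with at least 7 offsets spanning 0.
#' @param mask Logical matrix; defaults to [compute_brain_mask()].
#' @param method Estimation rule, see above.
#' @param grid_step Search-grid resolution (ppm) for `"spline_min"`.
#' @param search_range Maximum |B0| searched (ppm) for `"mscf"`.
#' @return List with `b0` (matrix, ppm; `NA` outside validity) and `valid`
#'   (logical matrix).
#' @export
fit_b0_wassr <- function(wassr, mask = NULL,
                         method = c("mscf", "spline_min"),
                         grid_step = 0.001, search_range = 0.45) {
  method <- match.arg(method)
  offs <- wassr$offsets
  if (length(offs) < 7 || min(offs) >= 0 || max(offs) <= 0)
    stop("WASSR stack must have >= 7 offsets spanning 0", call. = FALSE)
  if (is.null(mask)) mask <- compute_brain_mask(wassr)
  d <- dim(wassr$frames)
  Y <- matrix(wassr$frames, d[1] * d[2], d[3])[as.vector(mask), , drop = FALSE]
  ok <- apply(Y, 1, function(r) all(is.finite(r)) && any(r != 0))

  est <- rep(NA_real_, nrow(Y))
  if (any(ok)) {
    Yok <- Y[ok, , drop = FALSE]
    est[ok] <- if (method == "mscf") {
      .b0_mscf(Yok, offs, search_range)
    } else {
      .b0_spline_min(Yok, offs, grid_step)
    }
  }
  b0_map <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  b0_map[mask][ok] <- est[ok]
  valid[mask][ok] <- TRUE
  list(b0 = b0_map, valid = valid)
}

# MSCF on a symmetric evaluation grid (0.005 ppm), coarse step 0.02 ppm,
# parabolic refinement of the symmetry error.
.b0_mscf <- function(Y, offs, search_range) {
  h <- 0.005
  half <- min(-offs[1], offs[length(offs)])
  grid <- seq(-half, half, by = h)
  Zg <- Y %*% t(.spline_basis(offs, grid))
  center0 <- (length(grid) - 1L) %/% 2L # 0-based index of offset 0
  max_shift <- min(as.integer(round(search_range / h)), center0 - 3L)
  idx <- mscf_center_cpp(Zg, center0, max_shift, 4L)
  grid[1] + idx * h
}

# argmin of the interpolant on a grid_step grid, coarse-to-fine
.b0_spline_min <- function(Y, offs, grid_step) {
  rng <- range(offs)
  coarse_step <- grid_step * 10
  coarse <- seq(rng[1], rng[2], by = coarse_step)
  Bc <- .spline_basis(offs, coarse)
  nvox <- nrow(Y)
  x0 <- coarse[max.col(-(Y %*% t(Bc)), ties.method = "first")]
  fine_off <- seq(-2 * coarse_step, 2 * coarse_step, by = grid_step)
  xq <- outer(x0, fine_off, "+")
  xq <- pmin(pmax(xq, rng[1]), rng[2])
  Bf <- .spline_basis(offs, as.vector(xq))              # (nvox*nf) x nk
  Zf <- matrix(rowSums(Bf * Y[rep(seq_len(nvox), length(fine_off)), ]),
               nvox, length(fine_off))
  xq[cbind(seq_len(nvox), max.col(-Zf, ties.method = "first"))]
}

#' Per-voxel relative B1 (kappa) map from three flip-angle images
#'
#' Fits `S_i = S0 * cos(kappa * alpha_i)` per voxel by profiling out `S0`
#' in closed form and searching kappa over `[0.3, 2]` on a 1e-3 grid.
#' Because `cos(kappa * alpha)` is non-injective at large `kappa * alpha`,
#' near-ties are broken toward the kappa closest to 1. Non-finite voxel
#' signals yield invalid voxels.
#'
#' @param images Numeric array `nx x ny x 3`.
#' @param angles Nominal flip angles (degrees), strictly increasing.
#' @param mask Logical foreground matrix.
#' @param kappa_range Search bounds.
#' @param grid_step Kappa grid resolution.
#' @return List with `kappa` (matrix; `NA` where invalid) and `valid`.
#' @export
fit_b1_multiflip <- function(images, angles, mask = NULL,
                             kappa_range = c(0.3, 2), grid_step = 1e-3) {
  if (length(dim(images)) != 3L || dim(images)[3] != length(angles))
    stop("images must be nx x ny x length(angles)", call. = FALSE)
  if (length(angles) != 3L || is.unsorted(angles, strictly = TRUE))
    stop("need three strictly increasing flip angles", call. = FALSE)
  d <- dim(images)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  S <- t(matrix(images, d[1] * d[2], 3)[as.vector(mask), , drop = FALSE]) # 3 x n
  ok <- colSums(is.finite(S)) == 3L

  kg <- seq(kappa_range[1], kappa_range[2], by = grid_step)
  a <- angles * pi / 180
  C <- outer(kg, a, function(k, al) cos(k * al)) # n_k x 3
  c2 <- rowSums(C^2)
  est <- rep(NA_real_, ncol(S))
  if (any(ok)) {
    Sok <- S[, ok, drop = FALSE]
    num <- (C %*% Sok)^2 / c2          # explained sum of squares per kappa
    ss <- colSums(Sok^2)
    # residual = ss - num; minimize residual = maximize num, breaking
    # near-ties (within 1e-12 * ss) toward kappa nearest 1
    best <- numeric(ncol(Sok))
    for (v in seq_len(ncol(Sok))) {
      nv <- num[, v]
      tol <- 1e-10 * max(ss[v], 1e-300)
      cand <- which(nv >= max(nv) - tol)
      best[v] <- kg[cand[which.min(abs(kg[cand] - 1))]]
    }
    est[ok] <- best
  }
  kappa <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  kappa[mask][ok] <- est[ok]
  valid[mask][ok] <- TRUE
  list(kappa = kappa, valid = valid)
}

#' Field maps for one subject
#'
#' Convenience wrapper running [fit_b0_wassr()] and [fit_b1_multiflip()] on
#' a phantom (or equivalently structured real-data) bundle.
#'
#' @param bundle A [make_phantom()] bundle.
#' @return List of class `field_maps`: `b0` (ppm), `kappa`, `valid`, `mask`.
#' @export
fit_field_maps <- function(bundle) {
  mask <- compute_brain_mask(bundle$wassr)
  b0 <- fit_b0_wassr(bundle$wassr, mask)
  b1 <- fit_b1_multiflip(bundle$b1_images, bundle$b1_angles, mask)
  structure(list(b0 = b0$b0, kappa = b1$kappa,
                 valid = b0$valid & b1$valid, mask = mask),
            class = "field_maps")
}
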