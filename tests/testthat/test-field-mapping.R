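wassr_like_stack <- function(f, offsets = wassr_offsets()) {
  spectrum_stack(f(offsets), offsets)
}

test_that("symmetric dip centered at zero gives a zero B0 estimate", {
  st <- wassr_like_stack(function(x) lorentz_dip(x, center = 0))
  for (m in c("mscf", "spline_min")) {
    fit <- fit_b0_wassr(st, mask = matrix(TRUE, 1, 1), method = m)
    expect_lt(abs(fit$b0[1, 1]), 1e-6)
  }
})

test_that("off-center Lorentzian dip is recovered within 0.01 ppm", {
  # brute-force oracle: argmin of the analytic Lorentzian on a 1e-4 grid
  grid <- seq(-1.5, 1.5, by = 1e-4)
  truth <- grid[which.min(lorentz_dip(grid, center = 0.12))]
  expect_equal(truth, 0.12, tolerance = 1e-9)
  st <- wassr_like_stack(function(x) lorentz_dip(x, center = 0.12))
  for (m in c("mscf", "spline_min")) {
    fit <- fit_b0_wassr(st, mask = matrix(TRUE, 1, 1), method = m)
    expect_lt(abs(fit$b0[1, 1] - 0.12), 0.01)
  }
})

test_that("shifting a spectrum shifts the B0 estimate equivariantly", {
  for (delta in c(-0.3, 0.15)) {
    base <- fit_b0_wassr(wassr_like_stack(lorentz_dip),
                         mask = matrix(TRUE, 1, 1))$b0[1, 1]
    shifted <- fit_b0_wassr(
      wassr_like_stack(function(x) lorentz_dip(x, center = delta)),
      mask = matrix(TRUE, 1, 1))$b0[1, 1]
    expect_equal(shifted - base, delta, tolerance = 0.005)
  }
})

test_that("B0 estimate ignores global intensity rescaling", {
  ph <- make_phantom(phantom_config(nx = 48, ny = 32, noise_sd = 0.003),
                     seed = 21)
  mask <- compute_brain_mask(ph$wassr)
  a <- fit_b0_wassr(ph$wassr, mask)
  scaled <- ph$wassr
  scaled$frames <- scaled$frames * 7.3
  b <- fit_b0_wassr(scaled, mask)
  expect_equal(a$b0, b$b0, tolerance = 1e-12)
})

test_that("all-zero voxel spectra are invalid, not an error", {
  frames <- array(0, dim = c(2, 1, 21))
  frames[1, 1, ] <- lorentz_dip(wassr_offsets())
  st <- offset_stack(frames, wassr_offsets(), NULL)
  fit <- fit_b0_wassr(st, mask = matrix(TRUE, 2, 1))
  expect_true(fit$valid[1, 1])
  expect_false(fit$valid[2, 1])
  expect_true(is.na(fit$b0[2, 1]))
})

test_that("WASSR sampling requirements are enforced", {
  st <- spectrum_stack(c(0.9, 0.5, 0.9), c(0.1, 0.2, 0.3))
  expect_error(fit_b0_wassr(st), "spanning 0")
})

test_that("model-exact flip-angle signals recover kappa exactly", {
  a <- c(20, 40, 80)
  sig <- array(cos(1 * a * pi / 180), dim = c(1, 1, 3))
  fit <- fit_b1_multiflip(sig, a)
  expect_equal(fit$kappa[1, 1], 1.0, tolerance = 1e-9)
  # residual at the optimum is numerically zero
  s0 <- sum(sig * cos(fit$kappa[1, 1] * a * pi / 180)) /
    sum(cos(fit$kappa[1, 1] * a * pi / 180)^2)
  expect_lt(sum((sig - s0 * cos(fit$kappa[1, 1] * a * pi / 180))^2), 1e-10)
})

test_that("kappa = 1.25 signals are recovered within the grid resolution", {
  a <- c(20, 40, 80)
  # oracle: 1-D grid search at 1e-4 over the profiled objective
  sig <- 0.37 * cos(1.25 * a * pi / 180)
  kg <- seq(0.3, 2, by = 1e-4)
  C <- outer(kg, a * pi / 180, function(k, al) cos(k * al))
  obj <- (C %*% sig)^2 / rowSums(C^2)
  expect_equal(kg[which.max(obj)], 1.25, tolerance = 2e-4)
  fit <- fit_b1_multiflip(array(sig, dim = c(1, 1, 3)), a)
  expect_equal(fit$kappa[1, 1], 1.25, tolerance = 1e-3)
})

test_that("kappa fit is invariant to signal scaling and flags bad voxels", {
  a <- c(20, 40, 80)
  sig <- cos(0.85 * a * pi / 180)
  for (c0 in c(0.2, 5)) {
    fit <- fit_b1_multiflip(array(c0 * sig, dim = c(1, 1, 3)), a)
    expect_equal(fit$kappa[1, 1], 0.85, tolerance = 1e-3)
  }
  bad <- array(c(1, NA, 0.5), dim = c(1, 1, 3))
  fit <- fit_b1_multiflip(bad, a)
  expect_false(fit$valid[1, 1])
  expect_error(fit_b1_multiflip(array(1, dim = c(1, 1, 3)), c(80, 40, 20)),
               "increasing")
})

test_that("noiseless phantom fields are recovered to 5e-3", {
  ph <- make_phantom(phantom_config(nx = 48, ny = 32, noise_sd = 0), seed = 77)
  fm <- fit_field_maps(ph)
  bm <- ph$truth$brain_mask & fm$valid
  expect_gt(sum(bm), 500)
  expect_lt(max(abs(fm$b0[bm] - ph$truth$b0_map[bm])), 5e-3)
  expect_lt(max(abs(fm$kappa[bm] - ph$truth$kappa_map[bm])), 5e-3)
})
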