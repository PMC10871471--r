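cest_stack_from <- function(f, nx = 1, ny = 1) {
  offs <- cest_offsets()
  frames <- array(rep(f(offs), each = nx * ny), dim = c(nx, ny, length(offs)))
  offset_stack(frames, offs, NULL)
}

test_that("zero B0 reproduces the acquired +/-3 ppm frames exactly", {
  st <- cest_stack_from(two_lorentz)
  zz <- correct_b0(st, matrix(0, 1, 1))
  offs <- cest_offsets()
  expect_identical(zz$z_neg[1, 1], st$frames[1, 1, which(offs == -3)])
  expect_identical(zz$z_pos[1, 1], st$frames[1, 1, which(offs == 3)])
  expect_true(zz$valid[1, 1])
})

test_that("B0 correction undoes a 0.15 ppm shift within 1e-3", {
  # analytic oracle: the unshifted two-Lorentzian spectrum at +/-3 ppm
  st <- cest_stack_from(function(x) two_lorentz(x, center = 0.15))
  zz <- correct_b0(st, matrix(0.15, 1, 1))
  expect_lt(abs(zz$z_neg[1, 1] - two_lorentz(-3)), 1e-3)
  expect_lt(abs(zz$z_pos[1, 1] - two_lorentz(3)), 1e-3)
})

test_that("evaluation points outside the sampled branches invalidate voxels", {
  st <- cest_stack_from(two_lorentz)
  zz <- correct_b0(st, matrix(1.3, 1, 1))
  expect_false(zz$valid[1, 1])
  expect_true(is.na(zz$z_neg[1, 1]))
  zz2 <- correct_b0(st, matrix(-1.21, 1, 1))
  expect_false(zz2$valid[1, 1])
})

test_that("asymmetry arithmetic and degenerate voxels", {
  zn <- matrix(c(0.60, 0.5, 0), 3, 1)
  zp <- matrix(c(0.48, 0.5, 0.1), 3, 1)
  map <- compute_glucest(zn, zp)
  expect_equal(map$percent[1, 1], 20.0)
  expect_equal(map$percent[2, 1], 0.0)
  expect_false(map$valid[3, 1]) # z_neg <= 0
})

test_that("asymmetry is invariant to global stack rescaling", {
  st <- cest_stack_from(two_lorentz)
  zz <- correct_b0(st, matrix(0.1, 1, 1))
  m1 <- compute_glucest(zz$z_neg, zz$z_pos, zz$valid)
  st2 <- st
  st2$frames <- st2$frames * 3.7
  zz2 <- correct_b0(st2, matrix(0.1, 1, 1))
  m2 <- compute_glucest(zz2$z_neg, zz2$z_pos, zz2$valid)
  expect_equal(m1$percent, m2$percent, tolerance = 1e-12)
})

test_that("B1 correction is the identity at nominal B1 and clamps kappa", {
  cal <- b1_calibration_curve()
  map <- compute_glucest(matrix(0.7, 2, 2), matrix(0.6, 2, 2))
  same <- correct_b1(map, matrix(1, 2, 2), cal)
  expect_equal(same$percent, map$percent, tolerance = 1e-12)
  k <- matrix(1, 2, 2); k[1, 1] <- 0.4
  clamped <- correct_b1(map, k, cal)
  expect_false(clamped$valid[1, 1])
  expect_true(clamped$valid[2, 2])
  expect_error(correct_b1(map, matrix(1, 2, 2),
                          data.frame(kappa = c(1.2, 1.4),
                                     glucest_percent = c(2, 3))),
               "span")
})

test_that("B1 correction rescales by the calibration ratio", {
  cal <- b1_calibration_curve()
  raw <- simulate_glucest(pool_system(), cest_scheme(), b1_scale = 0.85)
  map <- compute_glucest(matrix(0.7, 1, 1), matrix(0.7 * (1 - raw / 100), 1, 1))
  corr <- correct_b1(map, matrix(0.85, 1, 1), cal)
  nominal <- simulate_glucest(pool_system(), cest_scheme())
  expect_equal(corr$percent[1, 1], nominal, tolerance = 0.01 * nominal)
})

test_that("ablating corrections degrades recovery on a perturbed phantom", {
  nx <- 48; ny <- 32
  kx <- matrix(seq(0.85, 1.15, length.out = nx), nx, ny)
  b0 <- matrix(seq(-0.2, 0.2, length.out = ny), nx, ny, byrow = TRUE)
  ph <- make_phantom(uniform_glu_config(nx = nx, ny = ny), seed = 31,
                     b0_map = b0, kappa_map = kx)
  fm <- fit_field_maps(ph)
  cal <- b1_calibration_curve()
  truth <- simulate_glucest(pool_system(), cest_scheme())
  err <- function(map) {
    bm <- ph$truth$brain_mask & map$valid
    mean(abs(map$percent[bm] - truth))
  }
  e_full <- err(glucest_pipeline_map(ph, fm, cal))
  e_nob0 <- err(glucest_pipeline_map(ph, fm, cal, b0_correction = FALSE))
  e_nob1 <- err(glucest_pipeline_map(ph, fm, cal, b1_correction = FALSE))
  expect_lt(e_full, e_nob0)
  expect_lt(e_full, e_nob1)
})
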