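small_cfg <- function(...) phantom_config(nx = 48, ny = 32, ...)

test_that("default phantom has the standard offset sampling", {
  ph <- make_phantom(small_cfg(), seed = 1)
  expect_length(ph$cest$offsets, 18)
  expect_length(ph$wassr$offsets, 21)
  expect_equal(ph$cest$offsets, cest_offsets())
  expect_equal(ph$wassr$offsets, wassr_offsets())
  expect_equal(dim(ph$b1_images), c(48, 32, 3))
})

test_that("same seed and config give byte-identical phantoms", {
  a <- make_phantom(small_cfg(), seed = 42)
  b <- make_phantom(small_cfg(), seed = 42)
  expect_identical(a, b)
  d <- make_phantom(small_cfg(), seed = 43)
  expect_false(identical(a$cest$frames, d$cest$frames))
})

test_that("truth labels partition the brain with all regions populated", {
  ph <- make_phantom(small_cfg(), seed = 5)
  lab <- ph$truth$label_map
  expect_true(all(lab[!ph$truth$brain_mask] == 0L))
  expect_true(all(lab[ph$truth$brain_mask] > 0L))
  counts <- table(factor(lab[lab > 0], levels = 1:9))
  expect_true(all(counts > 0))
  expect_true(all(counts[3:9] >= 10)) # cortical patches are analyzable
})

test_that("unperturbed noiseless phantom yields exact field recovery", {
  nx <- 48; ny <- 32
  ph <- make_phantom(small_cfg(noise_sd = 0), seed = 3,
                     b0_map = matrix(0, nx, ny), kappa_map = matrix(1, nx, ny))
  fm <- fit_field_maps(ph)
  bm <- ph$truth$brain_mask
  expect_true(all(fm$valid[bm]))
  # the amine wing leaves a sub-0.001 ppm asymmetry in the WASSR dip
  expect_lt(max(abs(fm$b0[bm])), 1e-3)
  expect_lt(max(abs(fm$kappa[bm] - 1)), 1e-12)
})

test_that("noiseless pipeline contrast equals the simulator prediction per voxel", {
  ph <- make_phantom(uniform_glu_config(nx = 48, ny = 32), seed = 9,
                     b0_map = matrix(0, 48, 32), kappa_map = matrix(1, 48, 32))
  pred <- simulate_glucest(pool_system(solute_fraction = glu_fraction(10)),
                           cest_scheme())
  # with the known truth fields, the numeric path is exact at the sample
  # offsets: contrast matches the simulator to 1e-6
  truth_fm <- structure(list(b0 = matrix(0, 48, 32),
                             kappa = matrix(1, 48, 32),
                             valid = ph$truth$brain_mask,
                             mask = ph$truth$brain_mask),
                        class = "field_maps")
  map <- glucest_pipeline_map(ph, truth_fm, b1_calibration_curve())
  bm <- ph$truth$brain_mask & map$valid
  expect_gt(sum(bm), 100)
  expect_lt(max(abs(map$percent[bm] - pred)), 1e-6)
  # with estimated fields the residual is the (tiny) field-estimation error
  fm <- fit_field_maps(ph)
  map2 <- glucest_pipeline_map(ph, fm, b1_calibration_curve())
  bm2 <- ph$truth$brain_mask & map2$valid
  expect_lt(max(abs(map2$percent[bm2] - pred)), 0.05)
})

test_that("dictionary engine reproduces the exact engine closely", {
  dicts <- default_dictionaries()
  cfg <- small_cfg(noise_sd = 0)
  a <- make_phantom(cfg, seed = 11, engine = "exact")
  b <- make_phantom(cfg, seed = 11, engine = "dictionary", dicts = dicts)
  expect_lt(max(abs(a$cest$frames - b$cest$frames)), 2e-3)
  expect_lt(max(abs(a$wassr$frames - b$wassr$frames)), 3e-3)
  expect_error(make_phantom(cfg, seed = 1, engine = "dictionary"), "dicts")
})

test_that("cohort has the study's structure: 10 + 9 usable subjects", {
  co <- make_cohort(cohort_config(), seed = 2)
  m <- co$manifest
  expect_equal(nrow(m), 20)
  usable <- m[m$usable, ]
  expect_equal(sum(usable$group == "non-smoker"), 10)
  expect_equal(sum(usable$group == "smoker"), 9)
  expect_true(all(m$age >= 20 & m$age <= 70))
  # one female and one male per decade in each recruited group
  for (g in c("non-smoker", "smoker")) {
    gm <- m[m$group == g, ]
    cell <- table(gm$sex, cut(gm$age, seq(20, 70, 10), right = FALSE))
    expect_true(all(cell == 1))
  }
  expect_equal(rownames(co$glu_truth), usable$subject_id)
})

test_that("degenerate cohort generator yields identical subjects", {
  co <- make_cohort(cohort_config(subject_sd_mM = 0, group_effect_mM = 0,
                                  age_slope_ns = 0, age_slope_s = 0), seed = 4)
  expect_equal(max(apply(co$glu_truth, 2, function(x) diff(range(x)))), 0)
})

test_that("cohort config rejects impossible group sizes", {
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
  expect_error(cohort_config(n_unusable_smokers = 10), "n_unusable")
})

test_that("age-slope injection propagates to subject truth", {
  co <- make_cohort(cohort_config(subject_sd_mM = 0,
                                  age_slope_s = c(CG = -0.1)), seed = 6)
  m <- co$manifest[co$manifest$usable, ]
  sm <- m$group == "smoker"
  fit <- stats::lm(co$glu_truth[sm, "CG"] ~ m$age[sm])
  expect_equal(unname(stats::coef(fit)[2]), -0.1, tolerance = 1e-10)
  # non-smokers unaffected
  expect_equal(max(co$glu_truth[!sm, "CG"]) - min(co$glu_truth[!sm, "CG"]), 0)
})
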