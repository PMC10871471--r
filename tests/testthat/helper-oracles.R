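# Independent oracles shared across test files.

# Dense ODE integration (radau, analytic Jacobian) of the two-pool
# Bloch-McConnell system: the reference the matrix-exponential engine is
# checked against. CW saturation only.
ode_oracle_z <- function(pools, sat, offsets, b0 = 0, kappa = 1) {
  hpp <- hz_per_ppm(sat)
  fb <- pools$solute_fraction
  kb <- pools$exchange_rate
  ka <- fb * kb
  w1 <- 2 * pi * sat$gyromagnetic_ratio * 1e-6 * sat$b1_rms * kappa
  r1a <- 1 / pools$t1_water; r2a <- 1 / pools$t2_water
  r1b <- 1 / pools$t1_solute; r2b <- 1 / pools$t2_solute
  vapply(offsets, function(o) {
    da <- 2 * pi * hpp * (b0 - o)
    db <- 2 * pi * hpp * (b0 + pools$solute_shift - o)
    A <- matrix(c(-(r2a + ka), da, 0, kb, 0, 0,
                  -da, -(r2a + ka), w1, 0, kb, 0,
                  0, -w1, -(r1a + ka), 0, 0, kb,
                  ka, 0, 0, -(r2b + kb), db, 0,
                  0, ka, 0, -db, -(r2b + kb), w1,
                  0, 0, ka, 0, -w1, -(r1b + kb)), 6, 6, byrow = TRUE)
    bvec <- c(0, 0, r1a, 0, 0, r1b * fb)
    out <- deSolve::ode(c(0, 0, 1, 0, 0, fb), c(0, sat$duration),
                        function(t, M, p) list(as.numeric(A %*% M) + bvec),
                        NULL, method = "radau",
                        jacfunc = function(t, M, p) A, jactype = "fullusr",
                        rtol = 1e-11, atol = 1e-13, maxsteps = 1e6)
    out[2, 4]
  }, numeric(1))
}

# Analytic Lorentzian dip (normalized so the baseline is 1)
lorentz_dip <- function(x, center = 0, depth = 0.8, width = 0.4) {
  1 - depth * width^2 / (width^2 + (x - center)^2)
}

# Two-Lorentzian z-spectrum: water line at `center`, solute line 3 ppm
# downfield of it.
two_lorentz <- function(x, center = 0) {
  # 0.8 ppm solute linewidth: fast-exchange amine lines are broad, and the
  # 0.3 ppm offset sampling then resolves the lineshape
  1 - 0.7 * 0.8^2 / (0.8^2 + (x - center)^2) -
    0.05 * 0.8^2 / (0.8^2 + (x - center - 3)^2)
}

# wrap a single spectrum (or a small set) into a 1 x n x k stack
spectrum_stack <- function(z, offsets, scheme = NULL) {
  offset_stack(array(z, dim = c(1, 1, length(z))), offsets, scheme)
}

# uniform-glutamate phantom configuration used by several correction tests
uniform_glu_config <- function(glu = 10, nx = 96, ny = 64, noise_sd = 0) {
  phantom_config(nx = nx, ny = ny, noise_sd = noise_sd,
                 glu_gm = glu, glu_wm = glu,
                 glu_regions = c(CG = glu, JLC = glu, ParaG = glu, FP = glu,
                                 MFG = glu, PreG = glu, PostG = glu))
}
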