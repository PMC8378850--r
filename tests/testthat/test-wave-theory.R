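r0_default <- log(2) / 480

test_that("closed-form wave speed reproduces the published values", {
  w <- wave_speed(a0 = 1, r0 = r0_default, D = 30)
  expect_equal(w$regime, "large_bias")
  expect_equal(signif(w$sigma, 3), 1.04)
  expect_equal(round(100 * w$phi), 40)

  # no-bias limit: Fisher speed, phi = 1
  w0 <- wave_speed(a0 = 0, r0 = r0_default, D = 30)
  expect_equal(w0$sigma, 2 * sqrt(r0_default * 30))
  expect_equal(w0$phi, 1)
  expect_equal(w0$regime, "small_bias")

  # continuity at the dichotomy a0 = sqrt(r0 D)
  ac <- sqrt(r0_default * 30)
  expect_equal(ac + r0_default * 30 / ac, 2 * sqrt(r0_default * 30))
  wlo <- wave_speed(ac * (1 - 1e-9), r0_default, 30)
  whi <- wave_speed(ac * (1 + 1e-9), r0_default, 30)
  expect_equal(wlo$sigma, whi$sigma, tolerance = 1e-6)
})

test_that("wave speed is monotone non-decreasing in a0, r0 and D", {
  set.seed(42)
  for (i in 1:50) {
    a0 <- runif(1, 0, 3); r0 <- runif(1, 1e-4, 5e-3); D <- runif(1, 5, 100)
    eps <- 1e-6
    s <- wave_speed(a0, r0, D)$sigma
    expect_gte(wave_speed(a0 + eps, r0, D)$sigma, s - 1e-12)
    expect_gte(wave_speed(a0, r0 * (1 + eps), D)$sigma, s - 1e-12)
    expect_gte(wave_speed(a0, r0, D * (1 + eps))$sigma, s - 1e-12)
    expect_gte(s, 2 * sqrt(r0 * D) - 1e-12)
  }
})

test_that("phi grid reproduces the pushed/pulled separatrix", {
  g <- phi_grid(a0 = seq(0.05, 1, by = 0.05), doubling_h = c(4, 8, 16))
  # large-bias exactly where a0 exceeds sqrt(r0 D)
  expect_equal(g$regime == "large_bias", g$a0 > g$a0_separatrix)
  expect_true(all(g$phi > 0 & g$phi <= 1))
  expect_equal(g$phi[g$regime == "small_bias"],
               rep(1, sum(g$regime == "small_bias")))
})

test_that("shape-based estimate matches the published flux-balance figure", {
  expect_equal(round(shape_speed_estimate(300, 4, r0_default), 1), 0.9)
  expect_equal(shape_speed_estimate(0, 4, r0_default), 0)
})

test_that("explicit elementary profile solves the traveling-wave ODE", {
  p <- mean_field_params(a0 = 1)
  prof <- explicit_profile(1, p$r0, p$D, "elementary", A = 500)
  expect_equal(prof$mu, 1 / 30) # mu = a0/D at the elementary speed
  # ODE residual ahead of the threshold: D rho'' + sigma rho' + r0 rho = 0
  z <- seq(1, 300, by = 0.01)
  rho <- prof$rho(z)
  d1 <- (prof$rho(z + 1e-3) - prof$rho(z - 1e-3)) / 2e-3
  d2 <- (prof$rho(z + 1e-3) - 2 * rho + prof$rho(z - 1e-3)) / 1e-6
  res <- p$D * d2 + prof$sigma * d1 + p$r0 * rho
  expect_lt(max(abs(res)) / max(rho), 1e-6)
  # plateau behind
  expect_equal(prof$rho(-1e6), prof$A * prof$B)
  # small-bias regime refuses the exponential ansatz
  expect_error(explicit_profile(0.1, p$r0, p$D), "small-bias")
})

test_that("two-threshold profile is continuous and solves its ODE pieces", {
  p <- mean_field_params(a0 = 1)
  tt <- two_threshold_speed(p)
  prof <- explicit_profile(1, p$r0, p$D, "two_threshold", h = tt$h,
                           sigma = tt$sigma, A = 100)
  # continuity at z = 0 and z = -h
  expect_equal(prof$rho(-1e-9), prof$rho(1e-9), tolerance = 1e-6)
  expect_equal(prof$rho(-tt$h - 1e-9), prof$rho(-tt$h + 1e-9),
               tolerance = 1e-6)
  # middle piece: D rho'' + (sigma - a0) rho' = 0
  z <- seq(-min(tt$h, 500) + 1, -1, by = 0.5)
  d1 <- (prof$rho(z + 1e-3) - prof$rho(z - 1e-3)) / 2e-3
  d2 <- (prof$rho(z + 1e-3) - 2 * prof$rho(z) + prof$rho(z - 1e-3)) / 1e-6
  res <- p$D * d2 + (tt$sigma - p$a0) * d1
  expect_lt(max(abs(res)) / max(prof$rho(z)), 1e-6)
})

test_that("two-threshold speed lies in its bracket and approaches the right limits", {
  p <- mean_field_params()
  tt <- two_threshold_speed(p)
  lo <- 2 * sqrt(p$r0 * p$D); hi <- p$a0 + p$r0 * p$D / p$a0
  expect_gte(tt$sigma, lo)
  expect_lte(tt$sigma, hi)
  expect_gt(tt$h, 0)
  # wide aerotaxis band (C0p far below C0): elementary speed recovered
  expect_lt(abs(tt$sigma - tt$sigma_elementary) / tt$sigma_elementary, 0.01)
  # vanishing band (C0p -> C0): aerotaxis no longer contributes and the
  # speed falls toward the Fisher speed
  t2 <- two_threshold_speed(mean_field_params(C0p = 0.69))
  expect_lt(t2$sigma, 0.7 * tt$sigma)
  expect_gt(t2$sigma, lo * 0.999)
  # sigma decreases monotonically as the band narrows
  sig <- vapply(c(0.1, 0.3, 0.5, 0.65),
                function(cp) two_threshold_speed(
                  mean_field_params(C0p = cp))$sigma, numeric(1))
  expect_true(all(diff(sig) < 0))
  # small-bias parameter sets are rejected
  expect_error(two_threshold_speed(mean_field_params(a0 = 0.1)),
               "large-bias")
})

test_that("two-threshold speed stays within 15% of the closed form over the scanned range", {
  worst <- 0
  for (a0 in seq(0.2, 2, by = 0.3)) {
    for (td in c(4, 8, 16)) {
      r0 <- log(2) / (td * 60)
      if (a0 <= sqrt(r0 * 30)) next
      res <- tryCatch(two_threshold_speed(mean_field_params(a0 = a0, r0 = r0)),
                      error = function(e) NULL)
      if (is.null(res)) next # marginal bias: no root above the Fisher speed
      worst <- max(worst, abs(res$sigma - res$sigma_elementary) /
                     res$sigma_elementary)
    }
  }
  expect_lt(worst, 0.15)
})

test_that("lattice unit conversions reproduce the printed arithmetic", {
  u <- potts_unit_conversions()
  expect_equal(u$mol_per_pixel, 1.25e-15)
  expect_equal(u$consumption_per_pixel, 0.1, tolerance = 0.01)
  expect_equal(u$boundary_flux, 6e-8)
  expect_equal(u$division_prob, 1 / 288000)
  expect_equal(u$division_prob_printed, 3e-6)
})

test_that("dichotomy-solved speed agrees with a two-threshold simulation", {
  # the analytic variant assumes constant consumption with unconstrained
  # oxygen; its oxygen structure spans Doxy/sigma, so the cross-check uses
  # a reduced oxygen diffusivity to fit the wave in a desk-scale domain
  # and starts the simulation from the exact analytic wave fields
  p <- mean_field_params(a0 = 1, Doxy = 3000)
  x <- seq(1, 10000, by = 2)
  tw <- two_threshold_wave_fields(p, x, front_x = 4000)
  p2 <- p; p2$Cboundary <- tw$C[length(x)]
  rho <- scalar_field1d(tw$rho, 2, "planar")
  C <- scalar_field1d(tw$C, 2, "planar")
  sol <- simulate_pde(rho, C, p2, dt = 0.04, t_end = 600,
                      model = "two_threshold", snapshot_every = 300,
                      consumption = "constant")
  sigma_sim <- measure_front_speed(sol, c(100, 600))
  expect_equal(sigma_sim, tw$wave$sigma, tolerance = 0.05)
  # and the speed genuinely differs from the elementary closed form here:
  # with slow oxygen diffusion the second threshold matters
  expect_lt(tw$wave$sigma, 0.8 * tw$wave$sigma_elementary)
})
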