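p_def <- mean_field_params()

test_that("advection field follows the piecewise Go-or-Grow rules", {
  n <- 50
  # uniform saturated oxygen: no advection anywhere
  C <- scalar_field1d(rep(21, n), 1)
  expect_equal(advection_speed(C, "go_or_grow", p_def), rep(0, n))

  # linear ramp entirely below the lower threshold: two-threshold variant off
  C2 <- scalar_field1d(seq(0.001, 0.09, length.out = n), 1)
  expect_equal(advection_speed(C2, "two_threshold", p_def), rep(0, n))
  # ...but the single-threshold model is fully on there
  a2 <- advection_speed(C2, "go_or_grow", p_def)
  expect_equal(a2[-1], rep(p_def$a0, n - 1))

  # increasing ramp crossing C0 at a known node
  C3 <- scalar_field1d(seq(0.2, 1.2, length.out = n), 1)
  a3 <- advection_speed(C3, "go_or_grow", p_def)
  below <- which(C3$values < p_def$C0)
  expect_equal(a3[setdiff(below, 1)],
               rep(p_def$a0, length(below) - 1))
  expect_equal(a3[C3$values > p_def$C0], rep(0, sum(C3$values > p_def$C0)))

  # mean-field advection is the sigmoid response times the local gradient
  a4 <- advection_speed(C3, "mean_field", p_def)
  g <- c(0, diff(C3$values))
  expect_equal(a4, ifelse(seq_len(n) == 1, 0,
                          lambda_mf(C3$values, p_def) * g))
  expect_error(advection_speed(C3, "bogus"), "arg")
})

test_that("consumption ramps to zero below the lower threshold", {
  expect_equal(consumption_rate(0, p_def), 0)
  expect_equal(consumption_rate(p_def$C0p, p_def), p_def$b0)
  expect_equal(consumption_rate(0.05, p_def), 0.005)
  expect_equal(consumption_rate(c(21, 5), p_def), c(0.01, 0.01))
  expect_error(consumption_rate(-1, p_def), ">= 0")
})

test_that("pure diffusion conserves mass and grows variance at rate 2D", {
  n <- 500
  p <- mean_field_params(r0 = 1e-15) # growth negligible
  x <- seq_len(n)
  rho <- scalar_field1d(exp(-(x - 250)^2 / 200), 1)
  C <- scalar_field1d(rep(21, n), 1)
  st <- list(rho = rho, C = C)
  nsteps <- 1000
  for (i in seq_len(nsteps)) st <- pde_step(st$rho, st$C, p, 0.02)
  expect_lt(abs(sum(st$rho$values) - sum(rho$values)) / sum(rho$values),
            1e-8)
  mvar <- function(w) sum(w * (x - sum(w * x) / sum(w))^2) / sum(w)
  growth <- (mvar(st$rho$values) - mvar(rho$values)) / (nsteps * 0.02)
  expect_equal(growth, 2 * p$D, tolerance = 1e-3)
  # radial geometry conserves the cylindrical mass integral
  rr <- scalar_field1d(exp(-(x - 250)^2 / 200), 1, "radial")
  R <- field_coords(rr)
  st <- list(rho = rr, C = scalar_field1d(rep(21, n), 1, "radial"))
  for (i in 1:200) st <- pde_step(st$rho, st$C, p, 0.02)
  expect_lt(abs(sum(st$rho$values * R) - sum(rr$values * R)) /
              sum(rr$values * R), 1e-8)
})

test_that("without consumers the oxygen field keeps its boundary value", {
  n <- 100
  rho <- scalar_field1d(rep(0, n), 1)
  C <- scalar_field1d(rep(21, n), 1)
  st <- list(rho = rho, C = C)
  for (i in 1:50) st <- pde_step(st$rho, st$C, p_def, 0.02)
  expect_equal(st$C$values, rep(21, n), tolerance = 1e-12)
  expect_equal(st$rho$values, rep(0, n))
})

test_that("mass balance with growth matches the division integral", {
  # d/dt (integral rho) = integral r(C) rho when advection fluxes vanish
  n <- 300
  p <- mean_field_params()
  rho <- scalar_field1d(500 * exp(-(seq_len(n) - 150)^2 / 500), 1)
  C <- scalar_field1d(rep(21, n), 1) # C > C0 everywhere: r = r0
  st <- list(rho = rho, C = C)
  m0 <- sum(rho$values)
  nsteps <- 500
  for (i in seq_len(nsteps)) st <- pde_step(st$rho, st$C, p, 0.02)
  m1 <- sum(st$rho$values)
  expect_equal(m1 / m0, exp(p$r0 * nsteps * 0.02), tolerance = 1e-3)
})

test_that("front positions and speeds are measured correctly", {
  fr <- data.frame(t = 0:100, x = 100 + 0.8 * (0:100))
  expect_equal(measure_front_speed(fr, c(0, 100)), 0.8)
  # stationary front
  fr2 <- data.frame(t = 0:100, x = rep(55, 101))
  expect_equal(measure_front_speed(fr2, c(0, 100)), 0)
  # noisy synthetic slope: fitted value within the regression CI
  set.seed(7)
  fr3 <- data.frame(t = 0:200, x = 50 + 1.3 * (0:200) + rnorm(201, 0, 5))
  fit <- lm(x ~ t, fr3)
  ci <- confint(fit)["t", ]
  est <- measure_front_speed(fr3, c(0, 200))
  expect_gte(est, ci[1]); expect_lte(est, ci[2])
  expect_equal(est, unname(coef(fit)[2]))
  # error when the front never crosses the threshold
  fr4 <- data.frame(t = 0:10, x = rep(NA_real_, 11))
  expect_error(measure_front_speed(fr4, c(0, 10)), "never crosses")
})

test_that("go-or-grow front speed is insensitive to mesh refinement", {
  p <- mean_field_params(a0 = 1)
  speeds <- vapply(list(c(2, 0.04), c(1, 0.02)), function(mesh) {
    init <- gen_initial_profiles("near_wave", p, dx = mesh[1], L = 5000,
                                 front_x = 1200, plateau = 500)
    sol <- simulate_pde(init$rho, init$C, p, dt = mesh[2], t_end = 500,
                        model = "go_or_grow", snapshot_every = 250)
    measure_front_speed(sol, c(250, 500))
  }, numeric(1))
  expect_lt(abs(speeds[2] - speeds[1]) / speeds[2], 0.02)
})

test_that("quasi-static oxygen solve is a fixed point of the dynamics", {
  p <- mean_field_params()
  n <- 2000
  rho <- scalar_field1d(ifelse(seq_len(n) < 800, 500, 0), 2)
  C <- quasi_static_oxygen(rho, p)
  expect_true(all(C$values >= 0))
  expect_equal(C$values[n], p$Cboundary)
  st <- list(rho = rho, C = C)
  for (i in 1:100) st <- pde_step(st$rho, st$C, mean_field_params(r0 = 1e-15), 0.02)
  # oxygen stays close to the relaxed profile when density is frozen-ish
  expect_lt(max(abs(st$C$values - C$values)), 0.2)
})
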