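p1 <- mean_field_params(a0 = 1)

make_wave_grid <- function(dz = 2, zmin = -2000, zmax = 1000,
                           params = p1) {
  z <- seq(zmin + dz / 2, zmax, by = dz)
  prof <- explicit_profile(params$a0, params$r0, params$D, "elementary",
                           A = 1)
  rho <- scalar_field1d(prof$rho(z), dz, "planar", origin = zmin)
  list(z = z, rho = rho, prof = prof,
       fields = gogrow_frame_fields(z, params))
}

test_that("splitting at the peak partitions the profile exactly", {
  # symmetric triangle: equal masses on both sides
  v <- c(1:10, 9:1)
  tri <- scalar_field1d(v, 1)
  sp <- split_at_peak(tri)
  expect_equal(sp$left$values + sp$right$values, v)
  expect_equal(sum(sp$left$values) - max(v), sum(sp$right$values))
  expect_equal(sp$peak_index, 10)

  # elementary wave: flat plateau splits where the decay begins
  w <- make_wave_grid()
  spw <- split_at_peak(w$rho)
  expect_equal(w$z[spw$peak_index], max(w$z[w$z < 0]))
  expect_equal(spw$left$values + spw$right$values, w$rho$values)

  # strictly monotone profile has no interior peak
  expect_error(split_at_peak(scalar_field1d(1:50, 1)), "no interior peak")
})

test_that("label evolution is linear and permutation-symmetric", {
  w <- make_wave_grid(dz = 5, zmin = -1000, zmax = 800)
  sp <- split_at_peak(w$rho)
  run <- function(fr) {
    evolve_fractions(fr, w$fields$a_z, w$fields$r_z, sigma = w$prof$sigma,
                     D = p1$D, dt = 0.5, t_end = 200, record_every = 100)
  }
  both <- run(list(a = sp$left, b = sp$right))
  whole <- run(list(all = w$rho))
  # evolving the sum equals the sum of evolved fractions
  expect_equal(both$fractions$a$values + both$fractions$b$values,
               whole$fractions$all$values, tolerance = 1e-12)
  # swapping the labels swaps the outputs exactly
  swapped <- run(list(b = sp$right, a = sp$left))
  expect_identical(swapped$fractions$b$values, both$fractions$b$values)
  expect_identical(swapped$fractions$a$values, both$fractions$a$values)
  # fractions stay non-negative
  expect_true(all(both$fractions$a$values >= -1e-14))
})

test_that("the wave profile is quasi-stationary in its own frame", {
  w <- make_wave_grid(dz = 2, zmin = -2000, zmax = 1000)
  st <- evolve_fractions(list(all = w$rho), w$fields$a_z, w$fields$r_z,
                         sigma = w$prof$sigma, D = p1$D, dt = 0.5,
                         t_end = 2000, record_every = 1000)
  rel <- sqrt(sum((st$total$values - w$rho$values)^2) /
                sum(w$rho$values^2))
  expect_lt(rel, 0.1) # discrete steady state is close to the analytic wave
})

test_that("large-bias labels mix uniformly (pushed wave)", {
  w <- make_wave_grid(dz = 2, zmin = -2000, zmax = 1000)
  sp <- split_at_peak(w$rho)
  st <- evolve_fractions(list(rear = sp$left, front = sp$right),
                         w$fields$a_z, w$fields$r_z, sigma = w$prof$sigma,
                         D = p1$D, dt = 0.5, t_end = 12000,
                         front_window = c(-200, 300), record_every = 600)
  cl <- classify_wave(st)
  expect_equal(cl$verdict, "pushed")
  expect_lt(cl$mixing_index, 0.05)
  # asymptotic front share matches the exp(U)-weighted overlap prediction
  pred <- pushed_share_prediction(sp$left$values, w$rho$values, w$z,
                                  w$fields$a_z, w$prof$sigma, p1$D)
  expect_equal(cl$rear_share, pred, tolerance = 0.05)
})

test_that("small-bias labels segregate (pulled wave)", {
  p <- mean_field_params(a0 = 0.1)
  fisher <- 2 * sqrt(p$r0 * p$D)
  dz <- 5
  z <- seq(-1000 + dz / 2, 7000, by = dz)
  mu <- sqrt(p$r0 / p$D)
  rho <- scalar_field1d(ifelse(z < 0, 1, exp(-mu * z)), dz, "planar",
                        origin = -1000)
  sp <- split_at_peak(rho)
  ff <- gogrow_frame_fields(z, p)
  st <- evolve_fractions(list(rear = sp$left, front = sp$right),
                         ff$a_z, ff$r_z, sigma = fisher, D = p$D, dt = 2,
                         t_end = 3e5, front_window = c(-200, 300),
                         record_every = 1.5e4)
  cl <- classify_wave(st)
  expect_equal(cl$verdict, "pulled")
  # the rear label's share decays by more than two orders of magnitude
  expect_lt(cl$rear_share, 0.01 * st$shares$rear[1])
})

test_that("classification flips near the predicted pushed/pulled boundary", {
  # sqrt(r0 D) = 0.208 um/min at the defaults: clearly below is pulled,
  # clearly above is pushed
  verdicts <- vapply(c(0.1, 0.5), function(a0) {
    p <- mean_field_params(a0 = a0)
    large <- a0 > sqrt(p$r0 * p$D)
    sigma <- wave_speed(a0, p$r0, p$D)$sigma
    dz <- 5
    if (large) {
      z <- seq(-2000 + dz / 2, 1500, by = dz)
      prof <- explicit_profile(a0, p$r0, p$D, "elementary", A = 1)
      rho <- scalar_field1d(prof$rho(z), dz, "planar", origin = -2000)
      tend <- 2e4; dt <- 1
    } else {
      z <- seq(-1000 + dz / 2, 7000, by = dz)
      mu <- sqrt(p$r0 / p$D)
      rho <- scalar_field1d(ifelse(z < 0, 1, exp(-mu * z)), dz, "planar",
                            origin = -1000)
      tend <- 3e5; dt <- 2
    }
    sp <- split_at_peak(rho)
    ff <- gogrow_frame_fields(z, p)
    st <- evolve_fractions(list(rear = sp$left, front = sp$right),
                           ff$a_z, ff$r_z, sigma = sigma, D = p$D, dt = dt,
                           t_end = tend, front_window = c(-200, 300),
                           record_every = tend / 20)
    classify_wave(st)$verdict
  }, character(1))
  expect_equal(verdicts, c("pulled", "pushed"))
})
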