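test_that("spot seeding reproduces the published colony geometry", {
  st <- init_spot()
  n <- length(st$volume)
  expect_gte(n, 1900); expect_lte(n, 2000)
  expect_true(all(st$volume == 2L))
  cells <- potts_cells(st)
  r <- sqrt((cells$x - 2500)^2 + (cells$y - 2500)^2)
  expect_lte(max(r), 905) # all cells within the 90-pixel outer radius
  expect_equal(unique(as.vector(st$o2)), 21)
  potts_audit(st)
  # three density tiers: inner crown denser than middle, middle than outer
  d1 <- sum(r < 280) / (pi * 280^2)
  d2 <- sum(r > 320 & r < 580) / (pi * (580^2 - 320^2))
  d3 <- sum(r > 620 & r < 880) / (pi * (880^2 - 620^2))
  expect_gt(d1, 1.5 * d2); expect_gt(d2, 1.3 * d3)
})

test_that("microfluidic seeding installs the frozen sigmoid gradient", {
  st <- init_microfluidic()
  expect_equal(st$o2[1, 201], 21.38 / 2) # sigmoid midpoint at x = 200
  expect_equal(st$o2[400, 201], st$o2[1, 201]) # x-only variation
  # uniform seeding density across the gradient at t = 0
  cells <- potts_cells(st)
  left <- sum(cells$x < 2000); right <- sum(cells$x >= 2000)
  expect_lt(abs(left - right) / (left + right), 0.05)
  # a short run leaves the frozen oxygen untouched
  set.seed(1)
  st2 <- potts_step(init_microfluidic(scale = 0.25), 100)
  expect_equal(st2$o2, init_microfluidic(scale = 0.25)$o2)
})

test_that("aerotaxis and temperature sigmoids evaluate as printed", {
  expect_equal(lambda_aero_potts(0.7), 400) # half amplitude at midpoint
  expect_equal(temperature_potts(21), 85 + 105 / (1 + exp(20.3)))
  expect_equal(temperature_potts(0), 85 + 105 / (1 + exp(-0.7)))
  expect_lt(temperature_potts(21), 85.001)
})

test_that("pixel bookkeeping survives Monte Carlo dynamics", {
  set.seed(31)
  st <- init_spot(scale = 0.25)
  st <- potts_step(st, 2000)
  potts_audit(st) # volumes, COM sums and pixel tiling all recomputed
  expect_true(all(st$volume >= 1L)) # no cell death
})

test_that("runs are reproducible bit-for-bit at a fixed seed", {
  set.seed(77); a <- potts_step(init_spot(scale = 0.25), 300)
  set.seed(77); b <- potts_step(init_spot(scale = 0.25), 300)
  expect_identical(a$grid, b$grid)
  expect_identical(a$o2, b$o2)
  expect_identical(a$volume, b$volume)
})

test_that("oxygen update: fixed point, capped consumption, budget audit", {
  # no cells and saturated field: the source boundaries keep C at 21
  st <- new_potts_state(matrix(0L, 30, 30), matrix(21, 30, 30),
                        integer(0), numeric(0), numeric(0), integer(0))
  st <- potts_step(st, 5, do_mc = FALSE)
  expect_equal(st$o2, matrix(21, 30, 30))

  # capped consumption: an occupied pixel at C = 0.05 loses exactly 0.05
  n <- 40
  g <- matrix(0L, n, n); g[20, 20] <- 1L; g[20, 21] <- 1L
  st <- new_potts_state(g, matrix(0.05, n, n), 2L, (19 + 20), 2 * 19,
                        1L)
  st <- potts_step(st, 1, do_mc = FALSE)
  leak_occ <- 0.001 * (21 - 0) / 21
  leak_emp <- 0.001 * (21 - 0.05) / 21
  expect_equal(st$o2[20, 20], 0 + leak_occ, tolerance = 1e-12)
  expect_equal(st$o2[20, 25], 0.05 + leak_emp, tolerance = 1e-12)

  # closed-box budget: with no leak, the interior oxygen drops by exactly
  # consumption_per_pixel per occupied pixel per step
  p0 <- potts_params(leak_coeff = 1e-300)
  g2 <- matrix(0L, n, n)
  occ <- cbind(c(18, 18, 22, 22), c(18, 19, 21, 22))
  for (i in seq_len(nrow(occ))) g2[occ[i, 1], occ[i, 2]] <- i
  st2 <- new_potts_state(g2, matrix(10, n, n), rep(1L, 4),
                         occ[, 2] - 1, occ[, 1] - 1, 1:4, params = p0)
  inner <- 12:28
  before <- sum(st2$o2[inner, inner])
  st2 <- potts_step(st2, 1, do_mc = FALSE)
  expect_equal(before - sum(st2$o2[inner, inner]), 0.1 * 4,
               tolerance = 1e-9)
})

test_that("division is gated by oxygen and paced by the printed probability", {
  # frozen hypoxic field: no divisions ever
  st <- init_microfluidic(nx = 100, ny = 100, scale = 1)
  st$o2[] <- 0.5
  set.seed(41)
  st2 <- potts_step(st, 20000, do_mc = FALSE)
  expect_equal(length(st2$volume), length(st$volume))

  # saturated field: counts follow the binomial expectation
  st$o2[] <- 21
  set.seed(42)
  st3 <- potts_step(st, 20000, do_mc = FALSE)
  n0 <- length(st$volume)
  expected <- n0 * 20000 / 288000
  got <- length(st3$volume) - n0
  expect_lt(abs(got - expected), 4 * sqrt(expected))

  # a forced division splits a 2-pixel cell into two 1-pixel cells
  stf <- init_microfluidic(nx = 40, ny = 40, scale = 1,
                           params = potts_params(division_prob = 1))
  stf$o2[] <- 21
  set.seed(43)
  st4 <- potts_step(stf, 1, do_mc = FALSE)
  expect_equal(length(st4$volume), 2 * length(stf$volume))
  expect_true(all(st4$volume == 1L))
  expect_equal(sort(unique(st4$lineage)), sort(unique(stf$lineage)))
  potts_audit(st4)
})

test_that("motion is unbiased without gradients and aerotactic with them", {
  make_state <- function(C0val, grad_per_px, seed) {
    N <- 120; M <- 240
    x <- matrix(rep(0:(M - 1), each = N), N, M)
    o2 <- pmin(pmax(C0val + grad_per_px * (x - M / 2), 0.001), 21)
    g <- matrix(0L, N, M)
    vol <- integer(0); sumx <- numeric(0); sumy <- numeric(0); id <- 0L
    for (y in seq(5, N - 5, by = 10)) for (xx in seq(60, M - 60, by = 12)) {
      id <- id + 1L
      g[y, xx] <- id; g[y, xx + 1] <- id
      vol[id] <- 2L; sumx[id] <- (xx - 1) + xx; sumy[id] <- 2 * (y - 1)
    }
    set.seed(seed)
    new_potts_state(g, o2, vol, sumx, sumy, seq_len(id),
                    geometry = "microfluidic")
  }
  displacement <- function(st, mcs) {
    c0 <- potts_cells(st)
    st <- potts_step(st, mcs, variant = "no_division")
    c1 <- potts_cells(st)
    list(dx = c1$x - c0$x, dy = c1$y - c0$y)
  }
  mcs_30min <- 18000

  # uniform hypoxia: no directional bias (132 cells)
  d0 <- displacement(make_state(0.4, 0, 51), mcs_30min)
  sem <- sd(d0$dx) / sqrt(length(d0$dx))
  expect_lt(abs(mean(d0$dx)), 2.5 * sem)
  D_hyp <- mean(d0$dx^2 + d0$dy^2) / (4 * 30)

  # aerokinesis: hypoxic cells are far more motile than atmospheric ones
  d21 <- displacement(make_state(21, 0, 52), mcs_30min)
  D_atm <- mean(d21$dx^2 + d21$dy^2) / (4 * 30)
  expect_gt(D_hyp, 5 * D_atm)

  # aerotaxis: up-gradient drift; the unmodulated response (constant
  # lambda_aero, division off) gives a clean directional signal over the
  # single-cell noise
  stg <- make_state(10, 0.1, 53)
  stg$params <- potts_params(division_prob = 0)
  c0 <- potts_cells(stg)
  stg <- potts_step(stg, mcs_30min, variant = "flat_aero")
  dxg <- potts_cells(stg)$x - c0$x
  semg <- sd(dxg) / sqrt(length(dxg))
  expect_gt(mean(dxg), 3 * semg) # significantly positive (up-gradient)
})

test_that("ablation variants remap parameters and run", {
  set.seed(61)
  st <- init_spot(scale = 0.25)
  for (v in c("constant_T", "wide_aero", "low_consumption")) {
    out <- potts_step(st, 50, variant = v)
    potts_audit(out)
    expect_gte(length(out$volume), length(st$volume))
  }
})

test_that("microfluidic cells vacate deep hypoxia and accumulate low", {
  set.seed(62)
  run <- run_assay("microfluidic", "no_division", t_end_h = 6, scale = 0.2,
                   snapshot_every_min = 180)
  C_of <- function(cells) microfluidic_gradient(cells$x / 10 / 0.2)
  C0v <- C_of(run$cells[[1]])
  Cend <- C_of(run$cells[[length(run$cells)]])
  # the strongly hypoxic side empties out
  expect_lt(sum(Cend < 0.5), 0.5 * sum(C0v < 0.5))
  # the density peak (per unit oxygen) sits in a low-oxygen band
  br <- c(0, 0.5, 1, 1.5, 2, 3, 5, 10, 22)
  h <- hist(Cend, breaks = br, plot = FALSE)
  dens <- h$counts / diff(br)
  peak_bin <- which.max(dens[1:7]) # density peak among C < 5 bins
  expect_gt(h$mids[peak_bin], 0.4)
  expect_lt(max(dens[1:7]), Inf)
  expect_gt(max(dens[2:6]), dens[1]) # denser above 0.5% than below
})
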