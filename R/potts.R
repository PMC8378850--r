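#' Initialize the spot-assay Potts lattice
#'
#' Cells (2-pixel dominoes, target volume 2) are seeded in three concentric
#' regions of decreasing density: radius < 30 px with a 1-pixel gap between
#' cells, 30--60 px with a 2-pixel gap, 60--90 px with a 3-pixel gap (all
#' radii and gaps scaled by `scale`), giving an initial colony of 900 um
#' radius with about 1900--2000 cells at full scale. The oxygen field
#' starts saturated at 21 \%O2 with the borders acting as a fixed source.
#'
#' @param grid_size lattice side, pixels (default 500).
#' @param scale desk-scale factor; 0.5 halves the lattice and all radii.
#' @param params a [potts_params()].
#' @return A `potts_state` list: `grid` (integer cell-id matrix, 0 =
#'   medium), `o2` (matrix, \%O2), per-cell `volume`, `sumx`, `sumy`,
#'   `lineage`, plus bookkeeping.
#' @export
init_spot <- function(grid_size = 500, scale = 1, params = potts_params()) {
  n <- round(grid_size * scale)
  grid <- matrix(0L, n, n)
  o2 <- matrix(21, n, n)
  cx <- (n - 1) / 2
  radii <- c(30, 60, 90) * scale
  gaps <- c(1, 2, 3)
  vol <- integer(0); sumx <- numeric(0); sumy <- numeric(0)
  id <- 0L
  for (tier in 1:3) {
    px <- 2 + gaps[tier] # x period: 2-pixel cell + gap
    py <- 1 + gaps[tier]
    r_in <- if (tier == 1) -1 else radii[tier - 1]
    r_out <- radii[tier]
    xs <- seq(round(cx) %% px, n - 2, by = px)
    ys <- seq(round(cx) %% py, n - 1, by = py)
    for (y in ys) for (x in xs) {
      # a cell belongs to the annulus its nearest pixel falls in
      r <- min(sqrt((x - cx)^2 + (y - cx)^2),
               sqrt((x + 1 - cx)^2 + (y - cx)^2))
      if (r <= r_in || r > r_out) next
      if (grid[y + 1, x + 1] != 0L || grid[y + 1, x + 2] != 0L) next
      id <- id + 1L
      grid[y + 1, x + 1] <- id
      grid[y + 1, x + 2] <- id
      vol[id] <- 2L; sumx[id] <- x + (x + 1); sumy[id] <- 2 * y
    }
  }
  new_potts_state(grid, o2, vol, sumx, sumy, seq_len(id), params,
                  geometry = "spot", scale = scale)
}

#' Initialize the microfluidic-assay Potts lattice
#'
#' Homogeneous seeding (2-pixel cells on a grid with a 6-pixel gap to the
#' next neighbor in all directions) on a 400 x 800 (x by y) lattice, with a
#' frozen oxygen field varying along x only:
#' `C(x) = 21.38 / (1 + exp(0.031 * (x - 200)))` (x in pixels at full
#' scale). In this geometry oxygen neither diffuses nor is consumed.
#'
#' @param nx,ny lattice extent along the gradient (x) and across it (y).
#' @param scale desk-scale factor applied to both extents (the sigmoid
#'   steepness and midpoint are rescaled so the gradient spans the same
#'   concentration range).
#' @param params a [potts_params()].
#' @return A `potts_state`, with `o2` frozen.
#' @export
init_microfluidic <- function(nx = 400, ny = 800, scale = 1,
                              params = potts_params()) {
  M <- round(nx * scale); N <- round(ny * scale)
  grid <- matrix(0L, N, M)
  xpix <- seq_len(M) - 1
  Cx <- microfluidic_gradient(xpix / scale)
  o2 <- matrix(rep(Cx, each = N), N, M)
  vol <- integer(0); sumx <- numeric(0); sumy <- numeric(0)
  id <- 0L
  for (y in seq(0, N - 1, by = 7)) for (x in seq(0, M - 2, by = 8)) {
    id <- id + 1L
    grid[y + 1, x + 1] <- id
    grid[y + 1, x + 2] <- id
    vol[id] <- 2L; sumx[id] <- x + (x + 1); sumy[id] <- 2 * y
  }
  new_potts_state(grid, o2, vol, sumx, sumy, seq_len(id), params,
                  geometry = "microfluidic", scale = scale)
}

#' Assemble a Potts state from raw components
#'
#' Low-level constructor used by the initializers; exposed for building
#' custom scenarios (e.g. isolated cells in a frozen gradient for
#' calibration runs). `sumx`/`sumy` are per-cell sums of 0-based pixel
#' coordinates.
#'
#' @param grid integer cell-id matrix (0 = medium).
#' @param o2 oxygen matrix, \%O2, same shape.
#' @param vol,sumx,sumy,lineage per-cell records.
#' @param params a [potts_params()].
#' @param geometry `"spot"` (dynamic oxygen) or `"microfluidic"` (frozen).
#' @param scale bookkeeping scale factor.
#' @return A `potts_state`.
#' @export
new_potts_state <- function(grid, o2, vol, sumx, sumy, lineage,
                            params = potts_params(),
                            geometry = "spot", scale = 1) {
  structure(list(grid = grid, o2 = o2, volume = as.integer(vol),
                 sumx = sumx, sumy = sumy, lineage = as.integer(lineage),
                 params = params, geometry = geometry, scale = scale,
                 time_mcs = 0), class = "potts_state")
}

#' @export
print.potts_state <- function(x, ...) {
  cat(sprintf("<potts_state> %s, %d x %d lattice, %d cells, t = %g MCS\n",
              x$geometry, nrow(x$grid), ncol(x$grid), length(x$volume),
              x$time_mcs))
  invisible(x)
}

potts_cpp_par <- function(state, variant = "full") {
  p <- state$params
  out <- list(lambda_v = p$lambda_v, V_target = p$V_target,
              lambda_aero_max = p$lambda_aero_max,
              aero_midpoint = p$aero_midpoint, aero_width = p$aero_width,
              aero_flat = 0L,
              T_base = p$T_base, T_amp = p$T_amp, T_midpoint = p$T_midpoint,
              T_width = p$T_width,
              consumption_per_pixel = p$consumption_per_pixel,
              leak_coeff = p$leak_coeff, division_prob = p$division_prob,
              division_cutoff = p$division_cutoff,
              moore = as.integer(p$neighborhood == "moore"),
              oxygen_dynamic = as.integer(state$geometry != "microfluidic"),
              division_on = 1L, Dox_px = p$Dox_px)
  switch(variant,
    full = {},
    no_division = { out$division_prob <- 0 },
    constant_T = { out$T_amp <- 0; out$T_base <- 135 },
    wide_aero = { out$lambda_aero_max <- 1225; out$aero_width <- 1.5 },
    flat_aero = { out$aero_flat <- 1L },
    low_consumption = {
      out$consumption_per_pixel <- p$consumption_per_pixel / 3
    },
    stop("unknown variant: ", variant))
  out
}

#' Advance a Potts state by a number of Monte Carlo steps
#'
#' @param state a `potts_state`.
#' @param n_mcs number of Monte Carlo steps (one MCS = N*M copy attempts
#'   = 0.1 s of simulated time).
#' @param variant parameter variant, see [run_assay()].
#' @param do_mc set `FALSE` to run only the oxygen/division bookkeeping
#'   (used in tests).
#' @return The advanced `potts_state`.
#' @export
potts_step <- function(state, n_mcs = 1, variant = "full", do_mc = TRUE) {
  par <- potts_cpp_par(state, variant)
  out <- .potts_advance_cpp(state$grid, state$o2, state$volume, state$sumx,
                            state$sumy, state$lineage, par,
                            as.integer(n_mcs), as.integer(do_mc))
  state$grid <- out$grid; state$o2 <- out$o2
  state$volume <- out$volume; state$sumx <- out$sumx
  state$sumy <- out$sumy; state$lineage <- out$lineage
  state$time_mcs <- state$time_mcs + n_mcs
  state
}

#' Per-cell table of a Potts state
#'
#' @param state a `potts_state`.
#' @return data.frame with `id`, `x`, `y` (center of mass, um), `volume`
#'   (pixels) and `lineage`.
#' @export
potts_cells <- function(state) {
  px <- state$params$px_um
  data.frame(id = seq_along(state$volume),
             x = (state$sumx / state$volume + 0.5) * px,
             y = (state$sumy / state$volume + 0.5) * px,
             volume = state$volume,
             lineage = state$lineage)
}

#' Aerotaxis and temperature sigmoids of the lattice model
#'
#' `lambda_aero(C) = lambda_aero_max / (1 + exp((C - 0.7)/0.2))` and
#' `T(C) = 85 + 105 / (1 + exp((C - 0.7)/1))` at the defaults.
#'
#' @param C oxygen concentration(s), \%O2.
#' @param params a [potts_params()].
#' @return Numeric vector.
#' @export
lambda_aero_potts <- function(C, params = potts_params()) {
  params$lambda_aero_max /
    (1 + exp((C - params$aero_midpoint) / params$aero_width))
}

#' @rdname lambda_aero_potts
#' @export
temperature_potts <- function(C, params = potts_params()) {
  params$T_base + params$T_amp /
    (1 + exp((C - params$T_midpoint) / params$T_width))
}

#' Run a Potts assay simulation
#'
#' Drives the Monte Carlo kernel over `t_end_h` simulated hours, recording
#' per-cell tables (and, for the spot geometry, the oxygen field) at a
#' regular stride. Runs are reproducible bit-for-bit for a fixed seed set
#' with `set.seed()` before the call.
#'
#' @param geometry `"spot"` or `"microfluidic"`.
#' @param variant `"full"`, `"no_division"`, `"constant_T"`, `"wide_aero"`,
#'   `"flat_aero"` or `"low_consumption"` (the ablation variants: division
#'   off; temperature constant regardless of oxygen; wider aerotaxis
#'   sigmoid 1225/(1+exp((C-0.7)/1.5)); aerotaxis constant for all C;
#'   consumption divided by 3).
#' @param t_end_h simulated hours.
#' @param scale desk-scale factor (0.5 halves the lattice and radii).
#' @param snapshot_every_min minutes between snapshots.
#' @param params a [potts_params()].
#' @param state optional pre-built initial state (overrides `geometry`).
#' @return Object of class `potts_run`: list with `times_min`, `cells`
#'   (list of per-cell tables), `o2` (list of oxygen matrices, spot only),
#'   `final` state, `geometry`, `variant`, `scale`.
#' @export
run_assay <- function(geometry = c("spot", "microfluidic"),
                      variant = "full", t_end_h = 3, scale = 1,
                      snapshot_every_min = 15, params = potts_params(),
                      state = NULL) {
  geometry <- match.arg(geometry)
  if (is.null(state)) {
    state <- if (geometry == "spot") {
      init_spot(scale = scale, params = params)
    } else {
      init_microfluidic(scale = scale, params = params)
    }
  }
  steps_per_min <- round(60 / state$params$step_s)
  chunk <- round(snapshot_every_min * steps_per_min)
  nchunk <- ceiling(t_end_h * 60 / snapshot_every_min)
  times <- numeric(nchunk + 1)
  cells <- vector("list", nchunk + 1)
  o2s <- vector("list", nchunk + 1)
  cells[[1]] <- potts_cells(state)
  o2s[[1]] <- state$o2
  for (i in seq_len(nchunk)) {
    state <- potts_step(state, chunk, variant = variant)
    times[i + 1] <- state$time_mcs * state$params$step_s / 60
    cells[[i + 1]] <- potts_cells(state)
    if (geometry == "spot") o2s[[i + 1]] <- state$o2
  }
  structure(list(times_min = times, cells = cells,
                 o2 = if (geometry == "spot") o2s else state$o2,
                 final = state, geometry = geometry, variant = variant,
                 scale = scale),
            class = "potts_run")
}

#' @export
print.potts_run <- function(x, ...) {
  cat(sprintf("<potts_run> %s / %s, %d snapshots to t = %.1f min, %d cells\n",
              x$geometry, x$variant, length(x$times_min),
              max(x$times_min), nrow(x$cells[[length(x$cells)]])))
  invisible(x)
}

#' Audit the pixel bookkeeping of a Potts state
#'
#' Recomputes per-cell volumes and centers of mass from the lattice and
#' checks them against the incremental records; also checks that cell
#' pixels plus medium pixels tile the lattice.
#'
#' @param state a `potts_state`.
#' @return `TRUE` invisibly; stops on any mismatch.
#' @export
potts_audit <- function(state) {
  tab <- tabulate(state$grid[state$grid > 0L], nbins = length(state$volume))
  if (!identical(as.integer(tab), state$volume)) {
    stop("potts_audit: recomputed volumes disagree with records")
  }
  if (sum(state$volume) + sum(state$grid == 0L) != length(state$grid)) {
    stop("potts_audit: cell pixels + medium pixels != lattice size")
  }
  idx <- which(state$grid > 0L, arr.ind = TRUE)
  sx <- vapply(split((idx[, 2] - 1), state$grid[idx]), sum, 0)
  ord <- as.integer(names(sx))
  if (max(abs(sx - state$sumx[ord])) > 1e-9) {
    stop("potts_audit: center-of-mass records disagree")
  }
  invisible(TRUE)
}
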