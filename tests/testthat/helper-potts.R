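# Shared Potts fixtures. The long spot runs are expensive, so they are
# built lazily once per test session and reused across test files.
potts_fixtures <- new.env(parent = emptyenv())

get_spot_run <- function() {
  if (is.null(potts_fixtures$full)) {
    set.seed(101)
    potts_fixtures$full <- run_assay("spot", "full", t_end_h = 7.5,
                                     scale = 0.5, snapshot_every_min = 20)
  }
  potts_fixtures$full
}

get_no_division_run <- function() {
  if (is.null(potts_fixtures$nodiv)) {
    set.seed(102)
    potts_fixtures$nodiv <- run_assay("spot", "no_division", t_end_h = 5,
                                      scale = 0.5, snapshot_every_min = 30)
  }
  potts_fixtures$nodiv
}

get_flat_aero_run <- function() {
  if (is.null(potts_fixtures$flat)) {
    set.seed(103)
    potts_fixtures$flat <- run_assay("spot", "flat_aero", t_end_h = 2,
                                     scale = 0.5, snapshot_every_min = 30)
  }
  potts_fixtures$flat
}

# ring-fit trajectory of a spot run: one row per snapshot with a converged fit
spot_ring_track <- function(run, bin_width = 25) {
  n <- nrow(run$final$grid)
  ctr <- rep(n / 2 * run$final$params$px_um, 2)
  out <- data.frame()
  for (i in seq_along(run$times_min)) {
    pr <- radial_profile(run$cells[[i]], center = ctr, bin_width = bin_width)
    fit <- tryCatch(fit_ring(pr), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    out <- rbind(out, data.frame(t = run$times_min[i], pos = fit$position,
                                 width = fit$width, peak = fit$peak_density,
                                 baseline = fit$baseline_density))
  }
  out
}

# radial extent that contains 90% of the cells
radius_q90 <- function(cells, center) {
  r <- sqrt((cells$x - center[1])^2 + (cells$y - center[2])^2)
  unname(stats::quantile(r, 0.9))
}
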