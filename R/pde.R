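#' 1-D scalar field on a uniform grid
#'
#' Light container for cell density or oxygen sampled on a uniform 1-D grid,
#' in planar (coordinate x) or radial (coordinate r) symmetry. Radial grids
#' are cell-centered: node i sits at `origin + (i - 1/2) * dx`, which places
#' the inner no-flux face exactly at the radial origin.
#'
#' @param values numeric vector of field values (length >= 3, finite).
#' @param dx grid spacing, um.
#' @param geometry `"planar"` or `"radial"`.
#' @param origin coordinate of the inner face of the first cell, um.
#' @return An object of class `scalar_field1d`.
#' @export
scalar_field1d <- function(values, dx, geometry = c("planar", "radial"),
                           origin = 0) {
  geometry <- match.arg(geometry)
  if (length(values) < 3) stop("scalar_field1d: need at least 3 nodes")
  if (!all(is.finite(values))) stop("scalar_field1d: values must be finite")
  if (!is.numeric(dx) || dx <= 0) stop("scalar_field1d: dx must be > 0")
  if (geometry == "radial" && origin < 0) {
    stop("scalar_field1d: radial origin must be >= 0")
  }
  structure(list(values = as.numeric(values), dx = dx, geometry = geometry,
                 origin = origin), class = "scalar_field1d")
}

#' Grid coordinates of a scalar field
#' @param field a [scalar_field1d()].
#' @return Numeric vector of node coordinates, um.
#' @export
field_coords <- function(field) {
  field$origin + (seq_along(field$values) - 0.5) * field$dx
}

#' @export
print.scalar_field1d <- function(x, ...) {
  cat(sprintf("<scalar_field1d> %d nodes, dx = %g um, %s, origin = %g um\n",
              length(x$values), x$dx, x$geometry, x$origin))
  invisible(x)
}

pde_par_list <- function(params, model, geometry, dx, dt, origin,
                         consumption = "ramp") {
  model_code <- match(model, c("mean_field", "go_or_grow", "two_threshold")) - 1L
  if (is.na(model_code)) stop("unknown model tag: ", model)
  c(unclass(params),
    list(model = model_code,
         geometry = match(geometry, c("planar", "radial")) - 1L,
         consumption_constant = as.integer(consumption == "constant"),
         dx = dx, dt = dt, origin = origin))
}

#' Per-node aerotactic advection values
#'
#' Signed advection speed a(C, dC/dx) at each node, using the one-sided
#' gradient `(C_i - C_{i-1})/dx` of the discretization (first node: 0).
#' `mean_field`: `lambda_mf(C) * dC/dx`; `go_or_grow`: `a0 * sign(dC/dx)`
#' where `C < C0`, 0 otherwise; `two_threshold`: additionally 0 where
#' `C < C0p`.
#'
#' @param C a [scalar_field1d()] of oxygen, \%O2.
#' @param model `"mean_field"`, `"go_or_grow"` or `"two_threshold"`.
#' @param params a [mean_field_params()].
#' @return Numeric vector of advection speeds, um/min (sign = direction of
#'   increasing coordinate).
#' @export
advection_speed <- function(C, model = c("go_or_grow", "mean_field",
                                         "two_threshold"),
                            params = mean_field_params()) {
  model <- match.arg(model)
  v <- C$values
  g <- c(0, diff(v)) / C$dx
  a <- switch(model,
    mean_field = lambda_mf(v, params) * g,
    go_or_grow = ifelse(v < params$C0, params$a0 * sign(g), 0),
    two_threshold = ifelse(v < params$C0 & v > params$C0p,
                           params$a0 * sign(g), 0))
  a[1] <- 0
  a
}

#' Per-cell oxygen consumption rate
#'
#' `b(C) = min(b0, b0 * C / C0p)`: constant consumption above the lower
#' threshold, ramping linearly to zero below it so that oxygen cannot turn
#' negative under a sufficiently small time step.
#'
#' @param C oxygen concentration(s), \%O2 (vector or [scalar_field1d()]).
#' @param params a [mean_field_params()].
#' @return Consumption rate(s), \%O2 min^-1 per (cell/mm^2).
#' @export
consumption_rate <- function(C, params = mean_field_params()) {
  v <- if (inherits(C, "scalar_field1d")) C$values else C
  if (any(v < 0)) stop("consumption_rate: C must be >= 0")
  pmin(params$b0, params$b0 * v / params$C0p)
}

#' Advance the coupled density/oxygen system by one time step
#'
#' One implicit (time-backward) update of the density with upwind advection,
#' followed by one implicit diffusion-consumption update of the oxygen using
#' the freshly updated density. Density has no-flux conditions at both ends;
#' oxygen has a no-flux inner end and a Dirichlet condition
#' `C = Cboundary` at the outer end.
#'
#' @param rho,C [scalar_field1d()] objects on the same grid.
#' @param params a [mean_field_params()].
#' @param dt time step, min.
#' @param model model tag, see [advection_speed()].
#' @return List with updated `rho` and `C` fields.
#' @export
pde_step <- function(rho, C, params = mean_field_params(), dt = 0.02,
                     model = "go_or_grow") {
  stopifnot(length(rho$values) == length(C$values), rho$dx == C$dx, dt > 0)
  par <- pde_par_list(params, model, rho$geometry, rho$dx, dt, rho$origin)
  out <- .pde_step_cpp(rho$values, C$values, par)
  list(rho = scalar_field1d(out$rho, rho$dx, rho$geometry, rho$origin),
       C = scalar_field1d(out$C, C$dx, C$geometry, C$origin))
}

#' Simulate the coupled density/oxygen system
#'
#' Repeated [pde_step()] with the discretization used throughout
#' (default mesh dt = 0.02 min, dx = 1 um). The front position
#' `x_bar(t)`, defined by `C(t, x_bar) = C0` (outermost upward crossing,
#' linearly interpolated), is recorded along the way.
#'
#' @param init_rho,init_C initial [scalar_field1d()] fields on a common grid.
#' @param params a [mean_field_params()].
#' @param dt,t_end time step and final time, min.
#' @param model model tag, see [advection_speed()].
#' @param snapshot_every interval between stored snapshots, min.
#' @param front_every interval between front-position records, min.
#' @param consumption `"ramp"` (default: `b(C) = min(b0, b0*C/C0p)`, keeps
#'   oxygen non-negative) or `"constant"` (`b = b0` with oxygen left
#'   unconstrained, the assumption of the analytically solvable
#'   two-threshold variant).
#' @return An object of class `pde_solution`: list with `times`,
#'   `rho_snapshots` and `C_snapshots` (matrices, one row per snapshot),
#'   `front` (data.frame `t`, `x`), the grid description, and the final
#'   fields `rho`, `C`.
#' @export
simulate_pde <- function(init_rho, init_C, params = mean_field_params(),
                         dt = 0.02, t_end = 600,
                         model = c("go_or_grow", "mean_field",
                                   "two_threshold"),
                         snapshot_every = 60, front_every = 1,
                         consumption = c("ramp", "constant")) {
  model <- match.arg(model)
  consumption <- match.arg(consumption)
  stopifnot(t_end > 0, length(init_rho$values) == length(init_C$values))
  nsteps <- max(1L, round(t_end / dt))
  snap_stride <- max(1L, round(snapshot_every / dt))
  front_stride <- max(1L, round(front_every / dt))
  par <- pde_par_list(params, model, init_rho$geometry, init_rho$dx, dt,
                      init_rho$origin, consumption)
  out <- .pde_simulate_cpp(init_rho$values, init_C$values, par, nsteps,
                           snap_stride, front_stride)
  structure(list(
    times = out$times,
    rho_snapshots = out$rho, C_snapshots = out$C,
    front = data.frame(t = out$front_t, x = out$front_x),
    dx = init_rho$dx, geometry = init_rho$geometry, origin = init_rho$origin,
    model = model, params = params,
    rho = scalar_field1d(out$rho_final, init_rho$dx, init_rho$geometry,
                         init_rho$origin),
    C = scalar_field1d(if (consumption == "ramp") pmax(out$C_final, 0) else
                         out$C_final,
                       init_C$dx, init_C$geometry, init_C$origin)
  ), class = "pde_solution")
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf("<pde_solution> model %s, %s grid of %d nodes, t in [0, %g] min\n",
              x$model, x$geometry, length(x$rho$values), max(x$times)))
  invisible(x)
}

#' Front speed from a PDE solution
#'
#' Least-squares slope of the front trajectory `x_bar(t)` over a time
#' window.
#'
#' @param sol a `pde_solution` from [simulate_pde()], or a data.frame with
#'   columns `t` and `x`.
#' @param window length-2 numeric, time interval (min) over which to fit.
#' @return Front speed, um/min.
#' @export
measure_front_speed <- function(sol, window = NULL) {
  fr <- if (inherits(sol, "pde_solution")) sol$front else sol
  if (is.null(window)) window <- c(max(fr$t) / 2, max(fr$t))
  keep <- fr$t >= window[1] & fr$t <= window[2] & is.finite(fr$x)
  if (sum(keep) < 2) {
    stop("measure_front_speed: front never crosses C0 in the window")
  }
  unname(stats::coef(stats::lm(x ~ t, data = fr[keep, ]))[2])
}

#' Quasi-static oxygen profile for a frozen density
#'
#' Relaxes the oxygen diffusion-consumption equation to steady state with
#' the density held fixed (implicit pseudo-time iterations), with the same
#' boundary conditions as [pde_step()]. Used to build initial conditions
#' consistent with a given density profile.
#'
#' @param rho density [scalar_field1d()].
#' @param params a [mean_field_params()].
#' @param iters number of pseudo-time iterations.
#' @return Oxygen [scalar_field1d()] on the same grid.
#' @export
quasi_static_oxygen <- function(rho, params = mean_field_params(),
                                iters = 200) {
  par <- pde_par_list(params, "go_or_grow", rho$geometry, rho$dx, 1,
                      rho$origin)
  Cinit <- rep(params$Cboundary, length(rho$values))
  v <- .oxygen_relax_cpp(rho$values, Cinit, par, iters, 1e4)
  scalar_field1d(pmax(v, 0), rho$dx, rho$geometry, rho$origin)
}
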