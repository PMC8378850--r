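#' Microfluidic oxygen gradient
#'
#' The oxygen profile imposed across the cell channel of the microfluidic
#' device, fitted by the sigmoid
#' `C(x) = 21.38 / (1 + exp(0.031 * (x - 200)))` with `x` in pixels
#' (10 um/pixel).
#'
#' @param x_px position(s) along the gradient, pixels.
#' @return Oxygen concentration, \%O2.
#' @export
microfluidic_gradient <- function(x_px) {
  21.38 / (1 + exp(0.031 * (x_px - 200)))
}

#' @rdname microfluidic_gradient
#' @return For the derivative: dC/dx in \%O2 per um.
#' @export
microfluidic_gradient_deriv <- function(x_px) {
  e <- exp(0.031 * (x_px - 200))
  -21.38 * 0.031 * e / (1 + e)^2 / 10 # per um (10 um/pixel)
}

#' Generate cell positions with a ring morphology
#'
#' Inhomogeneous Poisson point process with radial intensity
#' `baseline + (peak - baseline) * exp(-(r - position)^2/(2 width^2))`
#' inside a disk, sampled by thinning a uniform process, so expected
#' annulus counts are exactly the integrated intensity.
#'
#' @param position ring radius, um.
#' @param width ring Gaussian width, um.
#' @param peak peak density at the ring, cells/mm^2.
#' @param baseline bulk density behind/ahead, cells/mm^2.
#' @param field_radius disk radius of the observation field, um.
#' @return data.frame with columns `x`, `y` (um, centered on the colony).
#' @export
gen_ring_positions <- function(position = 1500, width = 150, peak = 1900,
                               baseline = 475, field_radius = 2500) {
  stopifnot(peak >= 0, baseline >= 0, width > 0)
  lam_max <- max(peak, baseline) / 1e6 # cells per um^2
  area <- pi * field_radius^2
  n <- stats::rpois(1, lam_max * area)
  th <- stats::runif(n, 0, 2 * pi)
  r <- field_radius * sqrt(stats::runif(n))
  lam <- (baseline + (peak - baseline) *
            exp(-(r - position)^2 / (2 * width^2))) / 1e6
  keep <- stats::runif(n) < lam / lam_max
  data.frame(x = (r * cos(th))[keep], y = (r * sin(th))[keep])
}

#' Expected ring-generator count
#'
#' Closed-form expectation of the number of points produced by
#' [gen_ring_positions()] (integral of the radial intensity over the disk).
#'
#' @inheritParams gen_ring_positions
#' @return Expected count.
#' @export
gen_ring_expected_count <- function(position = 1500, width = 150,
                                    peak = 1900, baseline = 475,
                                    field_radius = 2500) {
  f <- function(r) {
    2 * pi * r * (baseline + (peak - baseline) *
                    exp(-(r - position)^2 / (2 * width^2))) / 1e6
  }
  stats::integrate(f, 0, field_radius, rel.tol = 1e-10)$value
}

#' Generate 2-D random-walk tracks with optional drift
#'
#' Discrete walks with independent Gaussian per-step displacements of
#' variance `2 D dt` per axis plus `drift * dt`, emulating tracked cell
#' trajectories at a uniform frame interval.
#'
#' @param n number of tracks.
#' @param duration track duration, min.
#' @param frame_interval frame interval, min.
#' @param D diffusion constant, um^2/min.
#' @param drift function(x, y) returning a length-2 drift vector (um/min),
#'   or a length-2 constant vector, or `"radial"` with `drift_speed`
#'   outward from `center`.
#' @param drift_speed outward drift speed when `drift = "radial"`, um/min.
#' @param center origin for radial drift, um.
#' @param start_box length-2 numeric: starts drawn uniformly in
#'   `[-start_box/2, start_box/2]` around `center`.
#' @return A [track_set()].
#' @export
gen_tracks <- function(n = 100, duration = 60, frame_interval = 0.25,
                       D = 28.2, drift = c(0, 0), drift_speed = 1,
                       center = c(0, 0), start_box = c(2000, 2000)) {
  stopifnot(D >= 0)
  nsteps <- round(duration / frame_interval)
  sd_step <- sqrt(2 * D * frame_interval)
  tvec <- seq(0, by = frame_interval, length.out = nsteps + 1)
  tracks <- vector("list", n)
  const_drift <- !is.function(drift) && !identical(drift, "radial")
  for (i in seq_len(n)) {
    x0 <- center[1] + stats::runif(1, -0.5, 0.5) * start_box[1]
    y0 <- center[2] + stats::runif(1, -0.5, 0.5) * start_box[2]
    if (const_drift) {
      x <- x0 + c(0, cumsum(drift[1] * frame_interval +
                              stats::rnorm(nsteps, 0, sd_step)))
      y <- y0 + c(0, cumsum(drift[2] * frame_interval +
                              stats::rnorm(nsteps, 0, sd_step)))
    } else {
      x <- numeric(nsteps + 1); y <- numeric(nsteps + 1)
      x[1] <- x0; y[1] <- y0
      gx <- stats::rnorm(nsteps, 0, sd_step)
      gy <- stats::rnorm(nsteps, 0, sd_step)
      for (s in seq_len(nsteps)) {
        dv <- if (is.function(drift)) {
          drift(x[s], y[s])
        } else {
          rx <- x[s] - center[1]; ry <- y[s] - center[2]
          rr <- sqrt(rx^2 + ry^2)
          if (rr > 0) drift_speed * c(rx, ry) / rr else c(0, 0)
        }
        x[s + 1] <- x[s] + dv[1] * frame_interval + gx[s]
        y[s + 1] <- y[s] + dv[2] * frame_interval + gy[s]
      }
    }
    tracks[[i]] <- data.frame(t = tvec, x = x, y = y)
  }
  track_set(tracks, frame_interval)
}

#' Generate Stern-Volmer sensor image pairs
#'
#' Forward model of the sensing film: `I = Bg + (I0 - Bg)/(1 + K C)` plus
#' Gaussian noise, together with the 21 \%O2 reference image from the same
#' parameter maps.
#'
#' @param C_map oxygen map, \%O2 (matrix).
#' @param K_map,Bg_map,I0_map parameter maps (matrices or scalars,
#'   recycled).
#' @param noise_sd Gaussian noise s.d., a.u.
#' @return List with `I` (at `C_map`) and `I21` (at 21 \%O2), matrices.
#' @export
gen_sensor_images <- function(C_map, K_map = 4, Bg_map = 123, I0_map = 2673,
                              noise_sd = 0) {
  stopifnot(all(C_map >= 0), all(C_map <= 21))
  d <- dim(C_map)
  expand <- function(m) if (length(m) == 1) matrix(m, d[1], d[2]) else m
  K <- expand(K_map); Bg <- expand(Bg_map); I0 <- expand(I0_map)
  I <- intensity_from_oxygen(C_map, K, Bg, I0)
  I21 <- intensity_from_oxygen(21, K, Bg, I0)
  if (noise_sd > 0) {
    I <- I + stats::rnorm(length(I), 0, noise_sd)
    I21 <- I21 + stats::rnorm(length(I21), 0, noise_sd)
  }
  list(I = matrix(I, d[1], d[2]), I21 = matrix(I21, d[1], d[2]))
}

#' Initial density/oxygen profiles for the PDE models
#'
#' `kind = "spot"`: the three-tier radial step profile matching the
#' lattice-model seeding at matched areal densities (1667, 833 and 500
#' cells/mm^2 out to 300, 600 and 900 um), with saturated oxygen.
#' `kind = "near_wave"`: a profile close to the expected traveling wave —
#' the explicit large-bias profile when available, otherwise a plateau
#' with the critical leading-edge decay `exp(-sqrt(r0/D) z)` — together
#' with a quasi-static oxygen solve consistent with it.
#'
#' @param kind `"spot"` or `"near_wave"`.
#' @param params a [mean_field_params()].
#' @param dx grid spacing, um.
#' @param L domain size, um (defaults to `params$L`).
#' @param geometry `"planar"` or `"radial"` (spot defaults to radial,
#'   near_wave to planar).
#' @param front_x initial front position for `near_wave`, um.
#' @param plateau plateau density behind the front, cells/mm^2.
#' @return List with `rho` and `C` [scalar_field1d()] objects.
#' @export
gen_initial_profiles <- function(kind = c("spot", "near_wave"),
                                 params = mean_field_params(), dx = 1,
                                 L = NULL, geometry = NULL,
                                 front_x = 2000, plateau = 500) {
  kind <- match.arg(kind)
  if (is.null(L)) L <- params$L
  if (is.null(geometry)) {
    geometry <- if (kind == "spot") "radial" else "planar"
  }
  n <- round(L / dx)
  xs <- (seq_len(n) - 0.5) * dx
  if (kind == "spot") {
    rho <- ifelse(xs <= 300, 1000 / 0.6,
                  ifelse(xs <= 600, 1000 / 1.2, ifelse(xs <= 900, 500, 0)))
    rho_f <- scalar_field1d(rho, dx, geometry)
    C_f <- scalar_field1d(rep(params$Cboundary, n), dx, geometry)
    return(list(rho = rho_f, C = C_f))
  }
  z <- xs - front_x
  large_bias <- params$a0 > sqrt(params$r0 * params$D)
  if (large_bias) {
    prof <- explicit_profile(params$a0, params$r0, params$D, "elementary",
                             A = plateau)
    rho <- prof$rho(z)
  } else {
    mu <- sqrt(params$r0 / params$D)
    rho <- plateau * ifelse(z < 0, 1, exp(-mu * z))
  }
  rho_f <- scalar_field1d(rho, dx, geometry)
  C_f <- quasi_static_oxygen(rho_f, params)
  list(rho = rho_f, C = C_f)
}
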