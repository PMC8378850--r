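#' Radial density profile of a point cloud
#'
#' Counts cell positions within concentric annuli ("crowns") around a
#' center and divides by the annulus area to obtain densities in
#' cells/mm^2.
#'
#' @param positions matrix or data.frame with columns `x`, `y` (um).
#' @param center length-2 numeric (um); default: center of mass of the
#'   positions.
#' @param bin_width annulus width, um.
#' @param max_r outermost radius, um; default: maximum distance present.
#' @return data.frame of class `radial_profile` with `bin_center` (um),
#'   `density` (cells/mm^2) and `count`.
#' @export
radial_profile <- function(positions, center = NULL, bin_width = 50,
                           max_r = NULL) {
  positions <- as.data.frame(positions)
  if (nrow(positions) < 1) stop("radial_profile: need at least one position")
  if (is.null(center)) center <- c(mean(positions$x), mean(positions$y))
  r <- sqrt((positions$x - center[1])^2 + (positions$y - center[2])^2)
  if (is.null(max_r)) max_r <- max(r) + bin_width
  breaks <- seq(0, max_r + bin_width, by = bin_width)
  if (any(diff(breaks) <= 0)) stop("radial_profile: zero-area bin")
  counts <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  area_mm2 <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2) / 1e6
  out <- data.frame(bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    density = counts / area_mm2, count = counts)
  attr(out, "center") <- center
  attr(out, "n") <- nrow(positions)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Fit a Gaussian ring with a non-zero baseline to a radial profile
#'
#' Bins below 500 cells/mm^2 are stripped first (to avoid the asymmetric
#' near-zero baselines behind and ahead of the ring), then
#' `density = baseline + height * exp(-(r - position)^2 / (2 width^2))`
#' is fitted by nonlinear least squares.
#'
#' @param profile a [radial_profile()] (or data.frame with `bin_center`,
#'   `density`).
#' @param strip_below densities below this value are discarded before the
#'   fit, cells/mm^2.
#' @return List of class `ring_fit`: `position`, `width` (um),
#'   `peak_density` (baseline + height), `baseline_density` (cells/mm^2),
#'   `converged`.
#' @export
fit_ring <- function(profile, strip_below = 500) {
  keep <- profile$density >= strip_below
  if (sum(keep) < 5) {
    stop("fit_ring: fewer than 5 bins remain after stripping below ",
         strip_below, " cells/mm^2")
  }
  d <- profile[keep, ]
  i0 <- which.max(d$density)
  start <- list(baseline = max(min(d$density), 1),
                height = max(d$density) - min(d$density) + 1,
                position = d$bin_center[i0],
                width = 2 * mean(diff(profile$bin_center)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      density ~ baseline + height * exp(-(bin_center - position)^2 /
                                          (2 * width^2)),
      data = d, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(position = start$position, width = start$width,
                          peak_density = start$baseline + start$height,
                          baseline_density = start$baseline,
                          converged = FALSE), class = "ring_fit"))
  }
  cf <- as.list(stats::coef(fit))
  structure(list(position = cf$position, width = abs(cf$width),
                 peak_density = cf$baseline + cf$height,
                 baseline_density = cf$baseline,
                 converged = TRUE), class = "ring_fit")
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf("<ring_fit> position %.0f um, width %.0f um, peak %.0f, baseline %.0f cells/mm^2\n",
              x$position, x$width, x$peak_density, x$baseline_density))
  invisible(x)
}

#' Ring expansion speed from a sequence of ring fits
#'
#' Least-squares slope of ring position versus time, optionally excluding
#' the transient while the ring is still inside the initial spot.
#'
#' @param times fit times, min.
#' @param positions ring positions, um.
#' @param exclude_inside positions at or below this radius (um) are
#'   treated as transient and excluded (default 0 = keep everything).
#' @return Speed, um/min.
#' @export
ring_speed <- function(times, positions, exclude_inside = 0) {
  keep <- is.finite(positions) & positions > exclude_inside
  if (sum(keep) < 3) stop("ring_speed: need at least 3 usable fits")
  unname(stats::coef(stats::lm(positions[keep] ~ times[keep]))[2])
}

#' Track container
#'
#' @param tracks list of per-track data.frames with columns `t` (min),
#'   `x`, `y` (um).
#' @param frame_interval frame interval, min.
#' @return Object of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval) {
  for (tr in tracks) {
    if (nrow(tr) < 2) stop("track_set: each track needs >= 2 points")
    if (any(diff(tr$t) <= 0)) stop("track_set: time must increase")
  }
  structure(list(tracks = tracks, frame_interval = frame_interval),
            class = "track_set")
}

#' Radial velocity bias of tracks, binned by distance
#'
#' Displacements over a time lag `dt` are projected on the radial direction
#' (relative to `center`) at the segment start and divided by `dt`; the
#' resulting velocity biases are averaged within distance bins. Positive
#' values mean outward motion. Bins without data are reported `NA`.
#'
#' @param tracks a [track_set()].
#' @param center length-2 numeric, um.
#' @param lag time lag, min (multiple of the frame interval).
#' @param breaks distance bin breaks, um.
#' @param direction `"radial"` or `"x"` (gradient direction, for
#'   microfluidic geometry; `center[1]` then only sets the origin).
#' @return data.frame with `bin_center`, `bias` (um/min), `sem`, `n`.
#' @export
radial_bias <- function(tracks, center, lag, breaks,
                        direction = c("radial", "x")) {
  direction <- match.arg(direction)
  step <- max(1L, round(lag / tracks$frame_interval))
  proj <- dist0 <- numeric(0)
  for (tr in tracks$tracks) {
    n <- nrow(tr)
    if (n <= step) next
    i <- seq_len(n - step)
    dxv <- tr$x[i + step] - tr$x[i]
    dyv <- tr$y[i + step] - tr$y[i]
    dt <- tr$t[i + step] - tr$t[i]
    if (direction == "radial") {
      rx <- tr$x[i] - center[1]; ry <- tr$y[i] - center[2]
      rr <- sqrt(rx^2 + ry^2)
      ok <- rr > 0
      proj <- c(proj, (dxv[ok] * rx[ok] + dyv[ok] * ry[ok]) / rr[ok] / dt[ok])
      dist0 <- c(dist0, rr[ok])
    } else {
      proj <- c(proj, dxv / dt)
      dist0 <- c(dist0, tr$x[i] - center[1])
    }
  }
  bin <- findInterval(dist0, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  out <- data.frame(bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    bias = NA_real_, sem = NA_real_, n = 0L)
  for (b in seq_len(nb)) {
    v <- proj[bin == b]
    out$n[b] <- length(v)
    if (length(v)) {
      out$bias[b] <- mean(v)
      out$sem[b] <- stats::sd(v) / sqrt(length(v))
    }
  }
  out
}

#' Per-track effective diffusion constant
#'
#' End-to-end estimator: squared net displacement over the whole
#' trajectory, divided by the trajectory duration and by 4. Note that this
#' estimator conflates drift and diffusion: a pure drift of speed v over
#' duration T yields v^2 T / 4.
#'
#' @param track data.frame with `t` (min), `x`, `y` (um).
#' @return Diffusion constant, um^2/min.
#' @export
diffusion_constant <- function(track) {
  n <- nrow(track)
  T <- track$t[n] - track$t[1]
  if (T <= 0) stop("diffusion_constant: zero-duration track")
  ((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2) / (4 * T)
}

#' Oxygen concentration sampled at the ring position over time
#'
#' Bilinear interpolation of an oxygen kymograph `C(t, r)` at the ring
#' trajectory `(t_i, r_i)`.
#'
#' @param ring_t,ring_r ring times (min) and positions (um).
#' @param kymo_t kymograph times, min.
#' @param kymo_r kymograph positions, um.
#' @param kymo matrix `length(kymo_t)` x `length(kymo_r)` of \%O2.
#' @return Numeric vector of C at the ring, one per ring time.
#' @export
oxygen_at_ring <- function(ring_t, ring_r, kymo_t, kymo_r, kymo) {
  if (any(ring_r < min(kymo_r) | ring_r > max(kymo_r), na.rm = TRUE)) {
    stop("oxygen_at_ring: ring position outside the oxygen field extent")
  }
  if (any(ring_t < min(kymo_t) | ring_t > max(kymo_t))) {
    stop("oxygen_at_ring: ring times outside the kymograph range")
  }
  vapply(seq_along(ring_t), function(i) {
    if (!is.finite(ring_r[i])) return(NA_real_)
    it <- findInterval(ring_t[i], kymo_t, all.inside = TRUE)
    ir <- findInterval(ring_r[i], kymo_r, all.inside = TRUE)
    ft <- (ring_t[i] - kymo_t[it]) / (kymo_t[it + 1] - kymo_t[it])
    fr <- (ring_r[i] - kymo_r[ir]) / (kymo_r[ir + 1] - kymo_r[ir])
    (1 - ft) * ((1 - fr) * kymo[it, ir] + fr * kymo[it, ir + 1]) +
      ft * ((1 - fr) * kymo[it + 1, ir] + fr * kymo[it + 1, ir + 1])
  }, numeric(1))
}

#' Radial oxygen profile of a Potts oxygen field
#'
#' Ring-averages a 2-D oxygen matrix around the lattice center.
#'
#' @param o2 oxygen matrix, \%O2.
#' @param px_um pixel size, um.
#' @param bin_width radial bin width, um.
#' @return data.frame with `r` (um) and `C` (\%O2).
#' @export
o2_radial_profile <- function(o2, px_um = 10, bin_width = 50) {
  n <- nrow(o2); m <- ncol(o2)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  yy <- matrix(seq_len(n), n, m)
  xx <- matrix(seq_len(m), n, m, byrow = TRUE)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2) * px_um
  breaks <- seq(0, max(r) + bin_width, by = bin_width)
  bin <- findInterval(r, breaks, rightmost.closed = TRUE)
  Cm <- vapply(split(as.vector(o2), bin), mean, 0)
  idx <- as.integer(names(Cm))
  data.frame(r = (breaks[idx] + breaks[idx + 1]) / 2, C = unname(Cm))
}
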