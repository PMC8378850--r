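#' Closed-form traveling-wave speed of the Go-or-Grow model
#'
#' The elementary Go-or-Grow model (advection at constant speed `a0` below
#' the oxygen threshold, division at rate `r0` above it) admits explicit
#' traveling waves whose speed has a closed form with a dichotomy on the
#' relative size of the aerotactic bias `a0` and the Fisher half-speed
#' `sqrt(r0 * D)`:
#' \deqn{\sigma = a_0 + r_0 D / a_0 \quad (a_0 \ge \sqrt{r_0 D}), \qquad
#'       \sigma = 2\sqrt{r_0 D} \quad (a_0 \le \sqrt{r_0 D}).}
#' The fraction `phi = 2*sqrt(r0*D)/sigma` measures the relative
#' contribution of division and diffusion to the overall speed (`phi = 1`
#' for a pure reaction-diffusion, pulled wave).
#'
#' @param a0 aerotactic advection speed, um/min (>= 0).
#' @param r0 division rate, 1/min.
#' @param D cell diffusion constant, um^2/min.
#' @return List of class `wave_speed_result` with `sigma` (um/min),
#'   `regime` (`"small_bias"` or `"large_bias"`), and `phi` in (0, 1].
#' @examples
#' wave_speed(a0 = 1, r0 = log(2) / 480, D = 30) # sigma = 1.04, phi = 40%
#' @export
wave_speed <- function(a0, r0, D) {
  stopifnot(a0 >= 0, r0 > 0, D > 0)
  fisher_half <- sqrt(r0 * D)
  if (a0 > fisher_half) {
    sigma <- a0 + r0 * D / a0
    regime <- "large_bias"
  } else {
    sigma <- 2 * fisher_half
    regime <- "small_bias"
  }
  structure(list(sigma = sigma, regime = regime,
                 phi = 2 * fisher_half / sigma),
            class = "wave_speed_result")
}

#' @export
print.wave_speed_result <- function(x, ...) {
  cat(sprintf("sigma = %.4g um/min (%s), phi = %.3g\n",
              x$sigma, x$regime, x$phi))
  invisible(x)
}

#' Shape-based wave-speed estimate
#'
#' Integrating the traveling-wave equation over the line balances the mass
#' flux through the front against the total division in the wave. With
#' division restricted to (roughly) the front half of the ring this yields
#' the approximation `sigma = r0 * L_ring * density_ratio / 2`, an estimate
#' of the speed based solely on the shape of the density profile.
#'
#' @param L_ring ring width, um.
#' @param density_ratio peak-to-bulk density ratio (rho_hat / rho(-Inf)).
#' @param r0 division rate, 1/min.
#' @return Speed estimate, um/min.
#' @examples
#' shape_speed_estimate(300, 4, log(2) / 480) # ~ 0.9 um/min
#' @export
shape_speed_estimate <- function(L_ring, density_ratio, r0) {
  stopifnot(L_ring >= 0, density_ratio > 0, r0 > 0)
  r0 * L_ring * density_ratio / 2
}

#' Explicit traveling-wave density profile
#'
#' Piecewise-exponential traveling-wave profiles of the Go-or-Grow model in
#' the moving frame `z = x - sigma * t`, with the oxygen threshold placed at
#' `z = 0`. The `"elementary"` variant (single threshold) is a plateau `A`
#' for `z < 0` and `A * exp(-a0 * z / D)` for `z > 0` (decay rate
#' `mu = a0 / D` from the flux-jump relation at the threshold). The
#' `"two_threshold"` variant has three pieces separated at `z = -h` and
#' `z = 0`, with
#' `B = (sigma - mu*D)/(sigma - a0)`, `E = (mu*D - a0)/(sigma - a0)` and
#' `mu = (sigma + sqrt(sigma^2 - 4*D*r0))/(2*D)`. (Sign convention: the
#' elementary model's decay exponent is written `mu_minus = -a0/D` in the
#' derivation; here `mu` always denotes the positive decay rate of
#' `rho = A*exp(-mu*z)` for `z > 0`, which for the elementary wave equals
#' `a0/D` because `mu_plus * D = a0` exactly at `sigma = a0 + r0*D/a0`.)
#'
#' Only large-bias profiles are constructed: in the small-bias regime the
#' pure-exponential ansatz fails (at equality `a0 = sqrt(r0*D)` the leading
#' edge takes the degenerate form `(c1*z + c2) * exp(-sqrt(r0/D)*z)`, and
#' away from equality no explicit profile is available).
#'
#' @param a0,r0,D model parameters (um/min, 1/min, um^2/min).
#' @param variant `"elementary"` or `"two_threshold"`.
#' @param h threshold gap, um (two-threshold variant only); defaults to the
#'   gap implied by [two_threshold_speed()] at the given parameters if a
#'   full parameter set is supplied via `params`.
#' @param sigma wave speed; defaults to the closed-form elementary speed.
#' @param A amplitude (density scale, cells/mm^2).
#' @return Object of class `traveling_wave_profile`: list with the
#'   constants and a function `rho(z)` evaluable on any grid.
#' @export
explicit_profile <- function(a0, r0, D, variant = c("elementary",
                                                    "two_threshold"),
                             h = NULL, sigma = NULL, A = 1) {
  variant <- match.arg(variant)
  fisher_half <- sqrt(r0 * D)
  if (a0 <= fisher_half) {
    stop("explicit_profile: small-bias regime; no pure-exponential profile")
  }
  if (is.null(sigma)) sigma <- a0 + r0 * D / a0
  if (sigma^2 < 4 * r0 * D) stop("explicit_profile: sigma below Fisher speed")
  mu <- (sigma + sqrt(sigma^2 - 4 * D * r0)) / (2 * D)
  if (variant == "elementary") {
    B <- 1; E <- 0; h <- Inf
    fun <- function(z) A * ifelse(z < 0, 1, exp(-mu * z))
  } else {
    if (is.null(h)) stop("explicit_profile: two_threshold variant needs h")
    B <- (sigma - mu * D) / (sigma - a0)
    E <- (mu * D - a0) / (sigma - a0)
    k <- (sigma - a0) / D
    plateau <- B + E * exp(k * h)
    fun <- function(z) {
      A * ifelse(z < -h, plateau,
                 ifelse(z < 0, B + E * exp(-k * z), exp(-mu * z)))
    }
  }
  structure(list(mu = mu, A = A, B = B, E = E, h = h, sigma = sigma,
                 a0 = a0, r0 = r0, D = D, variant = variant, rho = fun),
            class = "traveling_wave_profile")
}

#' @export
print.traveling_wave_profile <- function(x, ...) {
  cat(sprintf("<traveling_wave_profile> %s, sigma = %.4g, mu = %.4g 1/um, h = %g um\n",
              x$variant, x$sigma, x$mu, x$h))
  invisible(x)
}

# Residual of the two-threshold implicit speed equation: C(-h) - C0p, with
# the piecewise oxygen profile re-derived from the consumption ODE
# Doxy C'' + sigma C' = b0 rho(z) and continuity of C and C' at z = 0, -h.
two_threshold_residual <- function(sigma, params) {
  a0 <- params$a0; r0 <- params$r0; D <- params$D
  Doxy <- params$Doxy; b0 <- params$b0
  C0 <- params$C0; C0p <- params$C0p; Cinf <- params$Cboundary
  disc <- sigma^2 - 4 * D * r0
  if (disc < 0) return(list(residual = NA_real_))
  mu <- (sigma + sqrt(disc)) / (2 * D)
  B <- (sigma - mu * D) / (sigma - a0)
  E <- (mu * D - a0) / (sigma - a0)
  k <- (sigma - a0) / D
  arg <- a0 * (sigma - mu * D) / (sigma * (a0 - mu * D))
  if (!is.finite(arg) || arg <= 0) return(list(residual = NA_real_))
  h <- log(arg) / k
  if (!is.finite(h) || h <= 0) return(list(residual = NA_real_))
  s <- sigma / Doxy
  # particular-solution coefficients (density scale folded into A)
  Ff <- b0 * (B + E * exp(k * h)) / sigma
  H <- b0 * B / sigma
  I <- b0 * E / (k * (Doxy * k - sigma))
  L <- b0 / (mu * (mu * Doxy - sigma))
  # unknowns (A, K) from C' continuity at z = 0 and z = -h;
  # M = C0 - Cinf - L*A and J = C0 - I*A - K close the system.
  # C'(0-) = H*A - I*k*A - s*K ; C'(0+) = -mu*L*A - s*M
  # C'(-h-) = Ff*A ; C'(-h+) = H*A - I*k*A*exp(k*h) - s*K*exp(s*h)
  a11 <- H - I * k + mu * L - s * L
  a12 <- -s
  rhs1 <- s * (Cinf - C0)
  a21 <- Ff - H + I * k * exp(k * h)
  a22 <- s * exp(s * h)
  rhs2 <- 0
  det <- a11 * a22 - a12 * a21
  if (!is.finite(det) || abs(det) < 1e-300) return(list(residual = NA_real_))
  A <- (rhs1 * a22 - a12 * rhs2) / det
  K <- (a11 * rhs2 - a21 * rhs1) / det
  J <- C0 - I * A - K
  Cmh <- -H * A * h + I * A * exp(k * h) + J + K * exp(s * h)
  list(residual = Cmh - C0p, h = h, A = A, mu = mu, B = B, E = E, k = k,
       s = s, Ff = Ff, H = H, I = I, J = J, K = K, L = L,
       M = C0 - L * A - Cinf, G = C0p + Ff * A * h, Cinf = Cinf)
}

#' Wave speed of the two-threshold Go-or-Grow model
#'
#' In the variant with a second threshold `C0p` below which cells stop
#' responding to gradients (and with constant per-cell consumption
#' `b(C) = b0`, oxygen allowed to relax unconstrained below zero), the
#' traveling-wave speed satisfies an implicit equation coupling the
#' threshold gap `h` to the piecewise oxygen profile. The root is located
#' inside `[2*sqrt(r0*D), a0 + r0*D/a0]` and found by dichotomy (bisection)
#' to relative tolerance `tol`.
#'
#' @param params a [mean_field_params()]; must be a large-bias set
#'   (`a0 > sqrt(r0 * D)`).
#' @param tol relative tolerance of the bisection.
#' @return List with `sigma` (um/min), `h` (threshold gap, um), and
#'   `sigma_elementary` (closed-form single-threshold speed).
#' @export
two_threshold_speed <- function(params = mean_field_params(), tol = 1e-6) {
  a0 <- params$a0; r0 <- params$r0; D <- params$D
  if (a0 <= sqrt(r0 * D)) {
    stop("two_threshold_speed: requires a large-bias parameter set ",
         "(a0 > sqrt(r0*D))")
  }
  lo0 <- 2 * sqrt(r0 * D)
  hi0 <- a0 + r0 * D / a0
  width <- hi0 - lo0
  lo <- lo0 + 1e-9 * width
  f <- function(s) {
    r <- two_threshold_residual(s, params)$residual
    # the residual diverges to -Inf at the upper endpoint (h -> Inf);
    # overflow there reads as a negative residual
    if (!is.finite(r)) -Inf else r
  }
  flo <- f(lo)
  if (!is.finite(flo) || flo < 0) {
    stop(sprintf(paste0("two_threshold_speed: no sign change on the bracket ",
                        "[%.6g, %.6g]; residual at the lower endpoint %.6g ",
                        "(the aerotaxis band is too weak to support a wave ",
                        "faster than the Fisher speed)"), lo0, hi0, flo))
  }
  # the root can sit extremely close to the upper endpoint when the
  # two-threshold correction is negligible; refine the bracket geometrically
  hi <- NA_real_
  for (k in 1:14) {
    s <- hi0 - width * 10^(-k)
    fs <- f(s)
    if (fs < 0) { hi <- s; break }
    lo <- s; flo <- fs
  }
  if (is.na(hi)) { # root within 1e-14 of the elementary speed
    sigma <- hi0 - width * 1e-14
  } else {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
      if ((hi - lo) / mid < tol) break
    }
    sigma <- (lo + hi) / 2
  }
  res <- two_threshold_residual(sigma, params)
  c(list(sigma = sigma, sigma_elementary = wave_speed(a0, r0, D)$sigma),
    res[setdiff(names(res), "residual")])
}

#' Analytic two-threshold traveling-wave fields on a grid
#'
#' Evaluates the full analytic traveling-wave solution of the specific
#' two-threshold model (constant per-cell consumption, oxygen
#' unconstrained) — both the piecewise density and the piecewise oxygen
#' profile, at the amplitude the oxygen-consistency condition selects.
#' Used to initialize cross-check simulations at the exact wave.
#'
#' @param params a large-bias [mean_field_params()].
#' @param x lab-frame coordinates, um.
#' @param front_x position of the upper threshold (`C = C0`), um.
#' @return List with `rho` and `C` numeric vectors on `x`, plus the
#'   [two_threshold_speed()] solution under `wave`.
#' @export
two_threshold_wave_fields <- function(params, x, front_x) {
  w <- two_threshold_speed(params)
  z <- x - front_x
  A <- w$A
  rho <- ifelse(z < -w$h, A * (w$B + w$E * exp(w$k * w$h)),
                ifelse(z < 0, A * (w$B + w$E * exp(-w$k * z)),
                       A * exp(-w$mu * z)))
  C <- ifelse(z < -w$h, w$Ff * A * z + w$G,
              ifelse(z < 0,
                     w$H * A * z + w$I * A * exp(-w$k * z) + w$J +
                       w$K * exp(-w$s * z),
                     w$L * A * exp(-w$mu * z) + w$M * exp(-w$s * z) +
                       w$Cinf))
  list(rho = rho, C = C, wave = w)
}

#' Division-contribution fraction phi over a parameter grid
#'
#' Computes `phi = 2*sqrt(r0*D)/sigma` on a grid of aerotactic bias `a0`
#' and population doubling time, at fixed diffusion constant, along with
#' the pushed/pulled separatrix `a0 = sqrt(r0*D)`.
#'
#' @param a0 vector of advection speeds, um/min.
#' @param doubling_h vector of doubling times, hours.
#' @param D diffusion constant, um^2/min.
#' @return data.frame with `a0`, `doubling_h`, `sigma`, `phi`, `regime`,
#'   and `a0_separatrix` (the pushed/pulled boundary at that doubling time).
#' @export
phi_grid <- function(a0 = seq(0.1, 2, by = 0.05),
                     doubling_h = seq(2, 24, by = 0.5), D = 30) {
  grid <- expand.grid(a0 = a0, doubling_h = doubling_h)
  r0 <- log(2) / (grid$doubling_h * 60)
  ws <- mapply(function(a, r) {
    w <- wave_speed(a, r, D)
    c(w$sigma, w$phi, w$regime == "large_bias")
  }, grid$a0, r0)
  grid$sigma <- ws[1, ]
  grid$phi <- ws[2, ]
  grid$regime <- ifelse(ws[3, ] == 1, "large_bias", "small_bias")
  grid$a0_separatrix <- sqrt(r0 * D)
  grid
}

#' Lattice-model unit conversion chain
#'
#' Reproduces the arithmetic converting measured per-cell quantities into
#' the lattice model's arbitrary units: a 10 um pixel under `confinement_um`
#' of medium at `solubility_uM` holds `mol_per_pixel` of O2 at saturation,
#' defined to be 21 units; cells occupy 2 pixels and one MCS is `step_s`
#' seconds.
#'
#' @param cell_O2_mol_per_s molar O2 consumption per cell, mol/(cell s).
#' @param px_um pixel size, um.
#' @param step_s seconds per MCS.
#' @param confinement_um vertical confinement height, um.
#' @param solubility_uM oxygen solubility of the medium, umol/L.
#' @param rho_star reference cell density for the boundary-flux figure,
#'   cells/mm^2.
#' @param doubling_h population doubling time, hours.
#' @return List with `mol_per_pixel` (mol at 21 units),
#'   `consumption_per_pixel` (units pixel^-1 step^-1), `boundary_flux`
#'   (mol m^-2 s^-1 at `rho_star`), `division_prob` (per MCS) and
#'   `division_prob_printed` (one significant figure).
#' @examples
#' potts_unit_conversions() # consumption ~ 0.1, flux 6e-8, division 3e-6
#' @export
potts_unit_conversions <- function(cell_O2_mol_per_s = 1.2e-16, px_um = 10,
                                   step_s = 0.1, confinement_um = 50,
                                   solubility_uM = 250, rho_star = 500,
                                   doubling_h = 8) {
  stopifnot(cell_O2_mol_per_s > 0, px_um > 0, step_s > 0, confinement_um > 0,
            solubility_uM > 0)
  # volume above one pixel (L) * solubility (mol/L)
  vol_L <- (px_um * 1e-6)^2 * (confinement_um * 1e-6) * 1e3
  mol_per_pixel <- vol_L * solubility_uM * 1e-6
  units_per_mol <- 21 / mol_per_pixel
  pixels_per_cell <- 2
  consumption_per_pixel <-
    cell_O2_mol_per_s * step_s / pixels_per_cell * units_per_mol
  # outward flux at the reference density: b * rho_star in mol m^-2 s^-1
  boundary_flux <- cell_O2_mol_per_s * rho_star * 1e6
  division_prob <- 1 / (doubling_h * 3600 / step_s)
  list(mol_per_pixel = mol_per_pixel,
       consumption_per_pixel = consumption_per_pixel,
       boundary_flux = boundary_flux,
       division_prob = division_prob,
       division_prob_printed = signif(division_prob, 1))
}
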