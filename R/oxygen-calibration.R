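#' Stern-Volmer forward model
#'
#' Intensity of an oxygen-quenched luminescent film over a background:
#' `I(C) = Bg + (I0 - Bg) / (1 + K * C)`, so that
#' `(I0 - Bg)/(I(C) - Bg) = 1 + K*C`.
#'
#' @param C oxygen concentration(s), \%O2.
#' @param K Stern-Volmer constant, 1/\%O2.
#' @param Bg background intensity, a.u.
#' @param I0 zero-oxygen intensity, a.u.
#' @return Intensity, a.u.
#' @export
intensity_from_oxygen <- function(C, K, Bg, I0) {
  Bg + (I0 - Bg) / (1 + K * C)
}

#' Invert the Stern-Volmer relation for oxygen
#'
#' @param I measured intensity, a.u.
#' @param K,Bg,I0 Stern-Volmer parameters.
#' @return Oxygen concentration, \%O2 (`NA` where `I <= Bg`).
#' @export
oxygen_from_intensity <- function(I, K, Bg, I0) {
  out <- ((I0 - Bg) / (I - Bg) - 1) / K
  out[I <= Bg] <- NA_real_
  out
}

#' Fit the Stern-Volmer relation to a calibration ramp
#'
#' Nonlinear least-squares fit of `I(C) = Bg + (I0 - Bg)/(1 + K*C)` with
#' `K`, `Bg` and `I0` free, for one region of interest of a sensing film
#' exposed to a ramp of known oxygen steps.
#'
#' @param C oxygen levels of the ramp, \%O2 (>= 3 distinct levels,
#'   spanning a near-zero and an atmospheric step).
#' @param I measured mean ROI intensities, a.u.
#' @return List of class `calibration_model`: `K`, `Bg`, `I0`, `residuals`,
#'   `converged`.
#' @export
fit_stern_volmer <- function(C, I) {
  stopifnot(length(C) == length(I))
  if (length(unique(C)) < 3) {
    stop("fit_stern_volmer: need at least 3 distinct oxygen levels")
  }
  if (diff(range(I)) < .Machine$double.eps * max(abs(I))) {
    stop("fit_stern_volmer: degenerate (constant) intensities")
  }
  d <- data.frame(C = C, I = I)
  Imax <- max(I); Imin <- min(I)
  start <- list(K = 4, Bg = max(Imin - (Imax - Imin) / 20, 0.5 * Imin),
                I0 = Imax)
  fit <- minpack.lm::nlsLM(I ~ Bg + (I0 - Bg) / (1 + K * C), data = d,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- as.list(stats::coef(fit))
  structure(list(K = cf$K, Bg = cf$Bg, I0 = cf$I0,
                 residuals = stats::resid(fit), converged = TRUE),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> K = %.3g %%^-1, Bg = %.4g, I0 = %.4g a.u.\n",
              x$K, x$Bg, x$I0))
  invisible(x)
}

#' Linear background model across the field of view
#'
#' The background `Bg` tracks the illumination pattern and is very
#' correlated with the 21\% reference intensity; a linear relation
#' `Bg = alpha * I21 + beta` is calibrated across ROIs.
#'
#' @param I21 per-ROI intensities at 21 \%O2, a.u.
#' @param Bg per-ROI fitted backgrounds, a.u.
#' @return List with `alpha`, `beta`, `max_rel_dev` (maximum relative
#'   deviation of `Bg` from the line), `fit` (the `lm` object).
#' @export
background_line <- function(I21, Bg) {
  if (length(I21) < 2) stop("background_line: need at least 2 ROIs")
  if (diff(range(I21)) < .Machine$double.eps * max(abs(I21))) {
    stop("background_line: all I(21%) values identical")
  }
  fit <- stats::lm(Bg ~ I21)
  cf <- stats::coef(fit)
  list(alpha = unname(cf[2]), beta = unname(cf[1]),
       max_rel_dev = max(abs(stats::resid(fit)) / abs(Bg)), fit = fit)
}

#' Correct a zero-oxygen reference measured at residual oxygen
#'
#' Applying pure nitrogen still leaves a residual oxygen level `C0star`
#' (about 0.15 \%O2 from leakage), so the measured `I0star` underestimates
#' the true zero-oxygen intensity: `I0 ~ I0star * (1 + K * C0star)`.
#'
#' @param I0star measured intensity at the residual level, a.u.
#' @param K Stern-Volmer constant, 1/\%O2.
#' @param C0star residual oxygen level, \%O2.
#' @return Corrected `I0`, a.u.
#' @export
correct_i0 <- function(I0star, K, C0star = 0.15) {
  I0star * (1 + K * C0star)
}

#' Reconstruct a pixelwise oxygen map from intensity images
#'
#' Implements the covered-film pipeline: from a reference image `I21`
#' (taken at 21 \%O2 immediately before the experiment) a background image
#' `Bg = alpha*I21 + beta` and a reconstituted zero-oxygen image
#' `I0 = R*I21` are built from the uncovered-film globals; a pixelwise
#' `K` map follows as `K = ((I0-Bg)/(I21-Bg) - 1)/21`, and the oxygen map
#' as `C = ((I0-Bg)/(I-Bg) - 1)/K`. Error bars are (max-min)/2 of the
#' recomputed map over a corner search of the stated perturbations:
#' `Bg` by `err_bg` relative to the read-noise-corrected background,
#' `I21` by `err_i21` of the read-noise-corrected signal, and `I0` by the
#' factor `err_i0_factor` (the residual-oxygen correction magnitude).
#'
#' @param I measurement image (matrix), a.u.
#' @param I21 reference image at 21 \%O2, a.u.
#' @param alpha,beta background line globals (see [background_line()]).
#' @param R ratio `I0/I(21%)` of the uncovered film.
#' @param RN camera read noise, a.u.
#' @param err_bg relative background error (0.10 or 0.02 depending on the
#'   setup).
#' @param err_i21 relative drift error on the reference signal.
#' @param err_i0_factor multiplicative uncertainty on `I0`.
#' @return List with `C` (matrix, \%O2), `error` (matrix, (max-min)/2),
#'   `K` (matrix), `n_masked` (pixels with `I <= Bg`).
#' @export
reconstruct_oxygen_map <- function(I, I21, alpha, beta, R, RN = 108,
                                   err_bg = 0.10, err_i21 = 0.02,
                                   err_i0_factor = 1.75) {
  compute <- function(dbg, di21, f0) {
    I21p <- I21 + di21 * (I21 - RN)
    Bg <- alpha * I21p + beta
    Bg <- Bg + dbg * (Bg - RN)
    I0 <- f0 * R * I21p
    K <- ((I0 - Bg) / (I21p - Bg) - 1) / 21
    C <- ((I0 - Bg) / (I - Bg) - 1) / K
    C[I <= Bg] <- NA_real_
    list(C = C, K = K, Bg = Bg)
  }
  nominal <- compute(0, 0, 1)
  corners <- expand.grid(dbg = c(-err_bg, err_bg),
                         di21 = c(-err_i21, err_i21),
                         f0 = c(1, err_i0_factor))
  stack <- lapply(seq_len(nrow(corners)), function(i) {
    compute(corners$dbg[i], corners$di21[i], corners$f0[i])$C
  })
  stack <- c(stack, list(nominal$C))
  lo <- Reduce(pmin, stack)
  hi <- Reduce(pmax, stack)
  list(C = nominal$C, error = (hi - lo) / 2, K = nominal$K,
       n_masked = sum(I <= nominal$Bg))
}
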