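#' Default mean-field / Go-or-Grow model parameters
#'
#' Container for the parameters of the coupled cell-density / oxygen
#' reaction-advection-diffusion system. Oxygen is measured in %O2 on the
#' atmospheric 0--21 scale, cell density in cells/mm^2, lengths in um and
#' times in min.
#'
#' @param D cell diffusion constant, um^2/min.
#' @param Doxy oxygen diffusion constant in medium, um^2/min.
#' @param r0 cell division rate, 1/min (default: doubling time of 8 h).
#' @param b0 per-cell oxygen consumption, \%O2 min^-1 per (cell/mm^2).
#' @param C0 upper oxygen threshold, \%O2: division above, aerotaxis below.
#' @param C0p lower oxygen threshold, \%O2: below it cells no longer sense
#'   gradients (two-threshold variant) and consumption ramps to zero.
#' @param a0 aerotactic advection speed of the Go-or-Grow model, um/min.
#' @param Cboundary oxygen concentration imposed at the far boundary, \%O2.
#' @param L half-domain size, um.
#' @param lambda_mf_max amplitude of the mean-field aerotactic response,
#'   um^2 min^-1 per (\%O2/um) of gradient. The default is calibrated so that
#'   the advection speed deep in the hypoxic region of the reference
#'   microfluidic gradient equals the measured bias of 1 um/min; see
#'   [calibrate_lambda_mf()].
#' @return An object of class `mean_field_params` (a validated list).
#' @seealso [potts_params()], [load_params()]
#' @export
mean_field_params <- function(D = 30, Doxy = 1.2e5, r0 = log(2) / 480,
                              b0 = 0.01, C0 = 0.7, C0p = 0.1, a0 = 1,
                              Cboundary = 21, L = 9000,
                              lambda_mf_max = calibrate_lambda_mf()) {
  p <- list(D = D, Doxy = Doxy, r0 = r0, b0 = b0, C0 = C0, C0p = C0p,
            a0 = a0, Cboundary = Cboundary, L = L,
            lambda_mf_max = lambda_mf_max)
  class(p) <- "mean_field_params"
  validate_mean_field_params(p)
  p
}

validate_mean_field_params <- function(p) {
  pos <- c("D", "Doxy", "r0", "b0", "Cboundary", "L", "lambda_mf_max")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("mean_field_params: field '", f, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (p$a0 < 0) stop("mean_field_params: field 'a0' must be >= 0", call. = FALSE)
  if (!(p$C0p >= 0 && p$C0p < p$C0 && p$C0 < p$Cboundary)) {
    stop("mean_field_params: thresholds must satisfy 0 <= C0p < C0 < Cboundary",
         call. = FALSE)
  }
  invisible(p)
}

#' Calibrate the mean-field aerotactic amplitude
#'
#' The aerotactic response of the lattice model is an energy coefficient
#' (amplitude 800 in lattice units) and cannot be used directly as an
#' advection coefficient. The mean-field amplitude is instead fixed by
#' requiring that, deep in the hypoxic region of the reference microfluidic
#' gradient (where the sigmoid modulation saturates), the advection speed
#' `lambda_mf_max * dC/dx` reproduces the measured aerotactic bias of
#' about 1 um/min. The reference gradient is evaluated at the position
#' where the gradient field crosses `C_ref` = 0.4 \%O2, the concentration at
#' which hypoxic cell motility was characterised.
#'
#' @param bias_target measured aerotactic bias to reproduce, um/min.
#' @param C_ref oxygen concentration defining the reference position, \%O2.
#' @return Amplitude in um^2 min^-1 per (\%O2/um).
#' @export
calibrate_lambda_mf <- function(bias_target = 1, C_ref = 0.4) {
  # invert the microfluidic sigmoid for the pixel position where C = C_ref
  x_ref <- 200 + log(21.38 / C_ref - 1) / 0.031
  g <- abs(microfluidic_gradient_deriv(x_ref)) # %O2 per um
  bias_target / g
}

#' Mean-field aerotactic response coefficient
#'
#' Sigmoid modulation of the aerotactic strength by local oxygen,
#' `lambda(C) = lambda_mf_max / (1 + exp((C - 0.7)/0.2))`, rescaled to
#' advection units. The advection speed is `lambda(C) * dC/dx`.
#'
#' @param C oxygen concentration(s), \%O2.
#' @param params a [mean_field_params()] object.
#' @return Response coefficient(s), um^2 min^-1 per (\%O2/um).
#' @export
lambda_mf <- function(C, params = mean_field_params()) {
  params$lambda_mf_max / (1 + exp((C - 0.7) / 0.2))
}

#' Default cellular Potts model parameters
#'
#' Parameters of the 2-D lattice simulation. Lengths are in pixels
#' (1 pixel = 10 um), time in Monte Carlo steps (1 MCS = 0.1 s), oxygen in
#' \%O2 where 21 corresponds to the 1.25e-15 mol available above one pixel
#' at full vertical confinement.
#'
#' @param lambda_v volume-constraint energy coefficient.
#' @param V_target target cell volume, pixels.
#' @param lambda_aero_max amplitude of the aerotaxis sigmoid.
#' @param aero_midpoint,aero_width midpoint and width of the aerotaxis
#'   sigmoid `lambda_aero(C) = lambda_aero_max/(1+exp((C-mid)/width))`, \%O2.
#' @param T_base,T_amp,T_midpoint,T_width effective-temperature sigmoid
#'   `T(C) = T_base + T_amp/(1+exp((C-mid)/width))` (aerokinesis).
#' @param consumption_per_pixel oxygen removed per occupied pixel per MCS.
#' @param leak_coeff maximal oxygen leak through the plate bottom per pixel
#'   per MCS (attained at C = 0).
#' @param division_prob per-cell division probability per MCS. Stored at
#'   full precision 1/288000; see [rounded_division_prob()] for the
#'   one-significant-figure value.
#' @param division_cutoff oxygen level below which division is off, \%O2.
#' @param px_um pixel size, um (fixed scale of the model).
#' @param step_s duration of one MCS, s (fixed scale of the model).
#' @param Dox_px oxygen diffusion constant, pixel^2 per MCS.
#' @param neighborhood `"vonneumann"` (4-connected, default) or `"moore"`
#'   (8-connected) copy-attempt neighborhood.
#' @return An object of class `potts_params`.
#' @export
potts_params <- function(lambda_v = 800, V_target = 2,
                         lambda_aero_max = 800, aero_midpoint = 0.7,
                         aero_width = 0.2,
                         T_base = 85, T_amp = 105, T_midpoint = 0.7,
                         T_width = 1,
                         consumption_per_pixel = 0.1, leak_coeff = 0.001,
                         division_prob = 1 / 288000, division_cutoff = 0.7,
                         px_um = 10, step_s = 0.1, Dox_px = 2,
                         neighborhood = c("vonneumann", "moore")) {
  p <- list(lambda_v = lambda_v, V_target = V_target,
            lambda_aero_max = lambda_aero_max, aero_midpoint = aero_midpoint,
            aero_width = aero_width, T_base = T_base, T_amp = T_amp,
            T_midpoint = T_midpoint, T_width = T_width,
            consumption_per_pixel = consumption_per_pixel,
            leak_coeff = leak_coeff, division_prob = division_prob,
            division_cutoff = division_cutoff, px_um = px_um,
            step_s = step_s, Dox_px = Dox_px,
            neighborhood = match.arg(neighborhood))
  class(p) <- "potts_params"
  validate_potts_params(p)
  p
}

validate_potts_params <- function(p) {
  pos <- c("lambda_v", "V_target", "T_base", "consumption_per_pixel",
           "leak_coeff", "px_um", "step_s", "Dox_px")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("potts_params: field '", f, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (p$division_prob < 0 || p$division_prob > 1) {
    stop("potts_params: 'division_prob' must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Division probability as printed at one significant figure
#'
#' The per-step division probability follows from the 8 h doubling time:
#' 1/(8 h * 3600 s/h * 10 step/s) = 1/288000 per MCS. The full-precision
#' value is stored in [potts_params()]; this accessor reproduces the
#' rounded one-significant-figure value 3e-6.
#'
#' @param params a [potts_params()] object.
#' @return The division probability rounded to one significant figure.
#' @export
rounded_division_prob <- function(params = potts_params()) {
  signif(params$division_prob, 1)
}

#' Unit conversion constants of the lattice model
#'
#' Helper constants tying lattice oxygen units to molar amounts: at full
#' atmospheric oxygen (21 units) the medium column above one 10 um pixel
#' under 50 um vertical confinement holds 1.25e-15 mol of O2 (250 uM
#' solubility in HL5).
#'
#' @return A named list with `mol_per_pixel_at_21` (mol), `o2_units_max`
#'   (21, \%O2), `solubility_uM` (250), `confinement_um` (50).
#' @export
potts_unit_constants <- function() {
  list(mol_per_pixel_at_21 = 1.25e-15, o2_units_max = 21,
       solubility_uM = 250, confinement_um = 50)
}

#' Load model parameters from a flat key/value config
#'
#' Reads a YAML document (or takes a named list) whose keys are a subset of
#' the field names of [mean_field_params()] and [potts_params()];
#' unspecified keys take the model defaults.
#'
#' @param config path to a YAML file, a named list, or `NULL` for defaults.
#' @return A list with elements `mean_field` and `potts`.
#' @examples
#' p <- load_params(list(a0 = 0.5, lambda_v = 600))
#' p$mean_field$a0
#' @export
load_params <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  mf_fields <- names(formals(mean_field_params))
  po_fields <- setdiff(names(formals(potts_params)), "neighborhood")
  unknown <- setdiff(names(config), c(mf_fields, po_fields, "neighborhood"))
  if (length(unknown)) {
    stop("load_params: unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  mf <- do.call(mean_field_params, config[intersect(names(config), mf_fields)])
  po <- do.call(potts_params,
                config[intersect(names(config), c(po_fields, "neighborhood"))])
  list(mean_field = mf, potts = po)
}

#' Serialize parameters back to a flat key/value document
#'
#' @param params list with `mean_field` and `potts` entries as returned by
#'   [load_params()].
#' @param path file to write; YAML format.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  flat <- c(unclass(params$mean_field), unclass(params$potts))
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}
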