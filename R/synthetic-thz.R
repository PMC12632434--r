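## Synthetic THz temperature series with recorded ground truth.
##
## Mode widths follow Arrhenius lifetimes: tau_i(T) = tau_pref_i *
## exp(E_a_i / (R T)), omega_i(T) = 1 / (c tau_i(T)); centers are
## temperature-invariant (no significant shift is seen experimentally
## over 298-340 K). Default truths place the stretching mode at 147
## 1/cm with E_a = 3.5 kJ/mol (width ~190 1/cm at 298 K) and the
## libration at 412 1/cm with E_a = 7.4 kJ/mol (width ~280 1/cm).

.default_mode_truth <- function() list(
  stretching = list(a = 3000, nu0 = 147, E_a_kJmol = 3.5,
                    tau_pref_fs = 42.7),
  libration  = list(a = 5000, nu0 = 412, E_a_kJmol = 7.4,
                    tau_pref_fs = 6.0)
)

## width (1/cm) implied by an Arrhenius lifetime at temperature T
.omega_of_T <- function(truth, T_K) {
  tau_fs <- truth$tau_pref_fs * exp(truth$E_a_kJmol * 1000 / (.R_gas * T_K))
  if (tau_fs <= 10 || tau_fs >= 2000)
    stop(sprintf("implied lifetime %.1f fs leaves (10, 2000) fs", tau_fs))
  1e15 / (tau_fs * .c_cm_s)
}

#' Generate a synthetic THz temperature series
#'
#' Builds water spectra on the 50-550 1/cm grid (2 1/cm steps) from
#' the Debye + high-frequency + two-DHO composition, with mode widths
#' driven by per-mode Arrhenius lifetime laws and additive Gaussian
#' noise scaled to the peak absorption. With \code{raw = TRUE} the
#' noiseless water spectra are pushed back through the lipid addition
#' and ATR Beer-Lambert relations to emit raw I0/I intensity pairs
#' plus a lipid-mixture reference spectrum, so the full conversion
#' chain can be exercised.
#'
#' @param T_grid Temperatures (K) within 290-350; default
#'   \code{seq(298, 340, by = 3)} (15 temperatures).
#' @param mode_truth Per-mode truth list (amplitude a, center nu0,
#'   E_a_kJmol, tau_pref_fs); defaults as documented.
#' @param a_LF,a_HF,lf,hf Background truth; package defaults.
#' @param noise_sd Additive noise as a fraction of the peak
#'   delta-alpha; default 0.01.
#' @param seed RNG seed.
#' @param raw Emit raw ATR intensity pairs instead of water spectra.
#' @param phi_m Lipid-mixture volume fraction used when \code{raw};
#'   default 0.5.
#' @param n_s Sample refractive index used when \code{raw}; default 1.41.
#' @return List with \code{spectra} (list of \code{water_spectrum}, or
#'   of \code{atr_spectrum} when raw), \code{lipid_ref} (an
#'   \code{absorption_spectrum}, raw only), and \code{ground_truth}
#'   (true parameters, per-T widths and lifetimes, noise model).
#' @export
gen_thz_series <- function(T_grid = seq(298, 340, by = 3),
                           mode_truth = .default_mode_truth(),
                           a_LF = 1, a_HF = 1,
                           lf = .default_lf(), hf = .default_hf(),
                           noise_sd = 0.01, seed = 1L, raw = FALSE,
                           phi_m = 0.5, n_s = 1.41) {
  if (any(T_grid < 290 | T_grid > 350))
    stop("T_grid must lie within 290-350 K")
  if (any(vapply(mode_truth, function(m) m$E_a_kJmol, numeric(1)) <= 0))
    stop("activation energies must be positive")
  set.seed(as.integer(seed))
  nu <- seq(50, 550, by = 2)
  ## smooth synthetic lipid-mixture reference (recorded, arbitrary)
  alpha_m_curve <- 80 * (1 - exp(-nu / 250)) + 0.25 * nu

  spectra <- vector("list", length(T_grid))
  widths <- matrix(NA_real_, length(T_grid), 2,
                   dimnames = list(NULL, names(mode_truth)))
  for (k in seq_along(T_grid)) {
    TK <- T_grid[k]
    w <- vapply(mode_truth, .omega_of_T, numeric(1), T_K = TK)
    widths[k, ] <- w
    model <- thz_model(
      stretching = list(a = mode_truth$stretching$a,
                        nu0 = mode_truth$stretching$nu0, omega = w[1L]),
      libration = list(a = mode_truth$libration$a,
                       nu0 = mode_truth$libration$nu0, omega = w[2L]),
      a_LF = a_LF, a_HF = a_HF, lf = lf, hf = hf)
    da <- eval_thz_model(model, nu)
    if (noise_sd > 0)
      da <- da + stats::rnorm(length(nu), sd = noise_sd * max(da))
    if (raw) {
      alpha_tot <- da + phi_m * alpha_m_curve
      d_cm <- penetration_thickness(nu, 2.42, n_s) * 1e-4
      I0 <- rep(1000, length(nu))
      spectra[[k]] <- atr_spectrum(nu, I0, I0 * exp(-alpha_tot * d_cm),
                                   temperature = TK, n_s = n_s,
                                   sample_id = "synthetic")
    } else {
      spectra[[k]] <- structure(
        list(nu = nu, delta_alpha = da, phi_m = if (raw) phi_m else 0,
             temperature = TK, sample_id = "synthetic"),
        class = "water_spectrum")
    }
  }
  gt <- list(generator = "gen_thz_series", seed = as.integer(seed),
             T_grid = T_grid, mode_truth = mode_truth,
             a_LF = a_LF, a_HF = a_HF, lf = lf, hf = hf,
             widths_cm1 = widths,
             tau_fs = 1e15 / (widths * .c_cm_s),
             noise = sprintf("additive Gaussian, sd = %g x peak", noise_sd),
             raw = raw, phi_m = phi_m, n_s = n_s)
  out <- list(spectra = spectra, ground_truth = gt)
  if (raw)
    out$lipid_ref <- absorption_spectrum(nu, alpha_m_curve,
                                         sample_id = "lipid_mixture")
  out
}
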