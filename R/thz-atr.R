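## ATR absorption spectra: effective thickness, Beer-Lambert conversion
## and lipid-reference subtraction.

#' ATR effective penetration thickness
#'
#' Effective path length of the evanescent wave in a single-reflection
#' ATR geometry:
#' \deqn{d_s = \frac{\lambda}{2\pi\sqrt{n_C^2\sin^2\theta - n_s^2}}}
#' with \eqn{\lambda = 10^4/\nu} in micrometres for \eqn{\nu} in
#' \eqn{cm^{-1}}. Requires total internal reflection,
#' \eqn{n_C\sin\theta > n_s}.
#'
#' @param nu Wavenumber grid (1/cm), positive.
#' @param n_C ATR-crystal refractive index (2.42 for diamond).
#' @param n_s Sample refractive index (1.47/1.44/1.41 for 30/40/50\%
#'   water content).
#' @param theta Incidence angle in radians; default \code{pi/4}.
#' @return Effective thickness in micrometres, one value per \code{nu}.
#' @examples
#' penetration_thickness(100, 2.42, 1.47)  # ~18.17 um
#' @export
penetration_thickness <- function(nu, n_C = 2.42, n_s = 1.47,
                                  theta = pi / 4) {
  if (any(nu <= 0)) stop("wavenumber must be positive")
  radicand <- n_C^2 * sin(theta)^2 - n_s^2
  if (radicand <= 1e-12)
    stop("no evanescent regime: n_C * sin(theta) must exceed n_s")
  lambda_um <- 1e4 / nu
  lambda_um / (2 * pi * sqrt(radicand))
}

#' Construct a raw ATR spectrum
#'
#' @param nu Wavenumber grid (1/cm), strictly increasing within [50, 550].
#' @param I0,I Incident and transmitted intensities, positive.
#' @param temperature K.
#' @param n_C,n_s,theta ATR optics; see
#'   \code{\link{penetration_thickness}}.
#' @param sample_id Label.
#' @param noise_tolerance Allowed fractional exceedance of I over I0
#'   (noise); default 0.05.
#' @return Object of class \code{atr_spectrum}.
#' @export
atr_spectrum <- function(nu, I0, I, temperature = NA_real_, n_C = 2.42,
                         n_s = 1.47, theta = pi / 4, sample_id = "sample",
                         noise_tolerance = 0.05) {
  nu <- as.numeric(nu)
  if (any(diff(nu) <= 0)) stop("nu grid must be strictly increasing")
  if (min(nu) < 50 - 1e-9 || max(nu) > 550 + 1e-9)
    stop("nu must lie within [50, 550] 1/cm")
  if (length(I0) != length(nu) || length(I) != length(nu))
    stop("I0 and I must match the nu grid")
  if (any(I0 <= 0) || any(I <= 0)) stop("intensities must be positive")
  if (any(I > I0 * (1 + noise_tolerance)))
    stop("I exceeds I0 beyond the declared noise tolerance")
  if (n_C * sin(theta) <= n_s)
    stop("total internal reflection requires n_C * sin(theta) > n_s")
  structure(list(nu = nu, I0 = as.numeric(I0), I = as.numeric(I),
                 temperature = temperature, n_C = n_C, n_s = n_s,
                 theta = theta, sample_id = sample_id),
            class = "atr_spectrum")
}

#' Absorption coefficient from raw ATR intensities
#'
#' Beer-Lambert inversion \eqn{\alpha(\nu) = \ln(I_0/I)/d_s(\nu)} with
#' the per-frequency effective thickness of
#' \code{\link{penetration_thickness}}. The natural logarithm is the
#' default (standard for absorption coefficients in 1/cm); set
#' \code{decadic = TRUE} for base-10.
#'
#' @param raw An \code{\link{atr_spectrum}}.
#' @param decadic Use the decadic logarithm. Default \code{FALSE}.
#' @return Object of class \code{absorption_spectrum}: list with
#'   \code{nu}, \code{alpha} (1/cm), \code{d_s_um}, \code{temperature},
#'   \code{log_base}.
#' @export
absorption_from_atr <- function(raw, decadic = FALSE) {
  stopifnot(inherits(raw, "atr_spectrum"))
  ratio <- raw$I0 / raw$I
  if (any(ratio <= 0)) stop("nonpositive intensity ratio")
  d_um <- penetration_thickness(raw$nu, raw$n_C, raw$n_s, raw$theta)
  d_cm <- d_um * 1e-4
  logf <- if (decadic) log10 else log
  structure(list(nu = raw$nu, alpha = logf(ratio) / d_cm, d_s_um = d_um,
                 temperature = raw$temperature,
                 log_base = if (decadic) "decadic" else "natural",
                 sample_id = raw$sample_id),
            class = "absorption_spectrum")
}

#' Construct an absorption spectrum directly
#'
#' For inputs already expressed as an absorption coefficient.
#'
#' @param nu Wavenumber grid (1/cm), strictly increasing.
#' @param alpha Absorption coefficient (1/cm), finite.
#' @param temperature K.
#' @param sample_id Label.
#' @return Object of class \code{absorption_spectrum}.
#' @export
absorption_spectrum <- function(nu, alpha, temperature = NA_real_,
                                sample_id = "sample") {
  nu <- as.numeric(nu)
  if (any(diff(nu) <= 0)) stop("nu grid must be strictly increasing")
  if (any(!is.finite(alpha))) stop("alpha must be finite")
  structure(list(nu = nu, alpha = as.numeric(alpha), d_s_um = NULL,
                 temperature = temperature, log_base = "natural",
                 sample_id = sample_id),
            class = "absorption_spectrum")
}

#' Isolate the water contribution by lipid-reference subtraction
#'
#' \eqn{\Delta\alpha(\nu) = \alpha(\nu) - \phi_m\,\alpha_m(\nu)} where
#' \eqn{\alpha_m} is the lipid-mixture reference spectrum and
#' \eqn{\phi_m} its volume fraction. The reference is linearly
#' resampled onto the sample grid (with a warning) when the grids
#' differ; non-overlapping grids are an error.
#'
#' @param alpha Sample \code{absorption_spectrum}.
#' @param alpha_m Lipid-mixture reference \code{absorption_spectrum}.
#' @param phi_m Lipid-mixture volume fraction in [0, 1].
#' @return Object of class \code{water_spectrum}: list with \code{nu},
#'   \code{delta_alpha}, \code{phi_m}, \code{temperature}, \code{sample_id}.
#' @export
subtract_lipid <- function(alpha, alpha_m, phi_m) {
  stopifnot(inherits(alpha, "absorption_spectrum"),
            inherits(alpha_m, "absorption_spectrum"))
  if (!is.numeric(phi_m) || phi_m < 0 || phi_m > 1)
    stop("phi_m must lie in [0, 1]")
  am <- alpha_m$alpha
  if (length(alpha_m$nu) != length(alpha$nu) ||
      any(abs(alpha_m$nu - alpha$nu) > 1e-9)) {
    if (min(alpha_m$nu) > min(alpha$nu) || max(alpha_m$nu) < max(alpha$nu))
      stop("reference grid does not cover the sample grid")
    warning("resampling lipid reference onto the sample grid")
    am <- stats::approx(alpha_m$nu, alpha_m$alpha, xout = alpha$nu)$y
  }
  structure(list(nu = alpha$nu, delta_alpha = alpha$alpha - phi_m * am,
                 phi_m = phi_m, temperature = alpha$temperature,
                 sample_id = alpha$sample_id),
            class = "water_spectrum")
}

#' @export
print.water_spectrum <- function(x, ...) {
  cat(sprintf(
    "Water THz spectrum '%s': %d points, nu in [%g, %g] 1/cm, T = %s K\n",
    x$sample_id, length(x$nu), min(x$nu), max(x$nu), format(x$temperature)))
  invisible(x)
}

#' Read a THz spectrum from CSV
#'
#' Columns: \code{nu_cm1} plus either \code{alpha_cm1} or both
#' \code{I0} and \code{I}. Header comment lines \code{# key: value}
#' may set \code{temperature_K}, \code{sample_id}, \code{phi_m},
#' \code{n_s}.
#'
#' @param path CSV file path.
#' @return An \code{absorption_spectrum} (when alpha is given) or an
#'   \code{atr_spectrum} (when I0/I are given); header metadata is
#'   attached as attribute \code{"meta"}.
#' @export
read_thz_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (key in c("temperature_K", "sample_id", "phi_m", "n_s")) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*[:=]\\s*(\\S+)"), hdr))
    v <- unlist(lapply(m, function(g) if (length(g) == 2L) g[2L] else NULL))
    if (length(v)) meta[[key]] <- v[1L]
  }
  tk <- if (!is.null(meta$temperature_K)) as.numeric(meta$temperature_K) else NA_real_
  sid <- if (!is.null(meta$sample_id)) meta$sample_id else basename(path)
  dat <- utils::read.csv(text = lines[!grepl("^\\s*#", lines)])
  out <- if ("alpha_cm1" %in% names(dat)) {
    absorption_spectrum(dat$nu_cm1, dat$alpha_cm1, tk, sid)
  } else if (all(c("I0", "I") %in% names(dat))) {
    ns <- if (!is.null(meta$n_s)) as.numeric(meta$n_s) else 1.47
    atr_spectrum(dat$nu_cm1, dat$I0, dat$I, tk, n_s = ns, sample_id = sid)
  } else stop("CSV must contain alpha_cm1 or both I0 and I")
  attr(out, "meta") <- meta
  out
}
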