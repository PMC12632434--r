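## Arrhenius analysis of temperature series.
##
## Convention: value(T) = prefactor * exp(E_a / (R T)), so E_a > 0 for
## quantities (lifetimes, HB counts) that decrease with increasing
## temperature. The fit is ordinary least squares of ln(value) on 1/T;
## E_a = slope * R.

#' Arrhenius fit of a positive temperature series
#'
#' Fits \eqn{\ln v = \ln v_\infty + E_a/(R T)} by ordinary least
#' squares and reports the activation energy \eqn{E_a} in kJ/mol
#' (gas constant R = 8.314 J/mol/K), the prefactor \eqn{v_\infty} in
#' the units of the input, \eqn{r^2} and standard errors. A constant
#' series yields \eqn{E_a = 0} with \eqn{r^2} reported as 0 and a flag.
#'
#' @param values Positive quantities (e.g. lifetimes in fs, mean HB
#'   counts); at least 3.
#' @param T_K Temperatures in kelvin, same length.
#' @param label Optional label (mode or sample name).
#' @return Object of class \code{arrhenius_fit} with elements
#'   \code{E_a_kJmol}, \code{E_a_se_kJmol}, \code{prefactor},
#'   \code{r_squared}, \code{label}, \code{flag} and the underlying
#'   \code{lm} fit.
#' @examples
#' T <- seq(298, 340, by = 3)
#' tau <- 100 * exp(3520 / (8.314 * T))
#' arrhenius_fit(tau, T)  # E_a = 3.52 kJ/mol
#' @export
arrhenius_fit <- function(values, T_K, label = "") {
  values <- as.numeric(values); T_K <- as.numeric(T_K)
  if (length(values) < 3L) stop("need at least 3 (value, T) pairs")
  if (length(values) != length(T_K)) stop("values and T_K lengths differ")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite")
  if (any(T_K <= 0)) stop("temperatures must be positive kelvin")
  fit <- stats::lm(log(values) ~ I(1 / T_K))
  cf <- stats::coef(fit)
  ## exact log-linear input is legitimate here; silence the
  ## perfect-fit advisory from summary.lm
  sm <- suppressWarnings(summary(fit))
  slope <- cf[[2L]]
  slope_se <- sm$coefficients[2L, 2L]
  r2 <- sm$r.squared
  flag <- ""
  if (stats::var(log(values)) < .Machine$double.eps) {
    r2 <- 0; flag <- "constant series: r_squared undefined, reported 0"
  }
  structure(list(
    E_a_kJmol = slope * .R_gas / 1000,
    E_a_se_kJmol = slope_se * .R_gas / 1000,
    prefactor = exp(cf[[1L]]),
    prefactor_se_log = sm$coefficients[1L, 2L],
    r_squared = r2, n = length(values), label = label, flag = flag,
    lm = fit, T_K = T_K, values = values
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit%s: E_a = %.4g +/- %.2g kJ/mol, r^2 = %.4f (n = %d)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$E_a_kJmol, x$E_a_se_kJmol, x$r_squared, x$n))
  if (nzchar(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(E_a_kJmol = object$E_a_kJmol, prefactor = object$prefactor)
}

#' @export
summary.arrhenius_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  prefactor = %.6g (log-scale se %.2g)\n",
              object$prefactor, object$prefactor_se_log))
  invisible(object)
}

#' @export
predict.arrhenius_fit <- function(object, T_K = object$T_K, ...) {
  object$prefactor * exp(object$E_a_kJmol * 1000 / (.R_gas * T_K))
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  invT <- 1 / x$T_K
  graphics::plot(invT, log(x$values), pch = 16,
                 xlab = "1/T (1/K)", ylab = "ln(value)",
                 main = sprintf("Arrhenius: E_a = %.3g kJ/mol", x$E_a_kJmol),
                 ...)
  graphics::abline(stats::coef(x$lm)[1L], stats::coef(x$lm)[2L], lwd = 2)
  invisible(x)
}
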