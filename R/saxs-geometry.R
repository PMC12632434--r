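## Mesophase geometry from the minimal-surface description.
##
## The bilayer midsurface is a triply periodic minimal surface with
## normalized unit-cell area A0 and Euler-Poincare characteristic chi.
## Water-channel radius: r = sqrt(A0 / (-2 pi chi)) * a - l.
## Lipid length l from the volume balance
##   phi_L = 2 A0 (l/a) + (4 pi chi / 3) (l/a)^3.
## Interfacial water fraction from the parameter-free relation
##   f_w,int = (-0.543 K0 - 2.092) / Gamma,  Gamma = f_w a^3 / (4 pi |chi|)
## with a in nm.

#' Water-channel radius and diameter of a cubic mesophase
#'
#' \eqn{r = \sqrt{A_0 / (-2\pi\chi)}\,a - l}; the diameter is
#' \eqn{2r}. The printed channel-size relation in the minimal-surface
#' literature is the radius form; both are returned so downstream
#' reports can use the diameter (3-7 nm for typical swollen phases).
#'
#' @param a Lattice parameter (nm), positive.
#' @param l Lipid length (nm), in [0, sqrt(A0/(-2 pi chi)) * a].
#' @param group A \code{\link{space_group}} or its name.
#' @return List with \code{channel_radius} and \code{channel_diameter} (nm).
#' @examples
#' channel_diameter(10, 1.7, "Pn3m")
#' @export
channel_diameter <- function(a, l, group) {
  sg <- as_space_group(group)
  if (!is.numeric(a) || a <= 0) stop("lattice parameter a must be positive")
  rmax <- .radius_coef(sg) * a
  if (!is.numeric(l) || l < 0) stop("lipid length l must be non-negative")
  if (l > rmax + 1e-12)
    stop(sprintf("l = %.4g nm exceeds the maximum %.4g nm for %s (negative channel)",
                 l, rmax, sg$name))
  r <- max(rmax - l, 0)
  list(channel_radius = r, channel_diameter = 2 * r)
}

## forward cubic: phi_L as a function of x = l/a
.phi_of_x <- function(x, sg) 2 * sg$A0 * x + (4 * pi * sg$chi / 3) * x^3

#' Lipid length from the lipid volume fraction
#'
#' Inverts \eqn{\phi_L = 2 A_0 (l/a) + \frac{4\pi\chi}{3} (l/a)^3} for
#' \eqn{l} on the physically monotone branch \eqn{l/a \in (0,
#' x_{turn})}, \eqn{x_{turn} = \sqrt{A_0/(-2\pi\chi)}}, where the cubic
#' is increasing. The root is bracketed and polished to an absolute
#' tolerance of 1e-12 in \eqn{l/a}.
#'
#' @param phi_L Lipid volume fraction, in (0, 1).
#' @param a Lattice parameter (nm), positive.
#' @param group A \code{\link{space_group}} or its name.
#' @return Lipid length l in nm.
#' @examples
#' lipid_length(0.5, 10, "Pn3m")  # ~1.357 nm
#' @export
lipid_length <- function(phi_L, a, group) {
  sg <- as_space_group(group)
  if (!is.numeric(phi_L) || phi_L <= 0 || phi_L >= 1)
    stop("phi_L must lie in (0, 1)")
  if (!is.numeric(a) || a <= 0) stop("lattice parameter a must be positive")
  x_turn <- .radius_coef(sg)
  phi_max <- .phi_of_x(x_turn, sg)
  if (phi_L > phi_max)
    stop(sprintf("phi_L = %.4g exceeds the maximum %.4g attainable for %s",
                 phi_L, phi_max, sg$name))
  root <- stats::uniroot(function(x) .phi_of_x(x, sg) - phi_L,
                         lower = 0, upper = x_turn, tol = 1e-14)$root
  ## Newton polish to drive the residual to the 1e-12 contract
  for (it in 1:4) {
    f <- .phi_of_x(root, sg) - phi_L
    fp <- 2 * sg$A0 + 4 * pi * sg$chi * root^2
    if (fp <= 0) break
    root <- root - f / fp
  }
  root * a
}

#' Interfacial water fraction of a swollen cubic mesophase
#'
#' Computes \eqn{\Gamma = f_w a^3 / (4\pi|\chi|)} (with \eqn{a}
#' numerically in nm) and the analytic interfacial water fraction
#' \eqn{f_{w,int} = (-0.543 K_0 - 2.092)/\Gamma}, clamped to [0, 1].
#' \eqn{K_0} is a dimensionless curvature parameter of the swollen
#' monolinolein-sugar-ester calibration and must be supplied by the
#' caller; setting \code{k0_convention = TRUE} uses the documented
#' convention \eqn{K_0 = 2\pi\chi/A_0} (integrated Gaussian curvature
#' per unit surface) instead of \code{K0}.
#'
#' @param f_w Total water volume fraction, in (0, 1].
#' @param a Lattice parameter in nm, positive.
#' @param group A \code{\link{space_group}} or its name.
#' @param K0 Dimensionless curvature parameter. Required unless
#'   \code{k0_convention} is \code{TRUE}.
#' @param k0_convention Use \eqn{K_0 = 2\pi\chi/A_0}. Default \code{FALSE}.
#' @return List with \code{Gamma}, \code{f_w_int}, \code{K0} and a
#'   \code{clamped} flag (TRUE when the raw value fell outside [0, 1]).
#'   The \code{units} element records that a enters Gamma in nm.
#' @examples
#' interfacial_water_fraction(0.5, 10, "Pn3m", k0_convention = TRUE)
#' @export
interfacial_water_fraction <- function(f_w, a, group, K0 = NULL,
                                       k0_convention = FALSE) {
  sg <- as_space_group(group)
  if (!is.numeric(f_w) || f_w <= 0 || f_w > 1) stop("f_w must lie in (0, 1]")
  if (!is.numeric(a) || a <= 0) stop("lattice parameter a must be positive")
  if (isTRUE(k0_convention)) {
    K0 <- 2 * pi * sg$chi / sg$A0
  } else if (is.null(K0) || !is.numeric(K0)) {
    stop("K0 must be supplied (or set k0_convention = TRUE)")
  }
  Gamma <- f_w * a^3 / (4 * pi * abs(sg$chi))
  if (Gamma == 0) stop("Gamma is zero; interfacial fraction undefined")
  raw <- (-0.543 * K0 - 2.092) / Gamma
  clamped <- raw < 0 || raw > 1
  list(Gamma = Gamma, f_w_int = min(max(raw, 0), 1), K0 = K0,
       clamped = clamped, units = "a in nm")
}

#' Geometry table over a temperature series
#'
#' Combines indexed phase assignments with a fixed composition into a
#' per-temperature table of cubic geometry. Temperatures at which two
#' phases coexist cannot be resolved into per-phase water contents, so
#' their geometry fields are emitted as \code{NA} with a recorded
#' reason, never silently dropped.
#'
#' @param assignments A list of \code{\link{phase_fit}} objects; one per
#'   temperature entry in \code{temperature}. A list of two fits in one
#'   slot marks phase coexistence at that temperature.
#' @param temperature Numeric vector of temperatures (K), same length.
#' @param phi_L Lipid volume fraction of the composition.
#' @param K0,k0_convention Passed to
#'   \code{\link{interfacial_water_fraction}}.
#' @return A data.frame with columns T_K, phase, a_nm, l_nm, d_nm,
#'   Gamma, f_w_int, flag.
#' @export
geometry_series <- function(assignments, temperature, phi_L,
                            K0 = NULL, k0_convention = FALSE) {
  if (length(assignments) != length(temperature))
    stop("one assignment (or coexistence pair) per temperature required")
  f_w <- 1 - phi_L
  empty <- data.frame(T_K = numeric(0), phase = character(0),
                      a_nm = numeric(0), l_nm = numeric(0),
                      d_nm = numeric(0), Gamma = numeric(0),
                      f_w_int = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE)
  if (!length(assignments)) return(empty)
  rows <- lapply(seq_along(assignments), function(i) {
    as_i <- assignments[[i]]
    if (inherits(as_i, "phase_fit")) as_i <- list(as_i)
    if (length(as_i) > 1L) {
      phases <- paste(vapply(as_i, function(p) p$space_group$name,
                             character(1)), collapse = "+")
      return(data.frame(T_K = temperature[i], phase = phases,
                        a_nm = NA_real_, l_nm = NA_real_, d_nm = NA_real_,
                        Gamma = NA_real_, f_w_int = NA_real_,
                        flag = "coexistence: geometry unavailable",
                        stringsAsFactors = FALSE))
    }
    p <- as_i[[1L]]
    sg <- p$space_group
    l <- lipid_length(phi_L, p$a_nm, sg)
    cd <- channel_diameter(p$a_nm, l, sg)
    iw <- interfacial_water_fraction(f_w, p$a_nm, sg, K0, k0_convention)
    data.frame(T_K = temperature[i], phase = sg$name, a_nm = p$a_nm,
               l_nm = l, d_nm = cd$channel_diameter, Gamma = iw$Gamma,
               f_w_int = iw$f_w_int,
               flag = if (iw$clamped) "f_w_int clamped" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
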