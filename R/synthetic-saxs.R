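## Synthetic SAXS profiles with recorded ground truth.

#' Generate a synthetic cubic-phase SAXS profile
#'
#' Places Gaussian Bragg peaks at \eqn{q_N = 2\pi\sqrt{N}/a} for the
#' first allowed reflections of the space group, with 1/N-decaying
#' amplitudes on a linear background and multiplicative Gaussian
#' noise, on the 0.05-0.45 1/Angstrom acquisition grid.
#'
#' @param group Space group (\code{\link{space_group}} or name).
#' @param a_nm True lattice parameter in nm.
#' @param n_peaks Number of reflections to include (default 4).
#' @param peak_width Gaussian sigma of each peak (1/Angstrom), default
#'   0.002.
#' @param background \code{c(level, slope)} of the linear background;
#'   default \code{c(5, -2)} (intensity units, units per 1/Angstrom).
#' @param noise_sd Multiplicative Gaussian noise level (fraction);
#'   default 0.01.
#' @param temperature,sample_id Metadata for the profile.
#' @param seed RNG seed.
#' @param q_step Grid step (1/Angstrom), default 5e-4.
#' @return List with \code{profile} (a \code{\link{saxs_profile}}) and
#'   \code{ground_truth} (generator name, seed, true parameters and
#'   peak positions, noise model).
#' @export
gen_saxs <- function(group, a_nm, n_peaks = 4L, peak_width = 0.002,
                     background = c(5, -2), noise_sd = 0.01,
                     temperature = 298, sample_id = "synthetic",
                     seed = 1L, q_step = 5e-4) {
  sg <- as_space_group(group)
  if (a_nm <= 0) stop("lattice parameter must be positive")
  if (n_peaks > length(sg$reflections))
    stop("n_peaks exceeds the available reflections for ", sg$name)
  set.seed(as.integer(seed))
  q <- seq(0.05, 0.45, by = q_step)
  N <- sg$reflections[seq_len(n_peaks)]
  q_true <- 2 * pi * sqrt(N) / (10 * a_nm)
  if (any(q_true < min(q) + 3 * peak_width) ||
      any(q_true > max(q) - 3 * peak_width))
    stop("peaks fall outside the 0.05-0.45 1/Angstrom grid for a = ",
         a_nm, " nm")
  amp <- 100 * N[1L] / N
  y <- background[1L] + background[2L] * q
  for (j in seq_along(N))
    y <- y + amp[j] * exp(-(q - q_true[j])^2 / (2 * peak_width^2))
  if (noise_sd > 0)
    y <- pmax(y * (1 + stats::rnorm(length(y), sd = noise_sd)), 0)
  list(
    profile = saxs_profile(q, y, temperature, sample_id),
    ground_truth = list(
      generator = "gen_saxs", seed = as.integer(seed),
      space_group = sg$name, a_nm = a_nm, reflections = N,
      q_peaks = q_true, amplitudes = amp, peak_width = peak_width,
      background = background,
      noise = sprintf("multiplicative Gaussian, sd = %g", noise_sd))
  )
}
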