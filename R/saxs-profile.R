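## 1-D SAXS profiles and Bragg-peak detection.

#' Construct a SAXS scattering profile
#'
#' A one-dimensional azimuthally averaged SAXS curve at a single
#' temperature. The scattering vector \eqn{q = (4\pi/\lambda)\sin\theta}
#' must be strictly increasing, positive and within [0.01, 1.0]
#' \eqn{\text{\AA}^{-1}}; intensities must be finite and non-negative.
#'
#' @param q Scattering vector grid (1/Angstrom), strictly increasing.
#' @param intensity Intensities (arbitrary units), same length as \code{q}.
#' @param temperature Sample temperature in kelvin.
#' @param sample_id Text label.
#' @return An object of class \code{saxs_profile}.
#' @export
saxs_profile <- function(q, intensity, temperature = NA_real_,
                         sample_id = "sample") {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity) || length(q) < 2L)
    stop("q and intensity must have equal length >= 2")
  if (any(!is.finite(q)) || any(diff(q) <= 0))
    stop("q grid must be finite and strictly increasing")
  if (any(q <= 0) || q[1L] < 0.01 || q[length(q)] > 1.0)
    stop("q must be positive and within [0.01, 1.0] 1/Angstrom")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and non-negative")
  structure(list(q = q, intensity = intensity,
                 temperature = as.numeric(temperature),
                 sample_id = as.character(sample_id)),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile '%s': %d points, q in [%.3f, %.3f] 1/A, T = %s K\n",
              x$sample_id, length(x$q), min(x$q), max(x$q),
              format(x$temperature)))
  invisible(x)
}

#' Read a SAXS profile from a two-column ASCII file
#'
#' Accepts whitespace- or comma-delimited files with q (1/Angstrom) in
#' column 1 and intensity in column 2. Lines starting with \code{#} are
#' treated as comments; \code{# temperature_K: <x>} and
#' \code{# sample_id: <x>} headers are honoured.
#'
#' @param path File path.
#' @return A \code{saxs_profile}.
#' @export
read_saxs_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  temperature <- NA_real_; sample_id <- basename(path)
  m <- regmatches(hdr, regexec("temperature_K\\s*[:=]\\s*([0-9.eE+-]+)", hdr))
  tv <- unlist(lapply(m, function(g) if (length(g) == 2L) g[2L] else NULL))
  if (length(tv)) temperature <- as.numeric(tv[1L])
  m <- regmatches(hdr, regexec("sample_id\\s*[:=]\\s*(\\S+)", hdr))
  sv <- unlist(lapply(m, function(g) if (length(g) == 2L) g[2L] else NULL))
  if (length(sv)) sample_id <- sv[1L]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  dat <- utils::read.table(text = gsub(",", " ", body))
  saxs_profile(dat[[1L]], dat[[2L]], temperature, sample_id)
}

## centered moving average with odd window; edges use a shrunken window
.moving_average <- function(y, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be a positive odd integer")
  n <- length(y)
  h <- window %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, y))
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

## rolling minimum over a window of 2*half+1 points
.rolling_min <- function(y, half) {
  n <- length(y)
  vapply(seq_len(n), function(i)
    min(y[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Detect Bragg peaks in a SAXS profile
#'
#' Smooths the curve with a centered moving average, subtracts a
#' rolling-minimum baseline and reports local maxima whose height above
#' the baseline exceeds \code{min_prominence} times the maximum
#' intensity.
#'
#' @param profile A \code{saxs_profile}.
#' @param min_prominence Required prominence as a fraction of the maximum
#'   intensity, in (0, 1). Default 0.02.
#' @param smoothing_window Odd moving-average window in points. Default 5.
#' @param baseline_halfwidth Half-width (points) of the rolling-minimum
#'   baseline window. Default 25.
#' @return Numeric vector of peak positions (1/Angstrom), ascending;
#'   empty when no peak qualifies.
#' @examples
#' q <- seq(0.05, 0.45, by = 5e-4)
#' y <- 1 + exp(-(q - 0.0889)^2 / (2 * 0.002^2))
#' detect_peaks(saxs_profile(q, y))
#' @export
detect_peaks <- function(profile, min_prominence = 0.02,
                         smoothing_window = 5L, baseline_halfwidth = 25L) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (!is.numeric(min_prominence) || min_prominence <= 0 || min_prominence >= 1)
    stop("min_prominence must lie in (0, 1)")
  y <- .moving_average(profile$intensity, smoothing_window)
  base <- .rolling_min(y, as.integer(baseline_halfwidth))
  thr <- min_prominence * max(profile$intensity)
  n <- length(y)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & (y[i] - base[i]) > thr
  profile$q[i[is_max]]
}
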