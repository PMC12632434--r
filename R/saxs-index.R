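## Bragg-peak indexing against cubic reflection sequences.
##
## For a cubic phase, peaks sit at q_N = 2 pi sqrt(N) / a with N running
## over the space group's allowed h^2+k^2+l^2. The lattice parameter is
## fit by least squares of q on x = 2 pi sqrt(N) through the origin
## (slope = 1/a): the d-spacing relation d = a / sqrt(N) has no
## intercept.

## fit q = x / a through the origin; q in 1/A, x = 2*pi*sqrt(N) (A scale)
.fit_lattice <- function(q, N) {
  x <- 2 * pi * sqrt(N)
  slope <- sum(x * q) / sum(x * x)         # = 1/a in 1/Angstrom
  pred <- slope * x
  resid <- q - pred
  ## relative RMS residual, per point
  rel_rms <- sqrt(mean((resid / q)^2))
  dof <- length(q) - 1L
  se_slope <- if (dof > 0L) sqrt(sum(resid^2) / dof / sum(x * x)) else NA_real_
  a_A <- 1 / slope
  list(a_nm = a_A / 10,                    # report in nm (1 nm = 10 A)
       a_stderr_nm = if (is.na(se_slope)) NA_real_ else se_slope / slope^2 / 10,
       residual = rel_rms, predicted = pred)
}

#' Index SAXS peaks against cubic space groups
#'
#' Assigns the observed peak positions, in order, to the first allowed
#' reflections of each candidate space group, fits the lattice parameter
#' by zero-intercept least squares of \eqn{q} on \eqn{2\pi\sqrt{N}}, and
#' selects the candidate with the lowest relative RMS residual.
#' Candidates whose residuals are within 10\% (relative) of the winner
#' are flagged as ambiguous near-ties rather than silently dropped.
#'
#' @param peaks Peak positions in 1/Angstrom, ascending; at least 2.
#' @param candidates Candidate space groups: a list of
#'   \code{\link{space_group}} objects or character names. Default all
#'   three cubic groups.
#' @param max_peaks_used Use at most this many peaks (from the low-q
#'   side). Default 8.
#' @return An object of class \code{phase_fit} with components
#'   \code{space_group}, \code{matched_peaks} (data.frame of q, N and
#'   d-spacing in Angstrom), \code{a_nm}, \code{a_stderr_nm},
#'   \code{residual}, \code{ambiguous} flag and a per-candidate
#'   \code{residual_table}.
#' @examples
#' a <- 100  # Angstrom
#' pk <- 2 * pi * sqrt(c(2, 3, 4, 6)) / a
#' index_phase(pk)
#' @export
index_phase <- function(peaks, candidates = space_groups(),
                        max_peaks_used = 8L) {
  peaks <- sort(as.numeric(peaks))
  if (length(peaks) < 2L) stop("need at least 2 peaks to index a phase")
  if (length(candidates) == 0L) stop("no candidate space groups supplied")
  candidates <- lapply(candidates, as_space_group)

  rows <- lapply(candidates, function(sg) {
    k <- min(length(peaks), max_peaks_used, length(sg$reflections))
    q <- peaks[seq_len(k)]
    N <- sg$reflections[seq_len(k)]
    fit <- .fit_lattice(q, N)
    if (!is.finite(fit$a_nm) || fit$a_nm <= 0)
      stop(sprintf("candidate %s yields a non-positive lattice parameter",
                   sg$name))
    c(list(space_group = sg, q = q, N = N), fit)
  })
  res_tab <- data.frame(
    space_group = vapply(rows, function(r) r$space_group$name, character(1)),
    a_nm = vapply(rows, function(r) r$a_nm, numeric(1)),
    residual = vapply(rows, function(r) r$residual, numeric(1)),
    stringsAsFactors = FALSE
  )
  best_i <- which.min(res_tab$residual)
  best <- rows[[best_i]]
  rmin <- res_tab$residual[best_i]
  ## near-tie: relative difference of residuals < 10% (exact ties included)
  tie <- abs(res_tab$residual - rmin) <= 0.10 * max(rmin, .Machine$double.eps)
  res_tab$near_tie <- tie
  structure(list(
    space_group = best$space_group,
    matched_peaks = data.frame(q = best$q, N = best$N,
                               d_A = 2 * pi / best$q),
    a_nm = best$a_nm,
    a_stderr_nm = best$a_stderr_nm,
    residual = best$residual,
    ambiguous = sum(tie) > 1L,
    residual_table = res_tab
  ), class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("Cubic phase assignment: %s%s\n", x$space_group$name,
              if (x$ambiguous) "  [ambiguous: residual near-tie]" else ""))
  cat(sprintf("  a = %.4f nm (se %.2g), relative RMS residual %.3g, %d peaks\n",
              x$a_nm, x$a_stderr_nm, x$residual, nrow(x$matched_peaks)))
  invisible(x)
}

#' @export
summary.phase_fit <- function(object, ...) {
  print(object)
  cat("  matched peaks:\n")
  print(cbind(object$matched_peaks,
              d_over_a = object$matched_peaks$d_A / (10 * object$a_nm)))
  cat("  candidate residuals:\n")
  print(object$residual_table)
  invisible(object)
}

#' @export
coef.phase_fit <- function(object, ...) {
  c(a_nm = object$a_nm)
}

#' Predicted peak positions of a fitted phase
#'
#' @param object A \code{phase_fit}.
#' @param n_reflections How many allowed reflections to predict.
#' @param ... Unused.
#' @return Numeric vector of predicted q positions (1/Angstrom).
#' @export
predict.phase_fit <- function(object, n_reflections = 6L, ...) {
  N <- object$space_group$reflections[seq_len(n_reflections)]
  2 * pi * sqrt(N) / (10 * object$a_nm)
}
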