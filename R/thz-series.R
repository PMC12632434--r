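## Temperature-series analysis: sequential spectral fits with warm
## starts, lifetime table, per-mode Arrhenius activation energies.

#' Analyse a temperature series of water THz spectra
#'
#' Fits the spectral decomposition at each temperature, warm-starting
#' each fit from the previous temperature's solution, then assembles
#' the per-mode lifetime table and Arrhenius fits for the stretching
#' and libration modes. Temperatures whose spectral fit fails to
#' converge are excluded from the Arrhenius stage and recorded; the
#' Arrhenius stage is skipped (with a reason) when fewer than 3
#' temperatures converge.
#'
#' @param spectra List of \code{water_spectrum} objects, ordered or
#'   unordered in temperature (they are sorted internally).
#' @param init Initial \code{\link{thz_model}} for the first fit.
#' @param free Free-parameter names, as in \code{\link{fit_thz_model}}.
#' @return Object of class \code{thz_series}: list with \code{fits}
#'   (per-T \code{thz_fit}), \code{lifetimes} (data.frame over T),
#'   \code{arrhenius} (list with stretching/libration
#'   \code{arrhenius_fit} or NULL), \code{skipped} (reason or "").
#' @export
analyze_series <- function(spectra, init, free = .par_names) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "water_spectrum")))
  TK <- vapply(spectra, function(s) s$temperature, numeric(1))
  if (any(is.na(TK))) stop("every spectrum needs a temperature")
  ord <- order(TK)
  spectra <- spectra[ord]; TK <- TK[ord]

  fits <- vector("list", length(spectra))
  cur_init <- init
  for (k in seq_along(spectra)) {
    fits[[k]] <- fit_thz_model(spectra[[k]], cur_init, free = free)
    if (fits[[k]]$converged) cur_init <- fits[[k]]$model
  }
  lt <- do.call(rbind, lapply(seq_along(fits), function(k) {
    out <- lifetimes(fits[[k]], temperature = TK[k])
    out$converged <- fits[[k]]$converged
    out
  }))

  ok <- vapply(fits, function(f) f$converged, logical(1))
  arr <- list(stretching = NULL, libration = NULL)
  skipped <- ""
  if (sum(ok) < 3L) {
    skipped <- sprintf(
      "Arrhenius skipped: only %d of %d temperatures converged (need 3)",
      sum(ok), length(ok))
  } else {
    for (nm in c("stretching", "libration")) {
      sub <- lt[lt$mode == nm & lt$converged, ]
      arr[[nm]] <- arrhenius_fit(sub$tau_fs, sub$T_K, label = nm)
    }
  }
  structure(list(fits = fits, lifetimes = lt, arrhenius = arr,
                 T_K = TK, skipped = skipped),
            class = "thz_series")
}

#' @export
print.thz_series <- function(x, ...) {
  cat(sprintf("THz temperature series: %d temperatures (%g-%g K), %d converged\n",
              length(x$fits), min(x$T_K), max(x$T_K),
              sum(vapply(x$fits, function(f) f$converged, logical(1)))))
  if (nzchar(x$skipped)) {
    cat(" ", x$skipped, "\n")
  } else {
    for (nm in names(x$arrhenius)) print(x$arrhenius[[nm]])
  }
  invisible(x)
}

#' @export
summary.thz_series <- function(object, ...) {
  print(object)
  cat("  lifetime table:\n")
  print(object$lifetimes[, c("T_K", "mode", "tau_fs", "tau_se_fs",
                             "converged")])
  invisible(object)
}
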