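## Distance-resolved hydrogen-bond coordination profiles.

#' Hydrogen-bond profile versus distance from the membrane midplane
#'
#' Assigns each water to a bin by the folded distance of its oxygen
#' from the membrane midplane (minimum image along the normal axis),
#' and reports the per-bin mean hydrogen bonds per water molecule,
#' pooled over frames, split into water-water and water-lipid
#' contributions. Empty bins are retained with count 0 and NA means,
#' flagged, never dropped.
#'
#' @param frames List of \code{\link{md_frame}} objects (consistent
#'   roles and box).
#' @param bin_width Bin width in nm; default 0.1.
#' @param r_cut,angle_cut Criterion parameters for
#'   \code{\link{find_hbonds}}.
#' @param n_HB_bulk Optional bulk reference coordination at this
#'   temperature (from \code{\link{bulk_value}}).
#' @return Object of class \code{hb_profile}: data.frame \code{bins}
#'   with bin_center, n_total, n_ww, n_wl, count, empty; plus
#'   \code{n_HB_mean} (frame-wide mean per water), \code{n_HB_bulk},
#'   \code{temperature}.
#' @export
hb_profile <- function(frames, bin_width = 0.1, r_cut = 0.35,
                       angle_cut = 30, n_HB_bulk = NULL) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  f1 <- frames[[1L]]
  ax <- f1$normal_axis
  half <- f1$box[ax] / 2
  edges <- seq(0, half + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  nb <- length(centers)
  acc_ww <- acc_wl <- acc_n <- numeric(nb)

  for (f in frames) {
    hb <- find_hbonds(f, r_cut, angle_cut)
    wc <- .water_counts(f, hb)
    o_idx <- which(f$role == "water_O")
    o_mol <- f$mol[o_idx]
    zo <- f$positions[o_idx, ax]
    dz <- zo - f$z_mid
    if (f$pbc[ax]) dz <- dz - f$box[ax] * round(dz / f$box[ax])
    x <- abs(dz)
    bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), nb)
    ord <- match(o_mol, wc$mol)
    for (b in unique(bin)) {
      m <- bin == b
      acc_n[b] <- acc_n[b] + sum(m)
      acc_ww[b] <- acc_ww[b] + sum(wc$ww[ord][m])
      acc_wl[b] <- acc_wl[b] + sum(wc$wl[ord][m])
    }
  }
  n_ww <- ifelse(acc_n > 0, acc_ww / acc_n, NA_real_)
  n_wl <- ifelse(acc_n > 0, acc_wl / acc_n, NA_real_)
  bins <- data.frame(bin_center = centers, n_total = n_ww + n_wl,
                     n_ww = n_ww, n_wl = n_wl, count = acc_n,
                     empty = acc_n == 0)
  structure(list(bins = bins,
                 n_HB_mean = sum(acc_ww + acc_wl) / sum(acc_n),
                 n_HB_bulk = n_HB_bulk,
                 temperature = f1$temperature,
                 bin_width = bin_width, n_frames = length(frames)),
            class = "hb_profile")
}

#' @export
print.hb_profile <- function(x, ...) {
  occ <- x$bins[!x$bins$empty, ]
  cat(sprintf(
    "HB profile: %d frames, %d occupied bins (%.2f-%.2f nm), mean n_HB = %.3f\n",
    x$n_frames, nrow(occ), min(occ$bin_center), max(occ$bin_center),
    x$n_HB_mean))
  if (!is.null(x$n_HB_bulk))
    cat(sprintf("  bulk reference n_HB = %.3f\n", x$n_HB_bulk))
  invisible(x)
}

#' @export
plot.hb_profile <- function(x, ...) {
  occ <- x$bins[!x$bins$empty, ]
  graphics::plot(occ$bin_center, occ$n_total, type = "b", pch = 16,
                 xlab = "distance from midplane (nm)",
                 ylab = expression(n[HB] ~ "per water"), ...)
  graphics::lines(occ$bin_center, occ$n_ww, lty = 2, col = "steelblue")
  graphics::lines(occ$bin_center, occ$n_wl, lty = 3, col = "tomato")
  if (!is.null(x$n_HB_bulk))
    graphics::abline(h = x$n_HB_bulk, lty = 4, col = "grey40")
  invisible(x)
}

#' Bulk-recovery distance of a hydrogen-bond profile
#'
#' Smallest occupied bin center beyond which the total coordination
#' stays within \code{tol} (relative) of the bulk reference for that
#' bin and all farther occupied bins. Flagged unreached when no bin
#' qualifies.
#'
#' @param profile An \code{\link{hb_profile}} carrying a bulk
#'   reference (or pass \code{n_HB_bulk}).
#' @param tol Relative tolerance; default 0.02 (2\% of bulk).
#' @param n_HB_bulk Bulk reference override.
#' @return List with \code{x_c} (nm, NA when unreached) and
#'   \code{unreached} flag.
#' @export
bulk_recovery_distance <- function(profile, tol = 0.02, n_HB_bulk = NULL) {
  stopifnot(inherits(profile, "hb_profile"))
  bulk <- if (!is.null(n_HB_bulk)) n_HB_bulk else profile$n_HB_bulk
  if (is.null(bulk)) stop("profile has no bulk reference")
  occ <- profile$bins[!profile$bins$empty, ]
  within <- abs(occ$n_total - bulk) / bulk < tol
  ## all occupied bins from position k outward must be within tolerance
  ok_from <- rev(cumprod(rev(within))) > 0
  if (!any(ok_from)) return(list(x_c = NA_real_, unreached = TRUE))
  list(x_c = occ$bin_center[which(ok_from)[1L]], unreached = FALSE)
}

#' Arrhenius fit of the mean hydrogen-bond count over temperature
#'
#' Fits the frame-wide mean hydrogen bonds per water molecule against
#' inverse temperature (same contract as \code{\link{arrhenius_fit}}).
#'
#' @param profiles List of \code{\link{hb_profile}} objects at distinct
#'   temperatures (at least 3).
#' @return An \code{\link{arrhenius_fit}}.
#' @export
hb_arrhenius <- function(profiles) {
  stopifnot(length(profiles) >= 3L,
            all(vapply(profiles, inherits, logical(1), "hb_profile")))
  TK <- vapply(profiles, function(p) p$temperature, numeric(1))
  vals <- vapply(profiles, function(p) p$n_HB_mean, numeric(1))
  arrhenius_fit(vals, TK, label = "n_HB")
}
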