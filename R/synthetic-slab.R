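## Synthetic lamellar slab frames with imposed hydrogen-bond statistics.
##
## The generator does not simulate water physics: it places isolated
## donor-acceptor clusters on a jittered exclusion grid (guaranteed
## inter-cluster separation beyond the HB cutoff) and imposes the
## expected coordination profile by construction. Each cluster is one
## "primary" water that, with probability p, donates exactly one bond
## to a partner placed in-plane at 0.28 nm -- a water (oriented so it
## cannot donate back) or a lipid head oxygen near the headgroup band.
## With the bond indicator stratified per distance bin (exact counts
## with cross-frame dithering), the realized per-bin mean coordination
##   M(x, T) = m_b(T) * (1 - deficit(x))
## is sharp at modest frame counts. m_b(T) = C exp(E_a/(R T)) is the
## imposed bulk Arrhenius law; deficit(x) holds a constant depth out to
## ramp_start and decays as sqrt((x_edge - x)/(x_edge - ramp_start)) up
## to x_edge = head_center + shell_extent, so the 2%-of-bulk recovery
## crossing stays within one 0.1-nm bin of x_edge.

.deficit_fn <- function(x, depth, ramp_start, x_edge) {
  frac <- pmin(pmax((x_edge - x) / (x_edge - ramp_start), 0), 1)
  depth * sqrt(frac)
}

## expected mean coordination and per-cluster bond probability
.slab_targets <- function(x, m_b, gt) {
  M <- m_b * (1 - .deficit_fn(x, gt$deficit_depth, gt$ramp_start, gt$x_edge))
  g <- gt$wl_weight * exp(-(x - gt$head_center)^2 / (2 * gt$head_sd^2))
  p <- M / (2 - g - M * (1 - g))
  list(M = M, g = g, p = p)
}

.m_b_of_T <- function(gt, T_K) gt$C * exp(gt$E_a_kJmol * 1000 / (.R_gas * T_K))

#' Expected coordination profile of a synthetic slab
#'
#' Computes, from a slab generator's ground truth alone, the expected
#' mean hydrogen bonds per water at given distances from the midplane
#' and temperature.
#'
#' @param ground_truth The \code{ground_truth} element returned by
#'   \code{\link{gen_slab_frames}}.
#' @param x Distances from the membrane midplane (nm).
#' @param T_K Temperature (K).
#' @return List with \code{n_HB} (expected means at \code{x}) and
#'   \code{n_HB_bulk} (expected bulk value at \code{T_K}).
#' @export
expected_hb_profile <- function(ground_truth, x, T_K) {
  m_b <- .m_b_of_T(ground_truth, T_K)
  list(n_HB = .slab_targets(x, m_b, ground_truth)$M, n_HB_bulk = m_b)
}

## build one frame from clusters; env$acc carries the stratified-bond
## accumulator across frames (one slot per 0.1-nm distance bin)
.build_cluster_frame <- function(box, z_mid, m_b, gt, env, TK,
                                 pure_water = FALSE,
                                 z_shift_frac = stats::runif(1)) {
  nxyz <- pmax(floor(box / 1.0), 1L)
  sp <- box / nxyz
  if (min(sp) - 2 * gt$jitter < 0.91)
    stop("cluster grid too dense: clusters would overlap within the HB cutoff")
  g0 <- as.matrix(expand.grid(
    x = (seq_len(nxyz[1]) - 0.5) * sp[1],
    y = (seq_len(nxyz[2]) - 0.5) * sp[2],
    z = (seq_len(nxyz[3]) - 0.5) * sp[3]))
  nc <- nrow(g0)
  ## uniform whole-lattice shift per frame: preserves every
  ## inter-cluster separation (spacing divides the box exactly) while
  ## sampling the distance-from-midplane coordinate continuously; the
  ## z fraction is stratified across frames by the caller so the frame
  ## ensemble covers the deficit ramp evenly
  shift <- c(stats::runif(2, 0, sp[1:2]), z_shift_frac * sp[3])
  centers <- g0 + matrix(shift, nc, 3, byrow = TRUE) +
    matrix(stats::runif(3 * nc, -gt$jitter, gt$jitter), nc, 3)
  centers <- centers %% matrix(box, nc, 3, byrow = TRUE)
  dz <- centers[, 3] - z_mid
  dz <- dz - box[3] * round(dz / box[3])
  xdist <- abs(dz)
  tg <- if (pure_water) {
    list(M = rep(m_b, nc), g = rep(0, nc),
         p = rep(m_b / (2 - m_b), nc))
  } else .slab_targets(xdist, m_b, gt)

  ## stratified bond assignment: per distance bin, floor-dither the
  ## cumulative target count so pooled means are exact to one bond
  bin <- floor(xdist / 0.1) + 1L
  bonded <- logical(nc)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    key <- as.character(b)
    ## random accumulator phase makes the floor-dither rounding unbiased
    prev <- if (is.null(env$acc[[key]])) stats::runif(1) else env$acc[[key]]
    tot <- prev + sum(tg$p[idx])
    nb <- floor(tot)
    env$acc[[key]] <- tot - nb
    if (nb > 0) bonded[sample(idx, min(nb, length(idx)))] <- TRUE
  }

  ## assemble atoms
  pos <- list(); role <- list(); mol <- list()
  mol_id <- 0L
  ang_h2 <- 104.5 * pi / 180
  for (i in seq_len(nc)) {
    phi <- stats::runif(1, 0, 2 * pi)
    d <- c(cos(phi), sin(phi), 0)
    e <- c(-sin(phi), cos(phi), 0)
    ctr <- centers[i, ]
    mol_id <- mol_id + 1L
    ## primary water: O at center, H1 along d, H2 at 104.5 deg in-plane
    pos[[length(pos) + 1L]] <- rbind(
      ctr, ctr + 0.1 * d, ctr + 0.1 * (cos(ang_h2) * d + sin(ang_h2) * e))
    role[[length(role) + 1L]] <- c("water_O", "water_H", "water_H")
    mol[[length(mol) + 1L]] <- rep(mol_id, 3L)
    if (bonded[i]) {
      po <- ctr + 0.28 * d
      mol_id <- mol_id + 1L
      if (!pure_water && stats::runif(1) < tg$g[i]) {
        ## lipid head oxygen accepts the bond
        pos[[length(pos) + 1L]] <- rbind(po)
        role[[length(role) + 1L]] <- "lipid_acceptor_heavy"
        mol[[length(mol) + 1L]] <- mol_id
      } else {
        ## partner water oriented so it cannot donate back (H at 120
        ## deg from the partner->primary axis)
        h1 <- po + 0.1 * (0.5 * d + sin(2 * pi / 3) * e)
        h2 <- po + 0.1 * (0.5 * d - sin(2 * pi / 3) * e)
        pos[[length(pos) + 1L]] <- rbind(po, h1, h2)
        role[[length(role) + 1L]] <- c("water_O", "water_H", "water_H")
        mol[[length(mol) + 1L]] <- rep(mol_id, 3L)
      }
    }
  }
  md_frame(do.call(rbind, pos), unlist(role), unlist(mol), box,
           temperature = TK, z_mid = z_mid)
}

#' Generate synthetic slab frames with imposed hydrogen-bond statistics
#'
#' Emits, per temperature, slab coordinate frames whose expected
#' coordination profile carries an interfacial deficit ramp of depth
#' \code{deficit_depth} vanishing at \code{head_center + shell_extent},
#' plus matching pure-water bulk boxes; the frame-wide expected
#' coordination follows an Arrhenius law in temperature. Water-lipid
#' bonds are concentrated in a Gaussian band around
#' \code{head_center}. All imposed expectations are recorded in the
#' ground truth and recoverable via \code{\link{expected_hb_profile}}.
#'
#' @param box Slab box edges (nm); default \code{c(5, 5, 7)} with the
#'   membrane normal along z.
#' @param head_center Headgroup band center distance from the midplane
#'   (nm); default 1.5.
#' @param head_sd Headgroup band Gaussian width (nm); default 0.3.
#' @param shell_extent Undercoordination shell beyond the interface
#'   (nm); default 0.9.
#' @param deficit_depth Maximum fractional coordination deficit;
#'   default 0.14.
#' @param ramp_start Distance (nm) out to which the deficit holds its
#'   full depth; default 1.0.
#' @param T_grid Temperatures (K); default \code{seq(308, 338, by = 5)}.
#' @param frames_per_T Frames per temperature (slab and bulk each);
#'   default 10.
#' @param E_a_kJmol Imposed Arrhenius activation energy of the mean
#'   coordination; default 1.48.
#' @param nHB_ref Imposed bulk coordination at \code{T_ref}; default
#'   0.9 (dimer-statistics scale, not a physical water coordination).
#' @param T_ref Reference temperature for \code{nHB_ref}; default 308.
#' @param wl_weight Peak fraction of bonds routed to lipid heads in
#'   the headgroup band; default 0.6.
#' @param bulk_box Bulk water box edge (nm); default 5.
#' @param seed RNG seed.
#' @return List with \code{slab} (per-T list of frame lists),
#'   \code{bulk} (per-T list of pure-water frame lists), and
#'   \code{ground_truth}.
#' @export
gen_slab_frames <- function(box = c(5, 5, 7), head_center = 1.5,
                            head_sd = 0.3, shell_extent = 0.9,
                            deficit_depth = 0.14, ramp_start = 1.0,
                            T_grid = seq(308, 338, by = 5),
                            frames_per_T = 10L, E_a_kJmol = 1.48,
                            nHB_ref = 0.9, T_ref = 308,
                            wl_weight = 0.6, bulk_box = 5, seed = 1L) {
  if (deficit_depth < 0 || deficit_depth >= 1)
    stop("deficit_depth must lie in [0, 1)")
  x_edge <- head_center + shell_extent
  if (box[3] / 2 < x_edge + 0.5)
    stop("box does not accommodate the slab plus recovered bulk water")
  set.seed(as.integer(seed))
  gt <- list(generator = "gen_slab_frames", seed = as.integer(seed),
             box = box, bulk_box = bulk_box, head_center = head_center,
             head_sd = head_sd, shell_extent = shell_extent,
             x_edge = x_edge, deficit_depth = deficit_depth,
             ramp_start = ramp_start, wl_weight = wl_weight,
             E_a_kJmol = E_a_kJmol,
             C = nHB_ref / exp(E_a_kJmol * 1000 / (.R_gas * T_ref)),
             T_grid = T_grid, frames_per_T = as.integer(frames_per_T),
             jitter = 0.02,
             noise = "stratified Bernoulli pairing, floor-dithered per bin")

  slab <- bulk <- stats::setNames(vector("list", length(T_grid)),
                                  as.character(T_grid))
  for (k in seq_along(T_grid)) {
    TK <- T_grid[k]
    m_b <- .m_b_of_T(gt, TK)
    if (m_b >= 1) stop("imposed bulk coordination must stay below 1")
    env_s <- new.env(); env_s$acc <- list()
    env_b <- new.env(); env_b$acc <- list()
    strat <- (sample(frames_per_T) - 1 +
                stats::runif(frames_per_T)) / frames_per_T
    slab[[k]] <- lapply(seq_len(frames_per_T), function(j)
      .build_cluster_frame(box, box[3] / 2, m_b, gt, env_s, TK,
                           z_shift_frac = strat[j]))
    bulk[[k]] <- lapply(seq_len(frames_per_T), function(j)
      .build_cluster_frame(rep(bulk_box, 3), bulk_box / 2, m_b, gt,
                           env_b, TK, pure_water = TRUE))
  }
  list(slab = slab, bulk = bulk, ground_truth = gt)
}

#' Serialize a generator's ground truth to JSON
#'
#' @param ground_truth A generator ground-truth list.
#' @param path Output file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
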