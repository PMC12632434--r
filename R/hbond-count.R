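## Geometric hydrogen-bond counting.
##
## Criterion (canonical geometric definition, configurable): donor
## heavy-atom to acceptor heavy-atom distance <= r_cut (default 0.35
## nm) under the minimum-image convention, AND the H-donor-acceptor
## angle at the donor (between donor->H and donor->acceptor) <=
## angle_cut (default 30 degrees), for every donor H. Donors: water O
## and lipid O bearing an H; acceptors: water O and any lipid O. Only
## water-involving bonds (w-w, w-l) are recorded.

#' Find hydrogen bonds in a frame
#'
#' @param frame An \code{\link{md_frame}}.
#' @param r_cut Donor-acceptor heavy-atom distance cutoff (nm).
#'   Default 0.35.
#' @param angle_cut H-donor-acceptor angle cutoff (degrees). Default 30.
#' @param method \code{"cell"} (linked-cell neighbor list, default) or
#'   \code{"brute"} (all-pairs reference); both give identical bond sets.
#' @return data.frame with one row per hydrogen bond: donor_mol,
#'   acceptor_mol, kind ("w-w" or "w-l"), distance_nm, angle_deg,
#'   donor_atom, h_atom, acceptor_atom; sorted for set comparison.
#' @examples
#' # ideal linear water dimer, O-O 0.28 nm, donor H on the axis
#' pos <- rbind(c(1, 1, 1),   c(1.1, 1, 1),   c(0.94, 1.08, 1),
#'              c(1.28, 1, 1), c(1.34, 1.08, 1), c(1.34, 0.92, 1))
#' f <- md_frame(pos, rep(c("water_O", "water_H", "water_H"), 2),
#'               rep(1:2, each = 3), box = c(2, 2, 2))
#' find_hbonds(f)
#' @export
find_hbonds <- function(frame, r_cut = 0.35, angle_cut = 30,
                        method = c("cell", "brute")) {
  stopifnot(inherits(frame, "md_frame"))
  method <- match.arg(method)
  if (any(frame$pbc & frame$box <= 2 * r_cut))
    stop("box too small for minimum image at r_cut")
  pos <- frame$positions; role <- frame$role; mol <- frame$mol
  box <- frame$box; pbc <- frame$pbc

  don <- which(role %in% c("water_O", "lipid_donor_heavy"))
  acc <- which(role %in% c("water_O", "lipid_donor_heavy",
                           "lipid_acceptor_heavy"))
  if (!length(don) || !length(acc)) return(.empty_hb_table())
  ## hydrogens attached to each donor heavy atom, by molecule
  hyd <- which(role %in% c("water_H", "lipid_H"))
  h_by_mol <- split(hyd, mol[hyd])

  cand_fn <- if (method == "brute") {
    function(i) acc
  } else {
    .cell_candidates(pos, acc, box, pbc, r_cut)
  }

  out <- vector("list", length(don))
  cosang <- cos(angle_cut * pi / 180)
  for (k in seq_along(don)) {
    i <- don[k]
    js <- cand_fn(i)
    js <- js[mol[js] != mol[i]]
    if (!length(js)) next
    d <- .min_image(pos[js, , drop = FALSE] -
                      matrix(pos[i, ], length(js), 3, byrow = TRUE),
                    box, pbc)
    dist <- sqrt(rowSums(d * d))
    keep <- dist <= r_cut
    if (!any(keep)) next
    js <- js[keep]; d <- d[keep, , drop = FALSE]; dist <- dist[keep]
    hs <- h_by_mol[[as.character(mol[i])]]
    if (is.null(hs)) next
    rows <- list()
    for (h in hs) {
      dh <- .min_image(matrix(pos[h, ] - pos[i, ], 1, 3), box, pbc)[1, ]
      ndh <- sqrt(sum(dh * dh))
      if (ndh == 0) next
      cosv <- (d %*% dh) / (dist * ndh)
      bond <- cosv >= cosang - 1e-12
      if (any(bond)) {
        ja <- js[bond]
        kind <- ifelse(role[i] == "water_O" & role[ja] == "water_O",
                       "w-w", "w-l")
        ## drop lipid-lipid pairs (neither side water)
        waterside <- role[i] == "water_O" | role[ja] == "water_O"
        if (any(waterside))
          rows[[length(rows) + 1L]] <- data.frame(
            donor_mol = mol[i], acceptor_mol = mol[ja],
            kind = kind, distance_nm = dist[bond],
            angle_deg = acos(pmin(pmax(cosv[bond], -1), 1)) * 180 / pi,
            donor_atom = i, h_atom = h, acceptor_atom = ja,
            stringsAsFactors = FALSE)[waterside, , drop = FALSE]
      }
    }
    if (length(rows)) out[[k]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_hb_table())
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$donor_atom, tab$h_atom, tab$acceptor_atom), ]
  rownames(tab) <- NULL
  tab
}

.empty_hb_table <- function() {
  data.frame(donor_mol = integer(0), acceptor_mol = integer(0),
             kind = character(0), distance_nm = numeric(0),
             angle_deg = numeric(0), donor_atom = integer(0),
             h_atom = integer(0), acceptor_atom = integer(0),
             stringsAsFactors = FALSE)
}

## Linked-cell candidate lookup over the acceptor set. Returns a
## closure index -> candidate acceptor indices (27 neighbor cells with
## periodic wrap; duplicates removed so small cell counts stay exact).
.cell_candidates <- function(pos, acc, box, pbc, r_cut) {
  nc <- pmax(floor(box / r_cut), 1)
  cell_of <- function(idx) {
    cc <- floor(t(pos[idx, , drop = FALSE]) / (box / nc))
    pmin(pmax(cc, 0), nc - 1)  # 3 x m integer cell coords
  }
  acc_cells <- cell_of(acc)
  lin <- acc_cells[1, ] + nc[1] * (acc_cells[2, ] + nc[2] * acc_cells[3, ])
  acc_by_cell <- split(acc, lin)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  function(i) {
    ci <- cell_of(i)[, 1L]
    nbr <- t(offs) + ci          # 3 x 27
    for (k in 1:3) {
      if (pbc[k]) nbr[k, ] <- nbr[k, ] %% nc[k]
      else nbr[k, ] <- pmin(pmax(nbr[k, ], 0), nc[k] - 1)
    }
    ids <- unique(nbr[1, ] + nc[1] * (nbr[2, ] + nc[2] * nbr[3, ]))
    unique(unlist(acc_by_cell[as.character(ids)], use.names = FALSE))
  }
}

## per-water bond counts from an HB table: each w-w bond contributes one
## to both waters, each w-l bond one to its water side
.water_counts <- function(frame, hb) {
  wmol <- unique(frame$mol[frame$role == "water_O"])
  ww <- stats::setNames(numeric(length(wmol)), wmol)
  wl <- ww
  if (nrow(hb)) {
    iww <- hb$kind == "w-w"
    t1 <- table(c(hb$donor_mol[iww], hb$acceptor_mol[iww]))
    ww[names(t1)] <- ww[names(t1)] + as.numeric(t1)
    iwl <- hb$kind == "w-l"
    ## the water side of a w-l bond is whichever molecule is a water
    wside <- ifelse(hb$donor_mol[iwl] %in% wmol,
                    hb$donor_mol[iwl], hb$acceptor_mol[iwl])
    t2 <- table(wside)
    wl[names(t2)] <- wl[names(t2)] + as.numeric(t2)
  }
  list(mol = as.integer(names(ww)), ww = unname(ww), wl = unname(wl))
}

#' Bulk hydrogen-bond coordination of a pure water box
#'
#' Mean number of hydrogen bonds per water molecule over frames of a
#' pure water box (no lipid roles allowed).
#'
#' @param frames List of \code{md_frame} objects containing only water.
#' @param r_cut,angle_cut Criterion parameters, as in
#'   \code{\link{find_hbonds}}.
#' @return Mean HBs per water molecule (a single number).
#' @export
bulk_value <- function(frames, r_cut = 0.35, angle_cut = 30) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  per_frame <- vapply(frames, function(f) {
    if (any(f$role %in% c("lipid_donor_heavy", "lipid_acceptor_heavy",
                          "lipid_H")))
      stop("bulk_value expects pure water frames")
    hb <- find_hbonds(f, r_cut, angle_cut)
    wc <- .water_counts(f, hb)
    mean(wc$ww + wc$wl)
  }, numeric(1))
  mean(per_frame)
}
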