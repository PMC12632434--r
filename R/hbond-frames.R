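## Molecular coordinate frames for hydrogen-bond analysis.
##
## A frame is a light container: positions in nm, a role per atom
## (water_O, water_H, lipid_donor_heavy, lipid_acceptor_heavy, lipid_H,
## other), a molecule index, an orthorhombic box with periodic flags,
## and the membrane geometry (normal axis, midplane coordinate).

.frame_roles <- c("water_O", "water_H", "lipid_donor_heavy",
                  "lipid_acceptor_heavy", "lipid_H", "other")

#' Construct a coordinate frame
#'
#' @param positions n x 3 numeric matrix of Cartesian coordinates (nm).
#' @param role Character vector of atom roles, one of
#'   \code{water_O, water_H, lipid_donor_heavy, lipid_acceptor_heavy,
#'   lipid_H, other}.
#' @param mol Integer molecule index per atom.
#' @param box Orthorhombic box edge lengths (nm), length 3.
#' @param pbc Logical length-3 periodic flags; default all TRUE.
#' @param temperature K.
#' @param normal Membrane normal axis: "x", "y" or "z" (default "z").
#' @param z_mid Membrane midplane coordinate along the normal (nm);
#'   default half the box edge.
#' @return Object of class \code{md_frame}. Waters must have exactly
#'   one O and two H per molecule; positions are wrapped into the box.
#' @export
md_frame <- function(positions, role, mol, box, pbc = c(TRUE, TRUE, TRUE),
                     temperature = NA_real_, normal = "z", z_mid = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be n x 3")
  n <- nrow(positions)
  if (length(role) != n || length(mol) != n)
    stop("role and mol must have one entry per atom")
  if (!all(role %in% .frame_roles))
    stop("unknown atom role(s): ",
         paste(setdiff(unique(role), .frame_roles), collapse = ", "))
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  ## water topology check: 1 O + 2 H per water molecule
  wmask <- role %in% c("water_O", "water_H")
  if (any(wmask)) {
    tab <- table(mol[wmask], role[wmask])
    if (!all(tab[, "water_O"] == 1L) || !all(tab[, "water_H"] == 2L))
      stop("every water molecule must have exactly 1 O and 2 H")
  }
  ## wrap into [0, box)
  for (d in 1:3)
    if (pbc[d]) positions[, d] <- positions[, d] %% box[d]
  ax <- match(match.arg(normal, c("x", "y", "z")), c("x", "y", "z"))
  if (is.null(z_mid)) z_mid <- box[ax] / 2
  structure(list(positions = positions, role = role, mol = as.integer(mol),
                 box = as.numeric(box), pbc = as.logical(pbc),
                 temperature = temperature, normal_axis = ax,
                 z_mid = z_mid),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("Coordinate frame: %d atoms (%d waters), box %s nm, T = %s K\n",
              nrow(x$positions), sum(x$role == "water_O"),
              paste(sprintf("%.2f", x$box), collapse = " x "),
              format(x$temperature)))
  invisible(x)
}

## minimum-image displacement matrix rows (vectorized over rows of d)
.min_image <- function(d, box, pbc) {
  for (k in 1:3)
    if (pbc[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Read coordinate frames from a PDB file
#'
#' Multi-model PDB files become one frame per MODEL. Roles are
#' assigned from a role map (atom name to role); unmapped atoms become
#' \code{other}. Molecules are taken from residue numbers. PDB
#' coordinates (Angstrom) are converted to nm.
#'
#' @param path PDB file.
#' @param role_map Named character vector or list: atom name -> role.
#' @param box Box edge lengths in nm (PDB CRYST1 is used when present).
#' @param temperature,normal,z_mid Passed to \code{\link{md_frame}}.
#' @return List of \code{md_frame} objects.
#' @export
read_frames_pdb <- function(path, role_map, box = NULL,
                            temperature = NA_real_, normal = "z",
                            z_mid = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  role <- unname(unlist(role_map)[at$elety])
  role[is.na(role)] <- "other"
  mol <- as.integer(factor(paste(at$chain, at$resno)))
  if (is.null(box)) {
    cl <- pdb$cryst1$abc
    if (!is.null(cl)) box <- cl / 10 else stop("no CRYST1: supply box")
  }
  nmod <- dim(pdb$xyz)[1L]
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE) / 10
    md_frame(xyz, role, mol, box, temperature = temperature,
             normal = normal, z_mid = z_mid)
  })
}

#' Read coordinate frames from a GRO file
#'
#' Fixed-column GROMACS coordinate format (nm), possibly with several
#' concatenated frames. Roles from a role map on atom names.
#'
#' @inheritParams read_frames_pdb
#' @param path GRO file.
#' @return List of \code{md_frame} objects.
#' @export
read_frames_gro <- function(path, role_map, temperature = NA_real_,
                            normal = "z", z_mid = NULL) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); i <- 1L
  rmap <- unlist(role_map)
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) break
    body <- lines[(i + 2L):(i + 1L + n)]
    resno <- as.integer(substr(body, 1, 5))
    aname <- trimws(substr(body, 11, 15))
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    boxline <- strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1L]]
    box <- as.numeric(boxline[1:3])
    role <- unname(rmap[aname]); role[is.na(role)] <- "other"
    frames[[length(frames) + 1L]] <-
      md_frame(cbind(x, y, z), role, resno, box, temperature = temperature,
               normal = normal, z_mid = z_mid)
    i <- i + 3L + n
  }
  frames
}
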