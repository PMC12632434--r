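## Cubic space groups of the inverse bicontinuous mesophases.
##
## Each bilayer drapes a triply periodic minimal surface: gyroid (Ia3d),
## diamond (Pn3m) or primitive (Im3m). A0 is the surface area of the
## minimal surface per unit cell normalized by a^2; chi is the
## Euler-Poincare characteristic of the surface in the unit cell.
## reflections are the allowed N = h^2+k^2+l^2 under each group's
## extinction rules, ascending.

.space_group_table <- list(
  Ia3d = list(name = "Ia3d", A0 = 3.091, chi = -8L,
              reflections = c(6L, 8L, 14L, 16L, 20L, 22L, 24L, 26L, 30L, 32L)),
  Pn3m = list(name = "Pn3m", A0 = 1.919, chi = -2L,
              reflections = c(2L, 3L, 4L, 6L, 8L, 9L, 10L, 11L, 12L, 14L)),
  Im3m = list(name = "Im3m", A0 = 2.345, chi = -4L,
              reflections = c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L, 18L, 20L))
)

#' Cubic space-group specification
#'
#' Returns the geometric and crystallographic constants of one of the
#' three inverse bicontinuous cubic space groups: the normalized unit-cell
#' minimal-surface area \eqn{A_0}, the Euler-Poincare characteristic
#' \eqn{\chi} and the allowed reflection sequence
#' \eqn{N = h^2 + k^2 + l^2} (first reflections \{6,8\} for Ia3d,
#' \{2,3\} for Pn3m, \{2,4\} for Im3m).
#'
#' @param name One of \code{"Ia3d"}, \code{"Pn3m"}, \code{"Im3m"}.
#' @return An object of class \code{space_group}: a list with elements
#'   \code{name}, \code{A0}, \code{chi} and \code{reflections}.
#' @examples
#' space_group("Pn3m")$reflections[1:2]  # 2 3
#' @export
space_group <- function(name) {
  name <- match.arg(name, names(.space_group_table))
  structure(.space_group_table[[name]], class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("Cubic space group %s: A0 = %.3f, chi = %d\n",
              x$name, x$A0, x$chi))
  cat("  allowed N = h^2+k^2+l^2:", paste(x$reflections, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname space_group
#' @details \code{space_groups()} returns all three specifications as a
#'   named list, in the order Ia3d, Pn3m, Im3m.
#' @export
space_groups <- function() {
  lapply(stats::setNames(names(.space_group_table),
                         names(.space_group_table)), space_group)
}

as_space_group <- function(x) {
  if (inherits(x, "space_group")) return(x)
  if (is.character(x) && length(x) == 1L) return(space_group(x))
  stop("expected a space_group object or one of 'Ia3d', 'Pn3m', 'Im3m'")
}

## sqrt(A0 / (-2 pi chi)): the dimensionless channel-radius coefficient;
## also the turning point of the lipid-length cubic.
.radius_coef <- function(sg) sqrt(sg$A0 / (-2 * pi * sg$chi))
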