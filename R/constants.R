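## Physical constants and literature reference values used across modules.

## speed of light in cm/s -- converts a Lorentzian width in cm^-1 to a
## lifetime in seconds via tau = 1/(omega * c)
.c_cm_s <- 2.99792458e10

## molar gas constant, J mol^-1 K^-1
.R_gas <- 8.314

#' Reference Arrhenius activation energies for monolinolein-sugar-ester
#' mesophases
#'
#' Literature activation energies (kJ/mol) of the intermolecular
#' hydrogen-bond stretching and libration modes of water confined in
#' swollen monolinolein-sugar-ester cubic mesophases at three hydration
#' levels (30, 40 and 50 wt.% water), as obtained from terahertz
#' absorption spectroscopy. Useful as plausibility references when
#' analysing comparable systems: the libration barrier is roughly twice
#' the stretching barrier at every hydration.
#'
#' @return A data.frame with columns \code{sample} (hydration label),
#'   \code{hydration} (weight fraction of water), \code{ea_stretching}
#'   and \code{ea_libration} (kJ/mol).
#' @examples
#' ea <- ea_reference()
#' ea$ea_libration / ea$ea_stretching
#' @export
ea_reference <- function() {
  data.frame(
    sample        = c("W30", "W40", "W50"),
    hydration     = c(0.30, 0.40, 0.50),
    ea_stretching = c(3.52, 3.01, 2.19),
    ea_libration  = c(7.44, 6.77, 5.27),
    stringsAsFactors = FALSE
  )
}
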