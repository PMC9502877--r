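# Physical constants, cgs units throughout the model internals.
# kB in g cm^2 s^-2 K^-1; N_A chosen from the same CODATA vintage so that
# molar masses in g/mol and densities in g/cm^3 convert consistently.
.kB <- 1.380658e-16
.NAvogadro <- 6.0221367e23

#' Physical constants used by the model
#'
#' Returns the Boltzmann constant and Avogadro number the model is built on.
#' All internal computation is carried out in cgs units (cm, g, s, K); these
#' values are fixed and not configurable, so that published parameter sets
#' remain reproducible.
#'
#' @return Named list with `boltzmann` (g cm^2 s^-2 K^-1) and
#'   `avogadro` (mol^-1).
#' @export
#' @examples
#' d12_constants()$boltzmann
d12_constants <- function() {
  list(boltzmann = .kB, avogadro = .NAvogadro)
}
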