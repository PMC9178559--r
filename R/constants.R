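# Monoisotopic mass constants (Da). Residue masses are the standard
# monoisotopic amino-acid residue masses; physical constants follow CODATA.

#' @keywords internal
PROTON_MASS <- 1.00727646677

#' @keywords internal
H2O_MASS <- 18.0105646863

#' @keywords internal
NH3_MASS <- 17.0265491015

# C13 - C12 spacing used for isotope envelopes and deisotoping
#' @keywords internal
ISOTOPE_SPACING <- 1.0033548378

# CH3SOH (methanesulfenic acid), the characteristic loss of sulfoxide stubs
#' @keywords internal
CH3SOH_MASS <- 63.99828592

#' @keywords internal
AA_MONO_MASS <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918496, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

# Default fixed modification: carbamidomethylation of cysteine
#' @keywords internal
CARBAMIDOMETHYL_MASS <- 57.021464

#' Common variable-modification catalog
#'
#' Returns the catalog of variable modifications used throughout the
#' package: methionine oxidation, asparagine/glutamine deamidation,
#' aspartate/glutamate methylation, and (when a crosslinker is supplied)
#' its hydrolyzed (-OH) and amidated (-NH2) dead-end forms on lysine and
#' the protein N-terminus.
#'
#' @param crosslinker Optional [crosslinker()] object whose hydrolyzed and
#'   amidated dead-end masses are appended to the catalog.
#' @return A tibble with columns `label`, `residues` (string of one-letter
#'   codes), `mass` (Da) and `nterm` (logical; may sit on the protein
#'   N-terminus).
#' @export
#' @examples
#' default_mod_catalog()
default_mod_catalog <- function(crosslinker = NULL) {
  cat <- tibble::tibble(
    label    = c("ox", "deam", "meth"),
    residues = c("M", "NQ", "ED"),
    mass     = c(15.994915, 0.984016, 14.015650),
    nterm    = c(FALSE, FALSE, FALSE)
  )
  if (!is.null(crosslinker)) {
    cat <- dplyr::bind_rows(cat, tibble::tibble(
      label    = paste0(crosslinker$name, c("-OH", "-NH2")),
      residues = c("K", "K"),
      mass     = c(crosslinker$hydrolyzed_mod, crosslinker$amidated_mod),
      nterm    = c(TRUE, TRUE)
    ))
  }
  cat
}
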