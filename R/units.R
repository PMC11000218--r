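#' Physical constants and unit conversions
#'
#' The model systems work in reduced units (kT = 1); laboratory units enter
#' only at the reporting boundary. The gas constant is kept in kcal/mol/K
#' because binding free energies are conventionally reported in kcal/mol,
#' while metadynamics hill heights are conventionally given in kJ/mol.
#'
#' @name units
NULL

#' Gas constant in kcal/mol/K
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Avogadro constant in 1/mol
#' @export
AVOGADRO <- 6.02214076e23

#' Convert kJ/mol to kcal/mol
#' @param x energy in kJ/mol
#' @return energy in kcal/mol
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Convert kcal/mol to kJ/mol
#' @param x energy in kcal/mol
#' @return energy in kJ/mol
#' @export
kcal_to_kj <- function(x) x * 4.184

#' Convert an energy between declared units
#'
#' Supported units: `"kcal/mol"`, `"kJ/mol"` and `"kT"` (the latter requires
#' `kT_kcal`, the thermal energy expressed in kcal/mol).
#'
#' @param x numeric energy values
#' @param from,to unit strings
#' @param kT_kcal thermal energy in kcal/mol, needed when either unit is "kT"
#' @return converted energies
#' @export
convert_energy <- function(x, from, to, kT_kcal = NULL) {
  units <- c("kcal/mol", "kJ/mol", "kT")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(x)
  if ((from == "kT" || to == "kT") && is.null(kT_kcal))
    stop("kT_kcal is required to convert to or from kT units")
  in_kcal <- switch(from,
    "kcal/mol" = x,
    "kJ/mol" = kj_to_kcal(x),
    "kT" = x * kT_kcal)
  switch(to,
    "kcal/mol" = in_kcal,
    "kJ/mol" = kcal_to_kj(in_kcal),
    "kT" = in_kcal / kT_kcal)
}
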