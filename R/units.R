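#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Default cell volume used for molecule/concentration conversion
#'
#' The merged model expresses every species in nM. Receptor abundances in the
#' trafficking module are published as molecules per cell; they are converted
#' to concentrations using a cell volume of 2.27e-12 L.
#'
#' @return Volume in liters.
#' @export
default_cell_volume <- function() 2.27e-12

#' Convert molecule counts to nanomolar concentration
#'
#' @param count Number of molecules (>= 0).
#' @param volume Compartment volume in liters (> 0); defaults to the cell
#'   volume of 2.27e-12 L.
#' @return Concentration in nM.
#' @examples
#' molecules_to_concentration(1367, 2.27e-12) # ~1 nM
#' @export
molecules_to_concentration <- function(count, volume = default_cell_volume()) {
  if (any(volume <= 0)) stop("volume must be positive", call. = FALSE)
  if (any(count < 0)) stop("molecule count must be nonnegative", call. = FALSE)
  count / (AVOGADRO * volume) * 1e9
}

#' Convert nanomolar concentration to molecule counts
#'
#' Inverse of [molecules_to_concentration()]; the round trip is the identity
#' up to floating-point error.
#'
#' @param conc Concentration in nM (>= 0).
#' @param volume Compartment volume in liters (> 0).
#' @return Number of molecules (not rounded).
#' @export
concentration_to_molecules <- function(conc, volume = default_cell_volume()) {
  if (any(volume <= 0)) stop("volume must be positive", call. = FALSE)
  if (any(conc < 0)) stop("concentration must be nonnegative", call. = FALSE)
  conc * 1e-9 * AVOGADRO * volume
}
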