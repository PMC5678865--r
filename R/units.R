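#' @keywords internal
"_PACKAGE"

#' @useDynLib cxcl12grad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

AVOGADRO <- 6.02214076e23

#' Molecules per nanomolar in a compartment volume
#'
#' Unit bridge between receptor-level molecule counts and continuum
#' concentrations: the number of molecules corresponding to 1 nM in a
#' compartment of volume `volume_l` liters. For the default 10-um voxel
#' (1 pL) this is about 602 molecules.
#'
#' @param volume_l compartment volume in liters.
#' @return molecules per nM (dimensionless count).
#' @export
molecules_per_nM <- function(volume_l = 1e-12) {
  1e-9 * volume_l * AVOGADRO
}

#' Molecule-count difference across a cell for a given gradient
#'
#' Converts a chemokine gradient (nM/um) into the difference in molecule
#' numbers sensed across a cell body: the concentration difference over one
#' cell diameter expressed as molecules in the given compartment volume.
#' A 0.002 nM/um gradient across a 10-um cell in a 1-pL compartment is about
#' 12 molecules, the scale reported to suffice for chemotactic sensing.
#'
#' @param gradient gradient magnitude in nM/um (>= 0).
#' @param cell_diameter cell diameter in um.
#' @param volume_l compartment volume in liters.
#' @return molecule count difference (not rounded).
#' @export
#' @examples
#' molecules_across_cell(0.002)
molecules_across_cell <- function(gradient, cell_diameter = 10,
                                  volume_l = 1e-12) {
  stopifnot(all(gradient >= 0), cell_diameter >= 0, volume_l >= 0)
  gradient * cell_diameter * molecules_per_nM(volume_l)
}
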