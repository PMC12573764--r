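# Physical constants and unit conversions.
# Internal working units are Hartree and bohr; user-facing geometry is in
# Angstrom and excitation thresholds in eV.

#' Unit conversion constants
#'
#' @format Named numeric constants used throughout the package:
#'   `bohr_per_angstrom` (1 Angstrom = 1/0.52917721092 bohr) and
#'   `ev_per_hartree` (1 Hartree = 27.211386 eV).
#' @name units
NULL

.BOHR_PER_ANGSTROM <- 1 / 0.52917721092
.EV_PER_HARTREE <- 27.211386

#' Convert Angstrom to bohr
#' @param x length in Angstrom
#' @return length in bohr
#' @export
ang_to_bohr <- function(x) x * .BOHR_PER_ANGSTROM

#' Convert bohr to Angstrom
#' @param x length in bohr
#' @return length in Angstrom
#' @export
bohr_to_ang <- function(x) x / .BOHR_PER_ANGSTROM

#' Convert Hartree to eV
#' @param x energy in Hartree
#' @return energy in eV
#' @export
hartree_to_ev <- function(x) x * .EV_PER_HARTREE

#' Convert eV to Hartree
#' @param x energy in eV
#' @return energy in Hartree
#' @export
ev_to_hartree <- function(x) x / .EV_PER_HARTREE
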