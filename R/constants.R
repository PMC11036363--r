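#' Physical constants and unit conversions
#'
#' Internal unit system: kcal/mol (energy), Angstrom (length), degrees
#' (angles), amu (mass), femtoseconds (time), g/cm^3 (density).
#'
#' @name constants
#' @keywords internal
NULL

## Boltzmann constant, kcal/mol/K
KB <- 1.987204e-3

## 1 atm * Angstrom^3 in kcal/mol (pressure-volume work conversion)
ATM_A3_TO_KCAL <- 1.4584e-5

## amu * Angstrom^3 -> g/cm^3
AMU_A3_TO_GCC <- 1.66053907

## Coulomb constant for charges in e, distances in Angstrom, energy kcal/mol
COULOMB <- 332.063713

## (kcal/mol/Angstrom) / amu -> Angstrom/fs^2
KCAL_MOL_A_AMU <- 4.184e-4

#' Boltzmann constant in kcal/mol/K
#' @return numeric scalar
#' @export
boltzmann_kcal <- function() KB

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
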