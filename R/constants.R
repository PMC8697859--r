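#' Physical constants and unit conversions
#'
#' All unit handling in the package goes through this one table.  The working
#' units at every interface are: distances in Angstrom, vibrational constants
#' in cm^-1, energies in eV, masses in unified atomic mass units (u).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{cm1_to_eV}{1 cm^-1 expressed in eV (1.239841984e-4).}
#'   \item{eV_to_cm1}{inverse of the above.}
#'   \item{wavenumber_factor}{factor F such that a harmonic force constant k
#'     in eV/Angstrom^2 acting on a reduced mass m in u vibrates at
#'     F * sqrt(k / m) cm^-1.}
#' }
#' @export
spectro_constants <- local({
  eV_J   <- 1.602176634e-19      # J per eV
  u_kg   <- 1.66053906660e-27    # kg per u
  c_cms  <- 2.99792458e10        # speed of light, cm/s
  # k [eV/A^2] -> N/m is eV_J / 1e-20; omega = sqrt(k/m); nu~ = omega/(2 pi c)
  wf <- sqrt(eV_J / 1e-20 / u_kg) / (2 * pi * c_cms)
  list(
    cm1_to_eV = 1.239841984e-4,
    eV_to_cm1 = 1 / 1.239841984e-4,
    wavenumber_factor = wf
  )
})
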