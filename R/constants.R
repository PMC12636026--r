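#' Physical constants used throughout the relaxivity model
#'
#' All internal computation is in SI units (s, rad s^-1, m, T); unit
#' conversion happens only at user-facing boundaries (MHz, Angstrom,
#' ns/ps, mM^-1 s^-1).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{mu0_4pi}{magnetic constant over 4 pi, 1e-7 T m A^-1}
#'   \item{gamma_H}{proton gyromagnetic ratio, rad s^-1 T^-1}
#'   \item{mu_B}{Bohr magneton, J T^-1}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{N_A}{Avogadro constant, mol^-1}
#'   \item{water_mM}{molar concentration of pure water, mM (55500)}
#' }
#' @export
physical_constants <- list(
  mu0_4pi  = 1e-7,
  gamma_H  = 2.6752218744e8,
  mu_B     = 9.2740100783e-24,
  hbar     = 1.054571817e-34,
  N_A      = 6.02214076e23,
  water_mM = 55500
)
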