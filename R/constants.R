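#' Physical constants and unit conversions
#'
#' The package works in an \{e, nm, V, ns\} unit system. All conversion
#' factors are derived from CODATA 2018 SI values at load time; nothing is
#' hard-coded beyond the two defining constants.
#'
#' @return A named list:
#' \describe{
#'   \item{e_charge_C}{elementary charge, C.}
#'   \item{eps0_F_per_m}{vacuum permittivity, F/m.}
#'   \item{volt_per_e_per_nm}{the Poisson scale \eqn{e/(\epsilon_0\,\mathrm{nm})}
#'     in volts; multiplying \eqn{-\rho Z^2/\epsilon_r} (with \eqn{\rho} in
#'     e/nm^3 and \eqn{Z} in nm) by this constant yields volts.}
#'   \item{avogadro_per_mol}{Avogadro constant.}
#'   \item{mol_per_L_per_e_per_nm3}{converts a number density in nm^-3 to mol/L.}
#'   \item{pN_per_nm_per_bar_nm}{converts bar x nm to pN/nm (tension formula).}
#' }
#' @examples
#' memvolt_constants()$volt_per_e_per_nm
#' @export
memvolt_constants <- function() {
  e_charge <- 1.602176634e-19      # C (exact, SI 2019)
  eps0 <- 8.8541878128e-12         # F/m (CODATA 2018)
  n_avogadro <- 6.02214076e23      # 1/mol (exact)
  list(
    e_charge_C = e_charge,
    eps0_F_per_m = eps0,
    # e/(eps0 * 1 nm) in volts
    volt_per_e_per_nm = e_charge / (eps0 * 1e-9),
    avogadro_per_mol = n_avogadro,
    # n [1/nm^3] -> mol/L : n / (N_A * 1e-24 L/nm^3)
    mol_per_L_per_e_per_nm3 = 1 / (n_avogadro * 1e-24),
    # 1 bar * 1 nm = 1e5 Pa * 1e-9 m = 1e-4 N/m = 1e-4 * (1e12 pN)/(1e9 nm)
    pN_per_nm_per_bar_nm = 1e5 * 1e-9 * 1e12 / 1e9
  )
}

# internal shortcuts
.kPoissonVolt <- function() memvolt_constants()$volt_per_e_per_nm
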