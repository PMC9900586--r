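# Physical constants (CODATA 2018) and unit conversions.
# Internal dynamical unit: angular frequency in rad/us.  Couplings are input
# in MHz, fields in uT, first-order rate constants in s^-1.

.constants <- list(
  g_e   = 2.00231930436256,   # free-electron g-factor
  mu_B  = 9.2740100783e-24,   # Bohr magneton, J/T
  h     = 6.62607015e-34,     # Planck constant, J s
  hbar  = 1.054571817e-34,    # reduced Planck constant, J s
  mu_0  = 1.25663706212e-6    # vacuum permeability, N/A^2
)

#' Physical constants used by the package
#'
#' Returns the CODATA 2018 values of the free-electron g-factor, Bohr
#' magneton, Planck constant and vacuum permeability that all unit
#' conversions in the package are derived from.
#'
#' @return Named list with elements `g_e`, `mu_B`, `h`, `hbar`, `mu_0`.
#' @export
physical_constants <- function() .constants

#' Electron Larmor frequency
#'
#' Frequency of electron spin precession in a static field,
#' \eqn{\nu = g \mu_B B / h}.  At the Earth-strength field of 49 uT this is
#' about 1.37 MHz, the scale against which hyperfine couplings compete.
#'
#' @param B_uT Field magnitude in microtesla (non-negative).
#' @param g Electron g-value; defaults to the free-electron value.
#' @return Frequency in MHz.
#' @export
larmor_frequency <- function(B_uT, g = .constants$g_e) {
  stopifnot(is.numeric(B_uT), all(B_uT >= 0))
  g * .constants$mu_B * (B_uT * 1e-6) / .constants$h * 1e-6
}

#' Point-dipole coupling from inter-radical distance
#'
#' The electron-electron dipolar coupling parameter for two point dipoles
#' separated by `r_nm`, \eqn{D = -3 \mu_0 g_e^2 \mu_B^2 / (8 \pi h r^3)}.
#' The sign convention makes D negative for the coupled radical pair, as
#' is standard for flavin-tryptophan pairs in cryptochrome.
#'
#' @param r_nm Centre-to-centre separation in nanometres (> 0).
#' @return D in MHz (negative).
#' @seealso [distance_from_dipolar()], [field_equivalent()]
#' @export
dipolar_from_distance <- function(r_nm) {
  stopifnot(is.numeric(r_nm), all(r_nm > 0))
  g <- .constants$g_e
  -3 * .constants$mu_0 * g^2 * .constants$mu_B^2 /
    (8 * pi * .constants$h * (r_nm * 1e-9)^3) * 1e-6
}

#' Inter-radical distance from the point-dipole coupling
#'
#' Closed-form inverse of [dipolar_from_distance()].
#'
#' @param D_MHz Dipolar coupling in MHz (non-zero).
#' @return Separation in nm.
#' @export
distance_from_dipolar <- function(D_MHz) {
  stopifnot(is.numeric(D_MHz), all(D_MHz != 0))
  g <- .constants$g_e
  r3 <- 3 * .constants$mu_0 * g^2 * .constants$mu_B^2 /
    (8 * pi * .constants$h * abs(D_MHz) * 1e6)
  (r3)^(1 / 3) * 1e9
}

#' Magnetic-field equivalent of a coupling
#'
#' Expresses a coupling given in frequency units as the magnetic field whose
#' electron Zeeman interaction has the same magnitude, via division by
#' \eqn{g_e \mu_B / h}.  A dipolar coupling of -11.2 MHz corresponds to about
#' -400 uT, i.e. roughly eight times the geomagnetic field.
#'
#' @param D_MHz Coupling in MHz.
#' @return Equivalent field in uT (sign preserved).
#' @export
field_equivalent <- function(D_MHz) {
  stopifnot(is.numeric(D_MHz))
  D_MHz * 1e6 / (.constants$g_e * .constants$mu_B / .constants$h) * 1e6
}

# MHz -> rad/us
mhz_to_angular <- function(f_MHz) 2 * pi * f_MHz

# s^-1 -> us^-1
rate_per_us <- function(k_s) k_s * 1e-6
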