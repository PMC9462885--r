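#' Physical constants used throughout the package
#'
#' All unit conversions in the package route through this list so that the
#' energy/time convention (energies in micro-eV, times in ps, momentum
#' transfer in inverse Angstrom, temperatures in K) is fixed in one place.
#'
#' @format A named list:
#' \describe{
#'   \item{hbar}{Reduced Planck constant, 658.2119569 micro-eV ps. Converts
#'     an energy transfer \eqn{\Delta E} (micro-eV) to an angular frequency
#'     \eqn{\Delta E/\hbar} (1/ps) in the Fourier pair between
#'     \eqn{S(q,\Delta E)} and \eqn{F(q,t)}.}
#'   \item{kB}{Boltzmann constant, 0.08617333 meV/K. Converts temperatures
#'     to thermal energies in the Arrhenius law, so activation energies come
#'     out in meV.}
#'   \item{coherent_b}{Bound coherent neutron scattering lengths in fm for
#'     H, D, C and O, used to build scattering length densities.}
#'   \item{atomic_mass}{Atomic masses in g/mol for the same elements.}
#' }
#' @export
hydro_constants <- list(
  hbar = 658.2119569,   # micro-eV * ps
  kB   = 0.08617333,    # meV / K
  coherent_b = c(H = -3.739, D = 6.671, C = 6.646, O = 5.803),  # fm
  atomic_mass = c(H = 1.008, D = 2.014, C = 12.011, O = 15.999) # g/mol
)
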