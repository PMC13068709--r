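#' Richardson constant and thermionic-emission current
#'
#' Closed-form thermionic emission over a Schottky barrier,
#' \eqn{J = A^* T^2 e^{-\phi_B/k_BT} (e^{qV/k_BT} - 1)}, with the effective
#' Richardson constant \eqn{A^* = 4\pi q m^* k_B^2 / h^3}. Used as the
#' analytic limit the Tsu-Esaki integral must reproduce when tunneling is
#' negligible.
#'
#' @param m_rel Effective mass in units of the electron rest mass.
#' @param barrier Barrier height, eV.
#' @param bias Voltage across the junction, V (semiconductor relative to
#'   metal; positive = forward injection).
#' @param temperature Kelvin.
#' @return `richardson_constant`: A/(m^2 K^2); `richardson_current`: A/cm^2.
#' @export
richardson_constant <- function(m_rel) {
  4 * pi * .const$q * m_rel * .const$m0 * .const$kB^2 / .const$h^3
}

#' @rdname richardson_constant
#' @export
richardson_current <- function(barrier, bias, m_rel, temperature = 298) {
  vt <- .const$kB * temperature / .const$q
  a_star <- richardson_constant(m_rel)
  a_star * temperature^2 * exp(-barrier / vt) * (exp(bias / vt) - 1) * 1e-4
}

# WKB transmission through a sampled barrier profile for a vector of
# energies. profile_x in m (distance from the contact, increasing),
# profile_e in eV (band edge relative to the metal Fermi level). Returns
# the log-transmission (<= 0) per energy; integration runs over the whole
# sampled window, which is exact for a single-crossing barrier and only
# adds suppression for re-rising profiles.
.wkb_log_transmission <- function(profile_x, profile_e, energies, m_kg) {
  pref <- 2 * sqrt(2 * m_kg * .const$q) / .const$hbar
  # kappa-like integrand, one column per energy
  dE <- outer(profile_e, energies, "-")
  dE[dE < 0] <- 0
  s <- sqrt(dE)
  d <- diff(profile_x)
  w <- c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  -pref * as.numeric(crossprod(s, w))
}

#' Tsu-Esaki injection flux through a Schottky barrier
#'
#' Evaluates the Tsu-Esaki current integral
#' \deqn{J = \frac{4\pi q m^* k_B T}{h^3} \int T(E)\,
#'   \ln\frac{1 + e^{(E_{F,m}-E)/k_BT}}{1 + e^{(E_{F,s}-E)/k_BT}}\, dE}
#' combining the supply-function difference between the metal and
#' semiconductor reservoirs with a transmission probability \eqn{T(E)} that
#' is 1 above the barrier maximum (thermionic emission) and WKB through the
#' sampled barrier profile below it (field emission / tunneling). At zero
#' bias the two supply functions coincide and the net flux vanishes
#' (detailed balance); for a thick barrier the result reduces to the
#' Richardson thermionic closed form.
#'
#' @param profile Barrier profile at the contact: a list/data frame with
#'   `x` (depth from the contact, nm, increasing, >= 8 points) and `energy`
#'   (barrier for the chosen carrier relative to the metal Fermi level, eV).
#' @param bias Voltage across the junction, V: the semiconductor
#'   quasi-Fermi level sits at \eqn{-q \cdot bias} relative to the metal
#'   Fermi level, so positive bias injects carriers from the metal.
#' @param carrier `"e"` or `"h"` (selects the tunneling mass).
#' @param materials A [material_params()].
#' @param n_energy Number of energy quadrature nodes (trapezoidal).
#' @return Net current density, A/cm^2 (positive = metal to semiconductor
#'   carrier flux).
#' @export
tsu_esaki_flux <- function(profile, bias, carrier = c("e", "h"),
                           materials = material_params(), n_energy = 240) {
  carrier <- match.arg(carrier)
  x <- profile$x; en <- profile$energy
  if (length(x) < 8) .fail("barrier profile needs >= 8 sample points")
  if (any(!is.finite(x)) || any(!is.finite(en)))
    .fail("non-finite barrier profile")
  .check_num(bias, "bias")
  vt <- .const$kB * materials$temperature / .const$q
  m_kg <- switch(carrier, e = materials$tunneling_mass_e,
                 h = materials$tunneling_mass_h) * .const$m0
  e_max <- max(en)
  # energy window: from 10 kT below the lower band edge/Fermi region up to
  # 10 kT above the barrier maximum. The quadrature is split at the barrier
  # maximum, where the transmission switches from WKB to 1 and may be
  # discontinuous (flat-top barriers), so neither panel straddles the step.
  e_lo <- min(0, min(en), -bias) - 10 * vt
  e_hi <- e_max + 10 * vt
  sup <- function(ef, energies) {
    z <- (ef - energies) / vt
    ifelse(z > 35, z, log1p(exp(pmin(z, 35))))
  }
  trapz <- function(e, f) sum(diff(e) * (f[-1] + f[-length(f)]) / 2)
  n1 <- max(8L, n_energy %/% 2)
  j_int <- 0
  if (e_max > e_lo) {
    e_below <- seq(e_lo, e_max, length.out = n1 + 1L)[-(n1 + 1L)]
    log_t <- .wkb_log_transmission(x * 1e-9, en, e_below, m_kg)
    f_below <- exp(pmin(log_t, 0)) *
      (sup(0, e_below) - sup(-bias, e_below))
    j_int <- j_int + trapz(e_below, f_below)
  }
  e_above <- seq(e_max, e_hi, length.out = max(8L, n_energy - n1))
  f_above <- sup(0, e_above) - sup(-bias, e_above)
  j_int <- j_int + trapz(e_above, f_above)
  j_si <- 4 * pi * .const$q * m_kg * .const$kB * materials$temperature /
    .const$h^3 * j_int * .const$q
  j_si * 1e-4  # A/m^2 -> A/cm^2
}
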