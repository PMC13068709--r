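#' Electrolyte / measurement condition at the bio-interface
#'
#' Describes the medium above the sensing surface. In `wet` mode the ionic
#' strength sets the Debye screening length; `dry` mode (read-out after
#' rinsing and drying) disables screening entirely.
#'
#' @param ionic_strength Ionic strength, molar. Required in wet mode.
#'   Convenience values: 1x PBS ~ 0.15 M, 0.01x PBS ~ 1.5 mM.
#' @param relative_permittivity Relative permittivity of the medium
#'   (default 78.4, water at 298 K).
#' @param temperature Kelvin.
#' @param mode `"wet"` or `"dry"`.
#' @return An `interface_condition` object.
#' @export
interface_condition <- function(ionic_strength = NULL,
                                relative_permittivity = 78.4,
                                temperature = 298,
                                mode = c("wet", "dry")) {
  mode <- match.arg(mode)
  if (mode == "wet") {
    if (is.null(ionic_strength)) .fail("wet mode requires ionic_strength")
    .check_num(ionic_strength, "ionic_strength", positive = TRUE)
  }
  .check_num(relative_permittivity, "relative_permittivity")
  if (relative_permittivity <= 1) .fail("relative_permittivity must be > 1")
  .check_num(temperature, "temperature", positive = TRUE)
  structure(list(ionic_strength = ionic_strength,
                 relative_permittivity = relative_permittivity,
                 temperature = temperature, mode = mode),
            class = "interface_condition")
}

#' Ionic strength of diluted phosphate-buffered saline
#'
#' @param dilution PBS dilution factor (1 for 1x, 0.01 for 0.01x).
#' @return Ionic strength in molar (0.15 M at 1x).
#' @export
pbs_ionic_strength <- function(dilution = 1) {
  .check_num(dilution, "dilution", positive = TRUE)
  0.15 * dilution
}

#' Debye screening length of an electrolyte
#'
#' \eqn{\lambda_D = \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}}
#' with the ionic strength \eqn{I} converted from molar to ions/m^3.
#' Scales as \eqn{I^{-1/2}}: a 100-fold dilution lengthens \eqn{\lambda_D}
#' tenfold.
#'
#' @param cond A wet-mode [interface_condition()].
#' @return Debye length in nm.
#' @export
debye_length <- function(cond) {
  stopifnot(inherits(cond, "interface_condition"))
  if (cond$mode != "wet")
    .fail("debye_length is only defined in wet mode; ",
          "dry-mode screening is handled by screening_factor")
  i_m3 <- cond$ionic_strength * 1e3 * .const$n_av  # mol/L -> ions/m^3
  lambda <- sqrt(.const$eps0 * cond$relative_permittivity * .const$kB *
                   cond$temperature / (2 * i_m3 * .const$q^2))
  lambda * 1e9
}

#' Electrostatic screening factor at a given height
#'
#' Point-charge-at-centroid reduction of interfacial screening: a charge at
#' height `height` above the surface couples to the channel attenuated by
#' \eqn{\exp(-h/\lambda_D)} in wet mode; in dry mode no electrolyte is
#' present and the factor is 1 at any height.
#'
#' @param height Height of the charge centroid above the substrate, nm
#'   (>= 0); vectorized.
#' @param cond An [interface_condition()].
#' @return Attenuation factor(s) in (0, 1\].
#' @export
screening_factor <- function(height, cond) {
  stopifnot(inherits(cond, "interface_condition"))
  .check_num(height, "height", nonneg = TRUE, len = NULL)
  if (cond$mode == "dry") return(rep(1, length(height)))
  exp(-height / debye_length(cond))
}

#' One conformational state of a surface probe
#'
#' Reduces a probe conformation to the two quantities the device model
#' consumes: its net charge and the height of its charge centroid above the
#' substrate.
#'
#' @param label `"unbound"` or `"bound"`.
#' @param net_charge Net charge in elementary charges (signed).
#' @param height Charge-centroid height above the substrate, nm (>= 0).
#' @return A `probe_state` object.
#' @export
probe_state <- function(label = c("unbound", "bound"), net_charge, height) {
  label <- match.arg(label)
  .check_num(net_charge, "net_charge")
  .check_num(height, "height", nonneg = TRUE)
  structure(list(label = label, net_charge = net_charge, height = height),
            class = "probe_state")
}

#' @export
print.probe_state <- function(x, ...) {
  cat(sprintf("<probe_state:%s> q = %+g e at h = %g nm\n",
              x$label, x$net_charge, x$height))
  invisible(x)
}

#' Immobilized probe layer
#'
#' @param density Probe surface density, molecules per cm^2.
#' @param area Sensing area, nm^2.
#' @param bound_fraction Fraction of probes bound to target, in \[0, 1\].
#' @return A `probe_layer` object.
#' @export
probe_layer <- function(density = 1e12, area = 66000, bound_fraction = 0) {
  .check_num(density, "density", positive = TRUE)
  .check_num(area, "area", positive = TRUE)
  .check_num(bound_fraction, "bound_fraction")
  if (bound_fraction < 0 || bound_fraction > 1)
    .fail("bound_fraction must be in [0, 1]")
  structure(list(density = density, area = area,
                 bound_fraction = bound_fraction),
            class = "probe_layer")
}

#' Number of probe molecules on the sensing area
#'
#' @param layer A [probe_layer()].
#' @return Integer count, `round(density * area)` with nm^2 -> cm^2.
#' @export
molecule_count <- function(layer) {
  stopifnot(inherits(layer, "probe_layer"))
  round(layer$density * layer$area * 1e-14)  # 1 nm^2 = 1e-14 cm^2
}

#' Active sensing area of a gate
#'
#' @param gate_length,gate_width Gate dimensions in nm (> 0).
#' @return Area in nm^2.
#' @export
sensing_area <- function(gate_length, gate_width) {
  .check_num(gate_length, "gate_length", positive = TRUE)
  .check_num(gate_width, "gate_width", positive = TRUE)
  gate_length * gate_width
}

#' Fraction-weighted effective surface charge of a probe layer
#'
#' The sheet charge presented to the program gate when a fraction `f` of
#' probes is bound:
#' \deqn{\sigma = \rho e [f q_b S(h_b) + (1-f) q_u S(h_u)]}
#' where \eqn{\rho} is the probe density, \eqn{S} the height-dependent
#' [screening_factor()], and \eqn{q_u, q_b} the net charges of the unbound
#' and bound states. Affine in `f` by construction.
#'
#' @param layer A [probe_layer()] (its `bound_fraction` is `f`).
#' @param unbound,bound [probe_state()]s with matching labels.
#' @param cond An [interface_condition()].
#' @return Effective sheet charge density in C/cm^2 (signed).
#' @export
effective_surface_charge <- function(layer, unbound, bound, cond) {
  stopifnot(inherits(layer, "probe_layer"),
            inherits(unbound, "probe_state"), inherits(bound, "probe_state"),
            inherits(cond, "interface_condition"))
  if (unbound$label != "unbound" || bound$label != "bound")
    .fail("probe_state labels must be (unbound, bound) in that order")
  f <- layer$bound_fraction
  q_eff <- f * bound$net_charge * screening_factor(bound$height, cond) +
    (1 - f) * unbound$net_charge * screening_factor(unbound$height, cond)
  layer$density * .const$q * q_eff
}

#' @export
print.interface_condition <- function(x, ...) {
  if (x$mode == "wet") {
    cat(sprintf(
      "<interface_condition:wet> I = %.4g M, eps_r = %g, T = %g K (lambda_D = %.3g nm)\n",
      x$ionic_strength, x$relative_permittivity, x$temperature,
      debye_length(x)))
  } else {
    cat("<interface_condition:dry> screening disabled\n")
  }
  invisible(x)
}
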