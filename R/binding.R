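#' Single-site binding model
#'
#' A `binding_model` bundles the dissociation constant \eqn{K_D} and the
#' temperature that define the Langmuir occupancy of a probe layer under the
#' 1:1 binding approximation \eqn{f_a = [T] / (K_D + [T])}.
#'
#' @param kd Dissociation constant, molar. Must be > 0.
#' @param temperature Absolute temperature, kelvin. Defaults to room
#'   temperature, 298 K.
#' @return An object of class `binding_model`.
#' @examples
#' m <- binding_model(kd = 1.47e-9)
#' bound_fraction(1.47e-9, m)  # 0.5 at [T] = KD
#' @export
binding_model <- function(kd, temperature = 298) {
  .check_num(kd, "kd", positive = TRUE)
  .check_num(temperature, "temperature", positive = TRUE)
  structure(list(kd = kd, temperature = temperature),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model> KD = %.4g M (%.3g nM), T = %g K\n",
              x$kd, x$kd * 1e9, x$temperature))
  invisible(x)
}

#' Convert a binding free energy to a dissociation constant
#'
#' Uses \eqn{K_D = \exp(\Delta G / (R T))} with the molar gas constant
#' \eqn{R = 1.9872 \times 10^{-3}} kcal/(mol K). A negative free energy of
#' binding gives \eqn{K_D < 1} M; e.g. an end-point (MM-PBSA style) estimate
#' of -12.05 kcal/mol at 298 K corresponds to about 1.5 nM.
#'
#' @param delta_g Binding free energy, kcal/mol (negative = favourable).
#' @param temperature Kelvin.
#' @return Dissociation constant in molar.
#' @seealso [free_energy_from_kd()] for the inverse.
#' @export
kd_from_free_energy <- function(delta_g, temperature = 298) {
  .check_num(delta_g, "delta_g")
  .check_num(temperature, "temperature", positive = TRUE)
  exp(delta_g / (.const$R_kcal * temperature))
}

#' Convert a dissociation constant to a binding free energy
#'
#' Inverse of [kd_from_free_energy()]: \eqn{\Delta G = R T \ln K_D},
#' kcal/mol.
#'
#' @param kd Dissociation constant, molar (> 0).
#' @param temperature Kelvin.
#' @return Free energy in kcal/mol.
#' @export
free_energy_from_kd <- function(kd, temperature = 298) {
  .check_num(kd, "kd", positive = TRUE)
  .check_num(temperature, "temperature", positive = TRUE)
  .const$R_kcal * temperature * log(kd)
}

#' Langmuir bound fraction
#'
#' Fraction of surface probes occupied at equilibrium for free target
#' concentration `concentration`: \eqn{f_a = [T] / (K_D + [T])}. Computed in
#' this ratio form so that `bound_fraction(kd, model)` is 0.5 exactly in
#' floating point.
#'
#' @param concentration Free target concentration, molar (>= 0); vectorized.
#' @param model A [binding_model()].
#' @return Bound fraction(s) in \[0, 1\].
#' @export
bound_fraction <- function(concentration, model) {
  stopifnot(inherits(model, "binding_model"))
  .check_num(concentration, "concentration", nonneg = TRUE, len = NULL)
  concentration / (model$kd + concentration)
}

#' Langmuir binding curve over a concentration grid
#'
#' @param concentrations Non-empty, strictly increasing, non-negative molar
#'   concentrations.
#' @param model A [binding_model()].
#' @return A `binding_curve`: data frame with columns `concentration_M` and
#'   `bound_fraction`, carrying the generating `kd` as an attribute.
#' @export
binding_curve <- function(concentrations, model) {
  stopifnot(inherits(model, "binding_model"))
  .check_num(concentrations, "concentrations", nonneg = TRUE, len = NULL)
  if (length(concentrations) == 0) .fail("concentrations must be non-empty")
  if (is.unsorted(concentrations, strictly = TRUE))
    .fail("concentrations must be strictly increasing")
  out <- data.frame(concentration_M = concentrations,
                    bound_fraction = bound_fraction(concentrations, model))
  structure(out, kd = model$kd, class = c("binding_curve", "data.frame"))
}

#' Read a dissociation constant off a binding curve
#'
#' Finds the concentration at which the curve crosses \eqn{f_a = 0.5} — the
#' defining property of \eqn{K_D} — by linear interpolation in
#' (log10 concentration, fraction) space, where a Langmuir isotherm is
#' nearly linear around the half-occupancy point.
#'
#' @param curve A `binding_curve` or data frame with columns
#'   `concentration_M` and `bound_fraction` bracketing 0.5.
#' @return Estimated `kd` in molar.
#' @export
kd_from_binding_curve <- function(curve) {
  conc <- curve$concentration_M
  f <- curve$bound_fraction
  if (is.null(conc) || is.null(f))
    .fail("curve needs columns concentration_M and bound_fraction")
  if (min(f) >= 0.5 || max(f) <= 0.5)
    .fail("curve does not bracket f = 0.5; cannot read off KD")
  i <- which(f >= 0.5)[1]  # f is non-decreasing for a Langmuir curve
  if (f[i] == 0.5) return(conc[i])
  lo <- i - 1L
  w <- (0.5 - f[lo]) / (f[i] - f[lo])
  10^((1 - w) * log10(conc[lo]) + w * log10(conc[i]))
}

#' Write / read a binding curve as CSV
#'
#' Two-column CSV (`concentration_M`, `bound_fraction`) preceded by a
#' `# kd_M=<value>` comment line recording the generating dissociation
#' constant.
#'
#' @param curve A `binding_curve`.
#' @param path File path.
#' @return `path`, invisibly (writer); a `binding_curve` (reader).
#' @export
write_binding_curve <- function(curve, path) {
  kd <- attr(curve, "kd")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(kd)) writeLines(sprintf("# kd_M=%.17g", kd), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_curve
#' @export
read_binding_curve <- function(path) {
  first <- readLines(path, n = 1L)
  kd <- if (startsWith(first, "# kd_M=")) {
    as.numeric(sub("# kd_M=", "", first, fixed = TRUE))
  } else NULL
  out <- utils::read.csv(path, comment.char = "#")
  structure(out, kd = kd, class = c("binding_curve", "data.frame"))
}
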