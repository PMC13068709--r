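#' Response curve container
#'
#' Pairs a sweep variable (control-gate voltage, bound fraction, or target
#' concentration) with the simulated drain current, plus run metadata.
#'
#' @param x Sweep values (sorted).
#' @param x_kind `"v_cg"`, `"fraction"`, or `"concentration"`.
#' @param current Drain currents, A (same length as `x`).
#' @param metadata Named list (bias point, fixture id, interface
#'   condition, ...).
#' @return A `response_curve` data frame with columns `x` and `current`.
#' @export
response_curve <- function(x, x_kind = c("v_cg", "fraction", "concentration"),
                           current, metadata = list()) {
  x_kind <- match.arg(x_kind)
  if (length(x) != length(current))
    .fail("x and current must have the same length")
  if (is.unsorted(x)) .fail("x must be sorted")
  structure(data.frame(x = x, current = current),
            x_kind = x_kind, metadata = metadata,
            class = c("response_curve", "data.frame"))
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %d points over %s in [%g, %g]\n",
              nrow(x), attr(x, "x_kind"), min(x$x), max(x$x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Drain current as a function of the bound-probe fraction
#'
#' For each bound fraction `f`, forms the fraction-weighted, Debye-screened
#' effective sheet charge of the probe layer and solves the device at the
#' ON read-out point of the programming template (|v_cg| = 5 V,
#' |v_ds| = 0.1 V by default). The program gate is biased by the molecular
#' charge itself (`v_pg = 0`, the "virtual doping" read-out, so the drain
#' junction — and hence the current — is programmed by the probe layer);
#' set `v_pg` to superpose an electrical program bias. Consecutive
#' fractions reuse the previous solution as a warm start.
#'
#' @param device An `rfet_device`.
#' @param template A [program_polarity()] template (or any list with a
#'   `bias` [bias_point()]).
#' @param fixture A [make_fixture()] case supplying the probe states.
#' @param cond An [interface_condition()]; default 0.01x PBS, the
#'   low-ionic-strength regime in which height-dependent screening (the
#'   aptamer signal mechanism) is active.
#' @param fractions Sorted bound fractions in \[0, 1\].
#' @param layer Optional [probe_layer()]; defaults to 1e12 molecules/cm^2
#'   on the program-gate sensing area of `device`.
#' @param v_pg Electrical program-gate bias superposed on the molecular
#'   charge, V (default 0: the charge input alone programs the junction).
#' @param control A [solver_control()].
#' @return A `response_curve` over fractions.
#' @export
current_vs_fraction <- function(device, template, fixture,
                                cond = interface_condition(
                                  ionic_strength = pbs_ionic_strength(0.01)),
                                fractions = seq(0, 1, 0.1),
                                layer = NULL, v_pg = 0,
                                control = solver_control()) {
  stopifnot(inherits(device, "rfet_device"), inherits(fixture, "fixture_case"))
  if (length(fractions) == 0) .fail("empty fraction grid")
  if (is.unsorted(fractions)) .fail("fractions must be sorted")
  if (any(fractions < 0 | fractions > 1)) .fail("fractions must be in [0, 1]")
  if (is.null(layer))
    layer <- probe_layer(density = 1e12,
                         area = sensing_area(device$spec$gate_length_pg,
                                             device$spec$width))
  bias0 <- template$bias
  currents <- numeric(length(fractions))
  state <- NULL
  for (i in seq_along(fractions)) {
    layer$bound_fraction <- fractions[i]
    sig <- effective_surface_charge(layer, fixture$unbound, fixture$bound,
                                    cond)
    b <- bias_point(v_pg = v_pg, v_cg = bias0$v_cg,
                    v_ds = bias0$v_ds, sigma_pg = sig)
    state <- solve_bias_point(device, b, control, init = state)
    currents[i] <- state$current_drain
  }
  response_curve(x = fractions, x_kind = "fraction", current = currents,
                 metadata = list(fixture = fixture$case_id,
                                 v_pg = v_pg, v_cg = bias0$v_cg,
                                 v_ds = bias0$v_ds,
                                 interface_mode = cond$mode,
                                 ionic_strength = cond$ionic_strength,
                                 layer_density = layer$density,
                                 layer_area = layer$area))
}

#' Calibration curve: drain current vs target concentration
#'
#' Composes a current-vs-fraction curve with the Langmuir isotherm:
#' each concentration maps to its bound fraction, and the current is read
#' off the fraction curve by monotone piecewise-cubic interpolation. Exact
#' at fraction-grid points.
#'
#' @param curve_f A `response_curve` over fractions covering \[0, 1\]
#'   with at least 11 points.
#' @param model A [binding_model()] (or a [make_fixture()] case, whose KD
#'   is used).
#' @param concentrations Molar concentrations (sorted, >= 0).
#' @return A `response_curve` over concentrations.
#' @export
calibration_curve <- function(curve_f, model, concentrations) {
  stopifnot(inherits(curve_f, "response_curve"))
  if (attr(curve_f, "x_kind") != "fraction")
    .fail("curve_f must be a fraction-sweep response curve")
  if (nrow(curve_f) < 11)
    .fail("curve_f needs >= 11 fraction points for interpolation")
  if (inherits(model, "fixture_case")) model <- binding_model(model$kd)
  stopifnot(inherits(model, "binding_model"))
  .check_num(concentrations, "concentrations", nonneg = TRUE, len = NULL)
  if (is.unsorted(concentrations)) .fail("concentrations must be sorted")
  f <- bound_fraction(concentrations, model)
  if (any(f < min(curve_f$x) - 1e-12) || any(f > max(curve_f$x) + 1e-12))
    .fail("concentration maps to a bound fraction outside the covered range")
  interp <- stats::splinefun(curve_f$x, curve_f$current, method = "hyman")
  md <- attr(curve_f, "metadata")
  md$kd_M <- model$kd
  response_curve(x = concentrations, x_kind = "concentration",
                 current = interp(f), metadata = md)
}

#' Relative current response summary
#'
#' Computes \eqn{\Delta I / I_0} per concentration with \eqn{I_0} the
#' zero-target current, the maximum relative response, the response sign
#' (suppression if |I| decreases with concentration, enhancement if it
#' increases; decided on magnitudes so the negative currents of p-type
#' operation are handled), and the concentration at which |dI/I0| crosses
#' half its maximum (interpolated in log-concentration).
#'
#' @param curve_c A concentration-sweep `response_curve` including c = 0.
#' @return A `response_summary` list: `i0`, `max_relative_response`,
#'   `response_sign`, `half_response_concentration`, and the per-point
#'   `delta_i_over_i0` table.
#' @export
relative_response <- function(curve_c) {
  stopifnot(inherits(curve_c, "response_curve"))
  if (attr(curve_c, "x_kind") != "concentration")
    .fail("relative_response needs a concentration-sweep curve")
  if (curve_c$x[1] != 0 || nrow(curve_c) < 2)
    .fail("curve must include c = 0 (baseline) and at least one c > 0")
  i0 <- curve_c$current[1]
  if (abs(i0) < 1e-18)
    .fail("degenerate baseline: |I0| below 1e-18 A")
  rel <- (curve_c$current - i0) / i0
  max_rel <- max(abs(rel))
  sign_lab <- if (abs(curve_c$current[nrow(curve_c)]) < abs(i0))
    "suppression" else "enhancement"
  # half-response crossing, log-interpolated over c > 0
  cpos <- curve_c$x[-1]; rpos <- abs(rel[-1])
  half <- max_rel / 2
  half_c <- NA_real_
  if (max_rel > 0) {
    ix <- which(rpos >= half)[1]
    if (ix == 1) {
      half_c <- cpos[1]
    } else {
      w <- (half - rpos[ix - 1]) / (rpos[ix] - rpos[ix - 1])
      half_c <- 10^((1 - w) * log10(cpos[ix - 1]) + w * log10(cpos[ix]))
    }
  }
  structure(list(i0 = i0, max_relative_response = max_rel,
                 response_sign = sign_lab,
                 half_response_concentration = half_c,
                 table = data.frame(concentration_M = curve_c$x,
                                    i_d_A = curve_c$current,
                                    delta_i_over_i0 = rel)),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf(
    "<response_summary> I0 = %.4g A; max |dI/I0| = %.3g (%s); half-response at %.3g nM\n",
    x$i0, x$max_relative_response, x$response_sign,
    x$half_response_concentration * 1e9))
  invisible(x)
}

#' Recover the dissociation constant from a calibration curve
#'
#' Inverts the (monotone) current-vs-fraction map to recover the bound
#' fraction behind each calibration-curve current, then fits the Langmuir
#' isotherm \eqn{f = c / (K_D + c)} by least squares in \eqn{\log K_D}.
#' On noiseless synthetic curves this is a round-trip of the forward
#' pipeline.
#'
#' @param curve_c Concentration-sweep `response_curve`.
#' @param curve_f Fraction-sweep `response_curve` (strictly monotone
#'   current).
#' @return Estimated KD, molar.
#' @export
invert_response_for_kd <- function(curve_c, curve_f) {
  stopifnot(inherits(curve_c, "response_curve"),
            inherits(curve_f, "response_curve"))
  cur <- curve_f$current
  if (all(diff(cur) > 0)) {
    inv <- stats::splinefun(cur, curve_f$x, method = "hyman")
  } else if (all(diff(cur) < 0)) {
    inv <- stats::splinefun(rev(cur), rev(curve_f$x), method = "hyman")
  } else {
    .fail("current_vs_fraction curve is not strictly monotone; cannot invert")
  }
  keep <- curve_c$x > 0
  conc <- curve_c$x[keep]
  f <- pmin(pmax(inv(pmin(pmax(curve_c$current[keep], min(cur)),
                          max(cur))), 0), 1)
  obj <- function(log_kd) sum((f - conc / (exp(log_kd) + conc))^2)
  fit <- stats::optimize(obj, interval = log(c(min(conc) / 1e3,
                                               max(conc) * 1e3)))
  exp(fit$minimum)
}

#' Write a response curve as CSV
#'
#' Concentration curves gain a `delta_i_over_i0` column when a baseline
#' point (c = 0) is present. A metadata header of `# key=value` lines
#' records the bias point and interface condition.
#'
#' @param curve A `response_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_curve <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  md <- attr(curve, "metadata")
  kind <- attr(curve, "x_kind")
  df <- as.data.frame(curve)
  names(df)[1] <- switch(kind, v_cg = "v_cg_V", fraction = "bound_fraction",
                         concentration = "concentration_M")
  names(df)[2] <- "i_d_A"
  if (kind == "concentration" && df[[1]][1] == 0 && abs(df$i_d_A[1]) > 0)
    df$delta_i_over_i0 <- (df$i_d_A - df$i_d_A[1]) / df$i_d_A[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(md)) {
    v <- md[[k]]
    if (is.null(v)) v <- "NA"
    writeLines(sprintf("# %s=%s", k, paste(format(v), collapse = ",")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Plot a response or calibration curve
#'
#' Convenience ggplot2 wrappers (transfer curve, current vs fraction, and
#' calibration / relative-response panels). Requires ggplot2.
#'
#' @param curve A `response_curve`.
#' @return A ggplot object.
#' @export
plot_response_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    .fail("plot_response_curve requires ggplot2")
  kind <- attr(curve, "x_kind")
  df <- data.frame(sweep = curve$x, abs_current = abs(curve$current))
  if (kind == "concentration") df <- df[df$sweep > 0, ]
  xlab <- switch(kind, v_cg = "V_CG (V)", fraction = "bound fraction",
                 concentration = "target concentration (M)")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = sweep, y = abs_current)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "|I_D| (A)") +
    ggplot2::theme_minimal()
  if (kind == "concentration")
    p <- p + ggplot2::scale_x_log10()
  p
}

utils::globalVariables(c("sweep", "abs_current"))
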