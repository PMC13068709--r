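#' Geometry and configuration of the dual-gate Schottky-barrier RFET
#'
#' Describes the simulated structure: a doping-free ultra-thin silicon
#' channel contacted by Schottky source/drain, with a control gate (CG)
#' abutting the source and a program gate (PG) abutting the drain
#' (program-gate-at-drain, PGAD). The third dimension (gate width) enters
#' the model as a multiplier on current.
#'
#' The mesh is a tensor grid: `mesh_nx` columns along the channel with
#' two-sided tanh clustering toward the Schottky contacts (to resolve
#' nm-scale tunneling barriers) and `mesh_ny` uniform rows through the
#' silicon film. The gate oxide is not meshed; it enters through its
#' capacitance per area (set by `eot`) as a mixed boundary condition on the
#' top surface.
#'
#' @param channel_length Channel length, nm.
#' @param gate_length_pg,gate_length_cg Program/control gate lengths, nm.
#' @param width Gate width, nm (multiplies current).
#' @param si_thickness Silicon film thickness, nm.
#' @param eot Equivalent oxide thickness of the gate stack, nm.
#' @param schottky_barrier_e,schottky_barrier_h Electron/hole Schottky
#'   barrier heights, eV (defaults: symmetric mid-gap, 0.56 eV).
#' @param pg_position Only `"drain_side"` (PGAD) is supported.
#' @param mesh_nx,mesh_ny Mesh node counts along and across the channel.
#' @param mesh_beta Contact-clustering strength of the tanh-stretched
#'   x-grid (larger = finer at the contacts).
#' @param density_gradient Logical; apply a first-order density-gradient
#'   quantum correction after the classical solve (default off).
#' @return A `device_spec` object.
#' @export
device_spec <- function(channel_length = 1000,
                        gate_length_pg = 440, gate_length_cg = 440,
                        width = 150, si_thickness = 10, eot = 1,
                        schottky_barrier_e = 0.56,
                        schottky_barrier_h = 0.56,
                        pg_position = "drain_side",
                        mesh_nx = 161, mesh_ny = 11,
                        mesh_beta = 2.2,
                        density_gradient = FALSE) {
  for (nm in c("channel_length", "gate_length_pg", "gate_length_cg",
               "width", "si_thickness", "eot"))
    .check_num(get(nm), nm, positive = TRUE)
  if (gate_length_pg + gate_length_cg > channel_length)
    .fail("gate lengths exceed channel length")
  pg_position <- match.arg(pg_position, "drain_side")
  structure(as.list(environment()), class = "device_spec")
}

#' Semiconductor and contact material parameters
#'
#' Silicon defaults at room temperature. Density-of-states effective masses
#' set the band effective densities of states (and the Richardson constants
#' of the Schottky contacts); the lighter tunneling masses control WKB
#' transmission through the contact barriers. Optional uniform doping is
#' provided for validation structures (MOS capacitors); the RFET channel
#' itself is doping-free.
#'
#' @param bandgap Bandgap, eV.
#' @param electron_mobility,hole_mobility Mobilities, cm^2/(V s).
#' @param effective_mass_e,effective_mass_h Density-of-states effective
#'   masses, units of the electron rest mass.
#' @param tunneling_mass_e,tunneling_mass_h Tunneling effective masses.
#' @param relative_permittivity_si,relative_permittivity_ox Dielectric
#'   constants of the silicon film and the gate oxide (the oxide value is
#'   used to convert `eot` to a capacitance).
#' @param temperature Kelvin.
#' @param acceptor_density,donor_density Uniform doping, cm^-3 (default 0).
#' @return A `material_params` object.
#' @export
material_params <- function(bandgap = 1.12,
                            electron_mobility = 1400, hole_mobility = 450,
                            effective_mass_e = 1.08, effective_mass_h = 0.81,
                            tunneling_mass_e = 0.19, tunneling_mass_h = 0.16,
                            relative_permittivity_si = 11.7,
                            relative_permittivity_ox = 3.9,
                            temperature = 298,
                            acceptor_density = 0, donor_density = 0) {
  for (nm in c("bandgap", "electron_mobility", "hole_mobility",
               "effective_mass_e", "effective_mass_h", "tunneling_mass_e",
               "tunneling_mass_h", "relative_permittivity_si",
               "relative_permittivity_ox", "temperature"))
    .check_num(get(nm), nm, positive = TRUE)
  .check_num(acceptor_density, "acceptor_density", nonneg = TRUE)
  .check_num(donor_density, "donor_density", nonneg = TRUE)
  structure(as.list(environment()), class = "material_params")
}

#' Bias configuration of one operating point
#'
#' @param v_pg,v_cg Program/control gate voltages, V.
#' @param v_ds Drain-source voltage, V (source grounded).
#' @param sigma_pg Molecular sheet charge applied on the sensing surface
#'   over the program-gate footprint, C/cm^2 (signed).
#' @return A `bias_point` object.
#' @export
bias_point <- function(v_pg = 0, v_cg = 0, v_ds = 0, sigma_pg = 0) {
  for (nm in c("v_pg", "v_cg", "v_ds", "sigma_pg"))
    .check_num(get(nm), nm)
  structure(list(v_pg = v_pg, v_cg = v_cg, v_ds = v_ds,
                 sigma_pg = sigma_pg), class = "bias_point")
}

#' Standard programming templates for the two polarities
#'
#' n-type programming biases the program gate positively and sweeps the
#' control gate from 0 to +5 V at v_ds = +0.1 V; p-type is the exact sign
#' mirror (both gates negative, v_cg swept from -5 to 0 V at v_ds =
#' -0.1 V). All values are starting points and can be overridden.
#'
#' @param sign `"n"` or `"p"`.
#' @return A list with `bias` (a [bias_point()] at the ON read-out:
#'   |v_cg| = 5 V, |v_ds| = 0.1 V) and `v_cg_sweep` (the transfer-curve
#'   grid endpoints).
#' @export
program_polarity <- function(sign = c("n", "p")) {
  sign <- match.arg(sign)
  s <- if (sign == "n") 1 else -1
  list(sign = sign,
       bias = bias_point(v_pg = 5 * s, v_cg = 5 * s, v_ds = 0.1 * s),
       v_cg_sweep = sort(c(0, 5 * s)))
}

# Two-sided tanh-stretched coordinates on [0, L]: clusters nodes at both
# ends (the Schottky contacts) where tunneling barriers need sub-nm
# resolution.
.stretched_grid <- function(L, n, beta) {
  xi <- seq(0, 1, length.out = n)
  x <- L / 2 * (1 + tanh(beta * (2 * xi - 1)) / tanh(beta))
  x[1] <- 0; x[n] <- L
  x
}

#' Discretize an RFET device
#'
#' Builds the finite-volume tensor mesh, maps the gate electrodes to
#' x-intervals (CG abutting the source at x = 0, PG abutting the drain at
#' x = L, any residual spacer ungated between them), precomputes
#' temperature-dependent semiconductor quantities (thermal voltage,
#' effective densities of states, intrinsic density, Richardson
#' velocities), and assembles the bias-independent part of the Poisson
#' operator.
#'
#' @param spec A [device_spec()].
#' @param materials A [material_params()].
#' @return An `rfet_device` object consumed by the solvers.
#' @export
build_device <- function(spec = device_spec(), materials = material_params()) {
  stopifnot(inherits(spec, "device_spec"), inherits(materials, "material_params"))
  cst <- .const
  nx <- spec$mesh_nx; ny <- spec$mesh_ny
  if (nx < 10 || ny < 3) .fail("mesh too coarse: need mesh_nx >= 10, mesh_ny >= 3")
  L <- spec$channel_length * 1e-9
  t_si <- spec$si_thickness * 1e-9
  xs <- .stretched_grid(L, nx, spec$mesh_beta)
  ys <- seq(0, t_si, length.out = ny)           # y = 0 is the gated surface
  dxc <- diff(xs); dyc <- diff(ys)
  # control-volume extents per node (half cells at boundaries)
  wx <- c(dxc[1] / 2, (dxc[-1] + dxc[-(nx - 1)]) / 2, dxc[nx - 1] / 2)
  wy <- c(dyc[1] / 2, (dyc[-1] + dyc[-(ny - 1)]) / 2, dyc[ny - 1] / 2)

  # gate footprint per column: 1 = CG (source side), 2 = PG (drain side)
  x_nm <- xs * 1e9
  gate_id <- integer(nx)
  gate_id[x_nm <= spec$gate_length_cg + 1e-9] <- 1L
  gate_id[x_nm >= spec$channel_length - spec$gate_length_pg - 1e-9] <- 2L
  if (sum(gate_id == 1L) < 4 || sum(gate_id == 2L) < 4)
    .fail("mesh too coarse to resolve a gate (fewer than 4 columns under it)")

  T <- materials$temperature
  vt <- cst$kB * T / cst$q
  nc <- 2 * (2 * pi * materials$effective_mass_e * cst$m0 * cst$kB * T / cst$h^2)^1.5
  nv <- 2 * (2 * pi * materials$effective_mass_h * cst$m0 * cst$kB * T / cst$h^2)^1.5
  ni <- sqrt(nc * nv) * exp(-materials$bandgap / (2 * vt))
  # Richardson constants and the equivalent surface-recombination velocities
  a_rich_e <- 4 * pi * cst$q * materials$effective_mass_e * cst$m0 * cst$kB^2 / cst$h^3
  a_rich_h <- 4 * pi * cst$q * materials$effective_mass_h * cst$m0 * cst$kB^2 / cst$h^3
  v_rich_e <- a_rich_e * T^2 / (cst$q * nc)
  v_rich_h <- a_rich_h * T^2 / (cst$q * nv)
  n_b <- nc * exp(-spec$schottky_barrier_e / vt)  # contact equilibrium densities
  p_b <- nv * exp(-spec$schottky_barrier_h / vt)
  c_ox <- cst$eps0 * materials$relative_permittivity_ox / (spec$eot * 1e-9)  # F/m^2
  eps_si <- cst$eps0 * materials$relative_permittivity_si
  # net fixed doping (m^-3), uniform; zero for the doping-free RFET channel
  doping <- (materials$donor_density - materials$acceptor_density) * 1e6
  # contact potentials at zero applied bias (barrier-pinned, midgap metal ref.)
  psi_contact0 <- vt * log(nc / ni) - spec$schottky_barrier_e / 1  # in V

  dev <- list(spec = spec, materials = materials,
              nx = nx, ny = ny, xs = xs, ys = ys, wx = wx, wy = wy,
              gate_id = gate_id, vt = vt, nc = nc, nv = nv, ni = ni,
              v_rich_e = v_rich_e, v_rich_h = v_rich_h,
              n_b = n_b, p_b = p_b, c_ox = c_ox, eps_si = eps_si,
              doping = doping, psi_contact0 = psi_contact0,
              width = spec$width * 1e-9,
              mu_n = materials$electron_mobility * 1e-4,
              mu_p = materials$hole_mobility * 1e-4)
  dev <- c(dev, .poisson_structure(dev))
  class(dev) <- "rfet_device"
  dev
}

#' @export
print.rfet_device <- function(x, ...) {
  cat(sprintf(
    "<rfet_device> L = %g nm (CG %g / spacer %g / PG %g), W = %g nm, t_si = %g nm, EOT = %g nm\n",
    x$spec$channel_length, x$spec$gate_length_cg,
    x$spec$channel_length - x$spec$gate_length_cg - x$spec$gate_length_pg,
    x$spec$gate_length_pg, x$spec$width, x$spec$si_thickness, x$spec$eot))
  cat(sprintf("  mesh %d x %d, phi_Bn = %g eV, phi_Bp = %g eV, ni = %.3g cm^-3\n",
              x$nx, x$ny, x$spec$schottky_barrier_e, x$spec$schottky_barrier_h,
              x$ni * 1e-6))
  invisible(x)
}

#' Gate-voltage equivalent of a molecular sheet charge
#'
#' Reports the first-order threshold shift a sheet charge on the sensing
#' surface produces through the gate-stack capacitance,
#' \eqn{\Delta V = \sigma / C_{ox}}.
#'
#' @param sigma_pg Sheet charge, C/cm^2.
#' @param device An `rfet_device` (or [device_spec()]/[material_params()]
#'   pair via `build_device`).
#' @return Equivalent gate-voltage shift, V.
#' @export
sigma_to_voltage_shift <- function(sigma_pg, device) {
  stopifnot(inherits(device, "rfet_device"))
  sigma_pg * 1e4 / device$c_ox
}
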