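# Run configuration: one YAML file drives a whole study. Sections mirror
# the package's constructors; unknown keys are rejected so typos fail fast.

.config_schema <- list(
  binding = c("kd_M", "delta_g_kcal_mol", "temperature_K"),
  interface = c("ionic_strength_M", "pbs_dilution", "relative_permittivity",
                "temperature_K", "mode"),
  layer = c("density_cm2", "area_nm2"),
  fixture = c("case_id", "overrides", "pqr_unbound", "pqr_bound",
              "substrate_z_nm"),
  device = c("channel_length", "gate_length_pg", "gate_length_cg", "width",
             "si_thickness", "eot", "schottky_barrier_e",
             "schottky_barrier_h", "mesh_nx", "mesh_ny", "mesh_beta",
             "density_gradient"),
  materials = c("bandgap", "electron_mobility", "hole_mobility",
                "effective_mass_e", "effective_mass_h", "tunneling_mass_e",
                "tunneling_mass_h", "relative_permittivity_si",
                "relative_permittivity_ox", "temperature",
                "acceptor_density", "donor_density"),
  protocol = c("polarity", "v_pg", "v_cg", "v_ds", "v_cg_sweep_n",
               "fractions_n", "concentrations_nM", "conc_points_per_decade"),
  run = c("output_dir", "seed", "verbosity"))

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `binding`, `interface`,
#' `layer`, `fixture`, `device`, `materials`, `protocol`, and `run`;
#' fills defaults for anything omitted and rejects unknown sections or
#' keys. Any referenced files (PQR probe profiles) must exist at load
#' time.
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .fail("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.config_schema))
  if (length(unknown))
    .fail("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(bad))
      .fail("unknown key(s) in section '", sec, "': ",
            paste(bad, collapse = ", "))
  }
  cfg <- rapply(raw, function(x) {
    # R's YAML reader leaves plain-notation scientific numbers ("1e12",
    # "1.47e-9") as strings; coerce anything number-shaped
    if (is.character(x) && length(x) == 1 &&
        grepl("^[+-]?([0-9]*\\.)?[0-9]+([eE][+-]?[0-9]+)?$", x))
      as.numeric(x) else x
  }, how = "replace")
  # defaults
  cfg$run$output_dir <- cfg$run$output_dir %||% "rfetsense-out"
  cfg$run$seed <- cfg$run$seed %||% 1L
  cfg$run$verbosity <- cfg$run$verbosity %||% "info"
  cfg$fixture$case_id <- cfg$fixture$case_id %||% "aptamer_cea"
  for (f in c("pqr_unbound", "pqr_bound")) {
    if (!is.null(cfg$fixture[[f]]) && !file.exists(cfg$fixture[[f]]))
      .fail("referenced file does not exist: ", cfg$fixture[[f]])
  }
  # validate by constructing the domain objects (their invariants apply)
  invisible(config_materials(cfg))
  invisible(config_device_spec(cfg))
  invisible(config_interface(cfg))
  invisible(config_layer(cfg))
  structure(cfg, path = path, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize configured domain objects
#'
#' Helpers translating `run_config` sections into the package's
#' constructors (defaults apply for omitted keys).
#'
#' @param cfg A `run_config` from [load_config()].
#' @return The corresponding domain object.
#' @export
config_device_spec <- function(cfg) {
  do.call(device_spec, cfg$device %||% list())
}

#' @rdname config_device_spec
#' @export
config_materials <- function(cfg) {
  do.call(material_params, cfg$materials %||% list())
}

#' @rdname config_device_spec
#' @export
config_interface <- function(cfg) {
  s <- cfg$interface %||% list()
  mode <- s$mode %||% "wet"
  i <- s$ionic_strength_M %||%
    pbs_ionic_strength(s$pbs_dilution %||% 0.01)
  interface_condition(ionic_strength = if (mode == "wet") i else NULL,
                      relative_permittivity = s$relative_permittivity %||% 78.4,
                      temperature = s$temperature_K %||% 298,
                      mode = mode)
}

#' @rdname config_device_spec
#' @export
config_layer <- function(cfg) {
  s <- cfg$layer %||% list()
  probe_layer(density = s$density_cm2 %||% 1e12,
              area = s$area_nm2 %||% 66000)
}

#' @rdname config_device_spec
#' @export
config_fixture <- function(cfg) {
  s <- cfg$fixture %||% list()
  if (!is.null(s$pqr_unbound) && !is.null(s$pqr_bound)) {
    z0 <- s$substrate_z_nm %||% 0
    fx <- make_fixture(s$case_id)
    fx$unbound <- probe_state_from_atoms(read_pqr(s$pqr_unbound), z0,
                                         "unbound")
    fx$bound <- probe_state_from_atoms(read_pqr(s$pqr_bound), z0, "bound")
    return(fx)
  }
  make_fixture(s$case_id %||% "aptamer_cea",
               overrides = s$overrides %||% list(),
               seed = cfg$run$seed)
}

#' @rdname config_device_spec
#' @export
config_binding_model <- function(cfg) {
  s <- cfg$binding %||% list()
  temp <- s$temperature_K %||% 298
  kd <- if (!is.null(s$kd_M)) s$kd_M
  else if (!is.null(s$delta_g_kcal_mol))
    kd_from_free_energy(s$delta_g_kcal_mol, temp)
  else config_fixture(cfg)$kd
  binding_model(kd, temp)
}

#' Serialize a run configuration back to YAML
#'
#' `dump_config(load_config(x))` loads back equal to `load_config(x)`.
#'
#' @param cfg A `run_config`.
#' @param path Output path (`NULL` returns the YAML text).
#' @return YAML text, invisibly when written.
#' @export
dump_config <- function(cfg, path = NULL) {
  txt <- yaml::as.yaml(unclass(cfg))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
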