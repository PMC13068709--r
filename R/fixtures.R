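#' Built-in probe fixtures for the two reference case studies
#'
#' Generates the parameter sets the package ships for its two reference
#' sensing systems, emulating what molecular simulation / crystallography
#' pipelines would supply:
#'
#' * `aptamer_cea`: a 40-nt DNA anti-CEA aptamer (39 phosphodiester
#'   linkages, net charge -39 e) that elongates on target binding, raising
#'   its charge centroid from 7.15 nm to 9.13 nm; CEA itself adds a small
#'   negative charge (default -2 e). KD = 1.47 nM.
#' * `protease_inhibitor`: a surface-tethered HIV-1 protease homodimer
#'   whose net positive charge grows on inhibitor binding (defaults
#'   +4 e -> +6 e at 2.0 nm; the literature gives only the sign and
#'   ordering, so both values are parameters, not asserted constants).
#'   KD = 0.31 nM.
#'
#' `overrides` replaces any default field; `jitter` (an override, default 0)
#' applies seeded Gaussian perturbation of that relative magnitude to
#' heights and charges for ensemble runs.
#'
#' @param case_id `"aptamer_cea"` or `"protease_inhibitor"`.
#' @param overrides Named list overriding `q_unbound`, `q_bound`,
#'   `h_unbound`, `h_bound`, `kd`, `q_target` (aptamer target charge, e),
#'   or `jitter`.
#' @param seed Integer seed for the jitter RNG (ignored when jitter = 0).
#' @return A `fixture_case`: list with `case_id`, `unbound` and `bound`
#'   [probe_state()]s, `kd` (molar), `polarity` (`"p"` or `"n"` programming
#'   the case calls for), and `seed`.
#' @export
make_fixture <- function(case_id = c("aptamer_cea", "protease_inhibitor"),
                         overrides = list(), seed = NULL) {
  case_id <- match.arg(case_id)
  defaults <- switch(case_id,
    aptamer_cea = list(q_unbound = -39, q_target = -2,
                       h_unbound = 7.15, h_bound = 9.13,
                       kd = 1.47e-9, polarity = "p", jitter = 0),
    protease_inhibitor = list(q_unbound = 4, q_bound = 6,
                              h_unbound = 2.0, h_bound = 2.0,
                              kd = 0.31e-9, polarity = "n", jitter = 0))
  unknown <- setdiff(names(overrides),
                     c(names(defaults), "q_bound", "q_target"))
  if (length(unknown))
    .fail("unknown fixture override(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, overrides)
  if (is.null(p$q_bound)) p$q_bound <- p$q_unbound + p$q_target
  jit <- function(x, scale) {
    if (p$jitter == 0) return(x)
    x * (1 + p$jitter * stats::rnorm(1))
  }
  if (p$jitter > 0) {
    if (is.null(seed)) .fail("jitter > 0 requires a seed")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  structure(list(
    case_id = case_id,
    unbound = probe_state("unbound", jit(p$q_unbound), jit(p$h_unbound)),
    bound = probe_state("bound", jit(p$q_bound), jit(p$h_bound)),
    kd = p$kd, polarity = p$polarity, seed = seed),
    class = "fixture_case")
}

#' @export
print.fixture_case <- function(x, ...) {
  cat(sprintf("<fixture_case:%s> KD = %.3g nM, %s-programmed\n",
              x$case_id, x$kd * 1e9, x$polarity))
  print(x$unbound); print(x$bound)
  invisible(x)
}

#' Export a fixture as a config-file fragment
#'
#' Writes the fixture's resolved parameters as a YAML fragment so a device
#' run is reproducible from one file.
#'
#' @param fixture A `fixture_case`.
#' @param path Output path (`NULL` returns the YAML string).
#' @return The YAML string, invisibly if written to `path`.
#' @export
fixture_to_config <- function(fixture, path = NULL) {
  stopifnot(inherits(fixture, "fixture_case"))
  frag <- list(fixture = list(
    case_id = fixture$case_id,
    kd_M = fixture$kd,
    polarity = fixture$polarity,
    unbound = list(net_charge_e = fixture$unbound$net_charge,
                   height_nm = fixture$unbound$height),
    bound = list(net_charge_e = fixture$bound$net_charge,
                 height_nm = fixture$bound$height)))
  txt <- yaml::as.yaml(frag)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
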