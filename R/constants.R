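# Physical constants (CODATA 2018 exact/recommended values) shared across
# modules. Internal unit system is SI; user-facing units are nm, V, eV, A,
# molar, kcal/mol as noted per function.
.const <- list(
  q    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  h    = 6.62607015e-34,    # Planck constant, J s
  hbar = 1.054571817e-34,   # reduced Planck constant, J s
  m0   = 9.1093837015e-31,  # electron rest mass, kg
  n_av = 6.02214076e23,     # Avogadro number, 1/mol
  R_kcal = 1.9872e-3        # molar gas constant, kcal/(mol K)
)

# stop() wrapper that keeps the caller out of the message
.fail <- function(...) stop(..., call. = FALSE)

.check_num <- function(x, name, finite = TRUE, positive = FALSE,
                       nonneg = FALSE, len = 1L) {
  if (!is.numeric(x)) .fail(name, " must be numeric")
  if (!is.null(len) && length(x) != len)
    .fail(name, " must have length ", len)
  if (finite && any(!is.finite(x))) .fail(name, " must be finite")
  if (positive && any(x <= 0)) .fail(name, " must be > 0")
  if (nonneg && any(x < 0)) .fail(name, " must be >= 0")
  invisible(x)
}
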