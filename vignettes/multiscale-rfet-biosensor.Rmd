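---
title: "Multiscale modeling of RFET biosensors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale modeling of RFET biosensors: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfetsense)
```

This vignette documents the models behind `rfetsense`, the assumptions
they rest on, and the choices made where the design was genuinely open.
It states no empirical result that the package's tests do not themselves
compute.

## The sensing problem

A reconfigurable field-effect transistor (RFET) is a doping-free
Schottky-barrier transistor with two gates: the program gate (PG) selects
the carrier type by electrostatically suppressing the unwanted species at
one junction, and the control gate (CG) modulates injection of the wanted
species at the other. In the program-gate-at-drain (PGAD) layout used
here, the CG abuts the source and the PG abuts the drain. When
recognition probes are immobilized over the PG, their net charge acts as
a "virtual doping" input: binding events change the sheet charge, the
drain-junction band bending, and hence the drain current. Because the
polarity is set by bias signs rather than fabrication, one device can
read out both negatively charged targets (p-programmed) and positively
charged targets (n-programmed).

## Binding layer

Probe-target occupancy follows the single-site Langmuir isotherm
$f_a = [T]/(K_D + [T])$, with $K_D = \exp(\Delta G / RT)$,
$R = 1.9872\times10^{-3}$ kcal/(mol K), default $T = 298$ K. The model
deliberately excludes multivalent, cooperative (Hill) and kinetic
(on/off-rate) effects: the recognition chemistries targeted here
(aptamer folding, enzyme-inhibitor binding) are well described by 1:1
equilibrium stoichiometry, and everything downstream consumes only the
equilibrium bound fraction. `bound_fraction` computes $[T]/(K_D+[T])$
in exactly that ratio form so that $f_a(K_D) = 0.5$ holds to the last
bit, and `kd_from_binding_curve` reads $K_D$ back off a curve by linear
interpolation in $(\log_{10} c, f)$ — the isotherm is nearly linear in
log-concentration around half-occupancy, so a 20-point-per-decade grid
reproduces the generating $K_D$ to well under 1%.

## Interface layer

Each probe conformation is collapsed to two numbers: its net charge $q$
(elementary charges) and the height $h$ of its $|q|$-weighted charge
centroid above the substrate. In electrolyte, the coupling of that
charge to the channel is attenuated exponentially,
$S(h) = e^{-h/\lambda_D}$, with the Debye length computed from the ionic
strength; in dry mode $S \equiv 1$. This point-charge-at-centroid
reduction is the package's stated simplification: a full treatment would
resolve the three-dimensional charge distribution and the nonlinear
double layer (Poisson-Boltzmann), neither of which is attempted. The
mixed layer at bound fraction $f$ presents
$\sigma(f) = \rho e [f q_b S(h_b) + (1-f) q_u S(h_u)]$, affine in $f$ by
construction.

PBS ionic strengths are fixed at 0.15 M (1×) and 1.5 mM (0.01×) with
$\varepsilon_r = 78.4$ at 298 K. These standard values place the Debye
length at about 0.78 nm and 7.8 nm respectively — straddling the
~3.4 nm binding height of the aptamer system, which is why read-out
condition matters.

**Wet vs dry read-out.** Raw device runs (`solve_bias_point`,
`transfer_curve`) take a sheet charge directly and are
condition-agnostic; when a condition is needed the dry default applies.
The response pipeline, however, defaults to wet 0.01× PBS. The reason is
mechanistic: the aptamer signal is generated by *conformational
elongation* — the bound state is slightly more charged but sits ~2 nm
farther from the surface, so its effective charge is smaller only
because distance-dependent screening discounts it. In dry conditions
that height information vanishes and the (more charged) bound state
would enhance rather than suppress the current. Low-ionic-strength
read-out is the regime in which the height-change mechanism operates,
and it is the pipeline's default study condition.

## Probe fixtures

`make_fixture` generates the parameter sets for the two reference
systems, emulating what an MD or crystallographic upstream pipeline
would deliver:

* `aptamer_cea` — a 40-nt DNA aptamer: 39 phosphodiester linkages give
  $q_u = -39$ e (the thiol tether is neglected); heights 7.15 nm
  (unbound) and 9.13 nm (bound); the target adds $q_{CEA} = -2$ e by
  default, a parameter rather than a constant because only the sign of
  the target charge is established; $K_D = 1.47$ nM.
* `protease_inhibitor` — a surface-tethered enzyme homodimer:
  $q_u = +4$ e, $q_b = +6$ e at 2.0 nm, $K_D = 0.31$ nM. The literature
  supports only the ordering (bound strictly more positive) and the
  nanometre-scale height of a tethered globular protein; the numbers are
  config-exposed placeholders and nothing asserts their absolute values.

Every field is overridable, and a seeded relative `jitter` supports
ensemble runs (default 0). Per-atom charge profiles can replace the
built-ins entirely via PQR files (`read_pqr`,
`probe_state_from_atoms`); the shipped
`inst/extdata/synthetic_probe_*.pqr` files are synthetic examples, not
measured structures. What the fixtures do *not* emulate: conformational
ensembles, orientation disorder, per-atom charge geometry, pH-dependent
(site-binding) surface chemistry, and ion-specific effects. A passing
pipeline therefore demonstrates the device-physics consequences of the
*assumed* molecular parameters, not a prediction of any particular
laboratory system.

## Device layer

The simulator solves the stationary drift-diffusion system on a 2-D
cross-section (x along the channel, y through the 10 nm silicon film),
with the 150 nm gate width entering as a current multiplier:

* **Discretization.** Box-method finite volumes on a tensor mesh. The
  x-grid is tanh-stretched toward both contacts (sub-nm spacing there,
  ~10 nm mid-channel) because gate-induced Schottky barrier thinning
  happens on a few-nm scale; the y-grid is uniform. Default
  161 × 11 nodes; the transport oracle tests run at 201 × 31. Doubling
  the mesh changes the reference ON current by under 5% (tested).
* **Poisson.** Newton iteration with per-node update clamping (0.5 V)
  and Boltzmann carrier statistics; the gate oxide is not meshed but
  enters as a capacitance boundary condition ($C_{ox}$ from a 1 nm EOT)
  with a mid-gap gate metal. Molecular charge is a sheet-charge source
  term on the surface cells under the PG footprint;
  `sigma_to_voltage_shift` reports its first-order gate-voltage
  equivalent $\sigma/C_{ox}$.
* **Continuity.** Scharfetter-Gummel edge fluxes (overflow-safe
  Bernoulli weights), no generation-recombination. The linear systems
  are M-matrices, so carrier densities stay positive.
* **Schottky contacts.** Poisson sees barrier-pinned Dirichlet columns;
  carriers see Robin (injection-velocity) conditions
  $J = q \gamma v_R (n_s - n_B)$, with $v_R$ the Richardson velocity,
  $n_B$ the barrier equilibrium density, and $\gamma \ge 1$ a tunneling
  enhancement recomputed each Gummel cycle by WKB through the
  mesh-sampled band profile of each boundary row. This is the Boltzmann
  linearization of the Tsu-Esaki integral; the full integral (supply
  difference of the two reservoirs times a transmission that is 1 above
  the barrier maximum and WKB below) is implemented separately as
  `tsu_esaki_flux` and verified against the Richardson closed form in
  the thermionic limit. Barriers default to symmetric mid-gap
  (0.56 eV), giving a cleanly ambipolar device; the contact metal,
  oxide thickness and film thickness are not pinned down by the device
  class and are all config-exposed with the documented defaults.
* **Nonlinear strategy.** Gummel iteration; convergence requires the
  max potential update below $10^{-5}$ V and drain-current stagnation
  below $10^{-4}$ relative (or sub-femtoampere absolute, which covers
  unbiased devices whose current is pure noise), capped at 200
  iterations. Bias targets are approached by continuation in steps of
  at most 0.5 V, and sweeps warm-start each point from the previous
  solution.
* **Numerical conservation.** Terminal currents are sums of
  near-cancelling edge fluxes that exceed the net current by up to ten
  orders of magnitude in accumulation regions, so the continuity solves
  use LU factorization plus two rounds of iterative refinement with a
  *compensated* residual (Dekker two-products, Neumaier row sums).
  Without this, source/drain current conservation at femtoampere OFF
  currents would be limited by double-precision matrix-vector rounding;
  with it, conservation holds to ~$10^{-9}$ relative (tested at
  $10^{-3}$).
* **Quantum correction.** The density-gradient option
  (`density_gradient = TRUE`) applies a first-order quantum potential
  $-\hbar^2/(6 m q) \nabla^2\sqrt{n}/\sqrt{n}$, clamped to ±0.2 V and
  held fixed during one corrective Gummel pass. It is off by default;
  at a 10 nm body the qualitative device behavior is insensitive to it,
  and all tested properties hold with it off.

## Response pipeline

`current_vs_fraction` solves the device at the ON read-out point
(|V_CG| = 5 V, |V_DS| = 0.1 V) for each bound fraction. The program gate
is driven by the molecular charge alone (v_pg = 0 default): superposing
a full ±5 V program bias saturates the drain junction and suppresses the
molecular sensitivity by two orders of magnitude, whereas with the
charge as the program input the junction transparency — and the current
— tracks σ(f) strongly. An electrical `v_pg` can still be superposed as
an argument.

`calibration_curve` composes the fraction sweep with the Langmuir map
using monotone piecewise-cubic (Hyman) interpolation, exact at grid
points; `relative_response` reports ΔI/I₀ with the sign decision made on
|I| so that negative p-branch currents classify correctly, and the
half-response concentration interpolated in log-concentration.
`invert_response_for_kd` inverts the monotone fraction curve and fits
$K_D$ by least squares in $\log K_D$; on noiseless synthetic pipelines
this round-trips to well under 5%.

Concentration grids default to log-spaced 0.01–100 nM — the nanomolar
window relevant for both reference affinities (1.47 and 0.31 nM) — with
c = 0 prepended to define I₀.

## Problem sizes and determinism

The shipped tests run the transport oracle suite (conservation,
detailed balance, thermionic limit, MOS-capacitor comparison, ambipolar
sign-flip symmetry) at a 201 × 31 mesh and the dual-polarity pipeline at
the 161 × 11 default with an 11-point fraction grid; these sizes are the
package's chosen study conditions and complete in a few minutes on one
CPU. The MOS comparison uses a thicker doped film (300 nm, $10^{17}$
cm$^{-3}$, 5 nm EOT) so a genuine depletion region exists to compare
against the classical square-root charge law. All solvers are
deterministic: identical configurations produce byte-identical output
files, and the only randomness in the package (fixture jitter) is
seeded and off by default.

## Known limitations

* Absolute currents are not calibrated to any fabricated device or
  commercial simulator; only trends, signs, symmetries and closed-form
  limits are claimed, and the test suite checks exactly those.
* Boltzmann statistics overestimate carrier densities in strong
  accumulation; Fermi-Dirac statistics are not implemented.
* The electrolyte is a linear screening factor, not a solved double
  layer; oxide surface chemistry (pH response) is out of scope.
* The probe layer is laterally uniform: no discreteness, crowding or
  percolation effects across the sensing area.
* PGAS (program-gate-at-source) geometries, self-heating, noise and AC
  analysis are not modeled.
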