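---
title: "A coupled amyloid-beta/tau heterodimer model on brain networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled amyloid-beta/tau heterodimer model on brain networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteonet)
```

## The model

`proteonet` simulates two interacting protein families — amyloid-β (Aβ) and
tau (τP) — each with a healthy and a toxic (misfolded) population, on a
weighted graph whose nodes are brain regions and whose edges are
white-matter tracts. Each family follows heterodimer kinetics: healthy
protein is produced at a constant rate, cleared at a first-order rate, and
converted to the toxic form at a rate proportional to the product of healthy
and toxic concentrations (a toxic seed recruits, misfolds and fragments a
healthy protein — treated as one mean-rate step). The two families are
coupled by a single balanced term, `b3·ũ·v·ṽ`, through which toxic Aβ
catalyses the conversion of healthy tau. Toxic Aβ acts enzymatically: the
coupling term appears with opposite signs in the healthy-tau and toxic-tau
equations and does not deplete Aβ. The assumptions, in plain terms:

* transport of all four species happens along axonal bundles, modelled by
  one graph Laplacian per species scaled by a per-species diffusivity;
* kinetic rates are constant in time and (unless regional overrides are
  given) in space;
* the Aβ→τP influence is one-way; τP does not feed back on Aβ kinetics;
* damage does not feed back on transport or kinetics (the graph is static).

At a node, with state `(u, ũ, v, ṽ)`:

```
u'  = a0 − a1·u − a2·u·ũ              (healthy Aβ)
ũ'  = −ã1·ũ + a2·u·ũ                  (toxic Aβ)
v'  = b0 − b1·v − b2·v·ṽ − b3·ũ·v·ṽ   (healthy τP)
ṽ'  = −b̃1·ṽ + b2·v·ṽ + b3·ũ·v·ṽ      (toxic τP)
```

plus `−L·x` transport for each species `x`. Concentrations are on a
dimensionless unit scale: "a p% seed" means the absolute concentration
p/100, so a 5% toxic-Aβ perturbation is `ũ += 0.05`. The time unit is the
reciprocal of the (unit) clearance rates and is left uninterpreted: the
mixed-modality preset (`adni_mixed_table3`) scales most rates by 1.38,
suggesting a per-year calibration, but no time unit is asserted anywhere in
the package and the values are stored verbatim.

### Stationary states and regimes

The homogeneous kinetics have up to four closed-form stationary states
(`stationary_states()`): healthy (`s1`), toxic-Aβ-only (`s2`),
toxic-τP-only (`s3`), and fully toxic (`s4`). Two balance-of-clearance
inequalities govern everything:

* Aβ: `ã1/a2 > a0/a1`, τP: `b̃1/b2 > b0/b1` — both hold: the healthy state
  is stable (`healthy_stable`);
* both violated: `primary_tauopathy` — an Aβ-free toxic-tau state exists,
  and toxic Aβ *raises* the asymptotic tau level by the strictly positive
  gap `tau_gap()`;
* Aβ violated, τP holds: toxic tau cannot sustain itself; if the coupling
  `b3` is strong enough that the fully toxic state is admissible the regime
  is `secondary_tauopathy` (tau disease slaved to Aβ), otherwise
  `amyloid_only`;
* the remaining combination is labelled `tau_only_inadmissible_4` — a
  package naming choice for a corner the clinical narrative rarely visits.

Equality of a clearance ratio with its production ratio (relative tolerance
1e-12) is the transcritical boundary — the moment of susceptibility — and is
reported as a `boundary` annotation rather than silently assigned to a side.

For state 4 we evaluate `v4` from its printed closed form and `ṽ4` from the
printed quotient; when `u1 = u2` exactly (or `b3 = 0`) the quotient is 0/0
and the analytic limit `ṽ4 → b1(v1 − v3)/b̃1` is used, flagged
`degenerate_state4`. This avoids root-finding entirely and reproduces the
printed specializations. In the secondary regime that limit is negative,
which is the analytic content of "sustained toxic tau requires toxic Aβ":
`ṽ4 ≥ 0` forces `ũ4 > 0`.

Stability is read from the Jacobian's block-triangular structure (the
coupling is one-way): the four eigenvalues split into two quadratics solved
in closed form (`eigen_report()`), cross-checked against `eigen()` on the
full matrix. Discriminants may be negative; complex pairs are returned as
complex numbers and stability judged on real parts.

### Graphs and transport

`connectome()` stores nodes (region label, optional coordinates) and
undirected edges carrying mean fiber number `n` and mean fiber length `l`.
Two distinct matrices derive from the same edge list:

* transport weights `W = n/l²` — the inverse-squared-length scaling a
  consistent graph discretization of the Laplacian requires — giving
  `L(ρ) = ρ(D − W)`;
* damage adjacency `A = n/l` (= `W·l`), weighting the non-local
  transneuronal term of the damage law.

Directed or duplicate GraphML edges are symmetrized/merged by summing `n`
and averaging `l` (reported via a message), since the model assumes
symmetric `W`. Edge-attribute names in connectome GraphML files vary by
pipeline, so `load_graphml()` takes an attribute map with documented
braingraph.org-style defaults (`fiber_count_mean`, `fiber_length_mean`).
Fiber lengths are used as-is; no unit is assumed. `cubic_lattice()` provides
the synthetic test domain: 6-connectivity, unit fiber count, fiber length
equal to the spacing — so a path lattice with spacing `dx` realizes exactly
the second-order central-difference Neumann discretization of 1D diffusion,
which is how `simulate_front_1d()` is implemented.

### Integration

The network system (4 concentration fields plus damage, `5V` equations) is
stiff — fast reactions against slow diffusion — and is integrated with
`deSolve`'s `lsodes` (sparse-Jacobian BDF), defaults `rtol = 1e-8`,
`atol = 1e-10`, on a user output grid. Damage is integrated jointly with the
concentrations, not post-processed, because its `A(q)` term couples nodes.
Homogeneity is preserved exactly in the model (the Laplacian annihilates
constant fields), so uniform runs must reproduce single-node runs — this is
the package's primary solver verification (`verify_model()`), together with
a transition check that a uniformly perturbed network converges to the
predicted stable stationary state. `verify_model(perturb_transport = TRUE)`
deliberately flips the transport sign as a negative control; the checks must
then fail. Concentration excursions below −1e-6 abort a run; the test suite
asserts the sharper invariant that concentrations stay above −1e-9.

### Fronts

Disease spreads as pulled fronts: the asymptotic speed is selected by the
linearization about the invaded state, giving the closed-form catalogue of
`linear_front_speeds()` (`c = 2√(ρ̃·radicand)` per transition; a negative
radicand means the target state does not exist and no front can develop).
The printed 1D experiments do not state diffusivities; the package adopts
toxic-species diffusivity 0.01 because it reproduces every published caption
speed (0.1, 1/(2√15) ≈ 0.129, √(2/3)/5 ≈ 0.163) from the same formulas, and
sets the healthy-species diffusivity equal (it does not enter the speeds).
The grouping of the state-2→4 tau speed formula was fixed by requiring it to
reproduce both printed caption values (couplings 1/2 and 3); a single value
cannot discriminate groupings, two can.

`measure_front_speed()` tracks the outermost crossing of 50% of the plateau
(linearly interpolated) and fits position against time by least squares,
dropping the first 20% and last 10% of the traversed span to avoid the
seeding transient and boundary interaction; pulled-front theory makes the
asymptotic slope insensitive to the tracking level. On a 40-unit domain at
`dx = 0.1` the measured speeds sit within ~1.5% of the closed forms, and
halving `dx` moves them by under 1%.

In 1D the non-local damage term has no continuum representation (neuron
positions are not encoded), so `simulate_front_1d()` accepts damage only
with `k4 = 0`.

### Observables

`toxic_load()` averages each field over nodes. The invasion window
(`invasion_window()`) runs from the first time the mean toxic-tau
concentration reaches 1% (absolute 0.01, per the percent convention) to the
time it reaches a fraction of the analytic asymptote `ṽ∞` taken from the
active regime's stationary state. "Asymptote achieved" needs a tolerance the
definition itself does not supply: the default is 0.99. The choice matters
quantitatively but not structurally — at 0.95 windows shorten and at 0.999
they lengthen (the approach is exponential, so the shift is roughly the
slowest eigenvalue's reciprocal times log-ratio of tolerances), while every
monotonicity and ordering property tested is unchanged. Both threshold
crossings are located by linear interpolation on the output grid.
`saturation_curve()` offers both normalizations in circulation: by the
analytic asymptote (absolute progression) and by the curve's own maximum
(per-coupling onset comparison). `fit_exponential()` fits
`A·exp(−k·x) + c` with `k > 0` (log-parameterized, Levenberg–Marquardt,
Nelder–Mead fallback); the offset is included by default because
saturation-time curves plateau, and a pure two-parameter fit is available by
flag. Constant inputs are flagged degenerate rather than fitted.

## Parameters

| Field | Meaning | Unit | Baseline (primary) |
|---|---|---|---|
| `a0`, `b0` | healthy production | conc/time | 0.75, 0.5 |
| `a1`, `b1` | healthy clearance | 1/time | 1, 1 |
| `a2`, `b2` | toxic conversion | 1/(conc·time) | 1, 1 |
| `a1t`, `b1t` | toxic clearance | 1/time | 0.6, 0.4 |
| `b3` | Aβ→τP coupling | 1/(conc²·time) | 1 |
| `rho_*` | per-species diffusivity | Laplacian scale | 1 |
| `k1`–`k3` | local damage rates | 1/(conc·time) | 1e-4, 1e-2, 1e-1 |
| `k4` | transneuronal rate | 1/time | 1e-3 |

Diffusivities are stored per species even though the transport definition
writes a single scale: the mixed-modality preset uses distinct values per
population (1.38, 0.138, 1.38, 0.014), and a single global value is just the
special case of four equal fields. Damage defaults encode the clinical
ordering: tau is far more damaging than Aβ (`k2 ≫ k1`), joint toxicity more
damaging still (`k3 > k2`).

Presets are literal transcriptions — `preset_params()` performs no fitting —
and serialize to flat YAML with ASCII names (`a1t`/`b1t` for ã1/b̃1);
`read_params_file(write_params_file(p))` round-trips values exactly.
Regional parameter maps apply ordered, last-write-wins overrides to nodes
matched by case-insensitive label substring (so `"cuneus"` deliberately
matches both hemispheres — and also the precuneus, which is why the
mixed-modality preset lists the precuneus override after it) or by explicit
node index; an override matching no node is an error, not a silent no-op.

## What the synthetic generators emulate — and what they do not

`cubic_lattice()` reproduces the published synthetic channel domain
(30×6×3, unit spacing) and, as a path graph, the 1D continuum; the test
helper builds small random connected graphs with anatomical-style labels and
tractography-style attribute ranges. These fixtures exercise every code
path — transport, seeding by region or coordinate, regional overrides,
damage, GraphML round-trips — at sizes where every claim can be checked
against closed forms in seconds. They do not emulate the topology of a real
connectome: its heavy-tailed degree distribution, hemispheric symmetry,
long-range shortcuts, or the 10³-node scale. Consequently, passing tests
establish the correctness of the kinetics, the analysis, and the integrator,
and the *qualitative* progression structure (plateaus, front ordering,
window trends); they do not certify quantitative staging patterns on real
connectomes, which are known to depend on graph resolution.

## Numerical choices

* Solver: `lsodes`, `rtol 1e-8` / `atol 1e-10`. The homogeneity-preservation
  tests tighten to `1e-11`/`1e-13` since they assert 1e-8 agreement between
  two solver outputs.
* Regime-boundary equality tolerance: relative 1e-12, reported as
  `boundary` rather than decided by a side.
* Threshold crossings (onset, saturation, front position): linear
  interpolation between output times / grid points; no dense event location
  is needed at the output densities used.
* Degenerate inputs: `b3 = 0` or `u1 = u2` route state 4 through the
  analytic limit with a flag; `rho = 0` yields the zero transport operator;
  an edgeless graph is valid (warning); a disconnected graph warns but is
  not an error, and its Laplacian kernel has one dimension per component.
* Problem sizes in the shipped tests: the 540-node lattice for plateau and
  invasion-window properties (a few seconds per run), 400–500-point 1D grids
  for front-speed measurement, 1000 random parameter draws for the
  eigenvalue and fixed-point properties.

## Known limitations

* No stochasticity, no structural plasticity, no damage feedback onto
  transport or kinetics; the graph and parameters are static.
* The 2D/3D continuum is out of scope; only the network model and the 1D
  continuum reduction are implemented.
* Anatomical seeding by label substring depends on the naming scheme of the
  loaded connectome; resolved node sets should be inspected when working
  with new files.
* In-vivo calibration of the nine kinetic rates is an open problem; presets
  are illustrative regimes, not patient parameters, and no fitting to
  clinical data is provided by design.
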