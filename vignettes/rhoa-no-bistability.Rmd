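---
title: "Modeling bistability in the RhoA-nitric-oxide mechano-signaling network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bistability in the RhoA-nitric-oxide mechano-signaling network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

RhoA (through its effector kinase ROCK) is a master regulator of actomyosin
contractility; nitric oxide (NO, through cGMP and protein kinase G) is a
master regulator of relaxation. The documented cross-talk between the two
pathways is predominantly antagonistic in both directions: ROCK suppresses
Akt-dependent phosphorylation of eNOS and destabilizes eNOS mRNA, while
NO-activated PKG phosphorylates RhoA at Ser188 and inactivates it. Mutual
antagonism is a double-negative feedback loop — a net positive feedback —
and, combined with ultrasensitivity, a canonical generator of bistability.

This package asks, computationally: can the RhoA-NO network behave as a
bistable switch, over what range of the antagonism strengths, and how much
does mechanical tension (which RhoA increases and NO relieves, and which in
turn activates RhoA) change the robustness of that switch?

Three models are bundled:

* **Two-node motif** (`build_two_node()`): species A and B with zeroth-order
  production, first-order degradation, and mass-action mutual inhibition.
  This motif is *provably monostable* for every positive parameter
  combination — eliminating one variable leaves a quadratic whose root
  product is negative, so exactly one equilibrium is admissible
  (`two_node_steady_state()`). Mutual antagonism alone is therefore not
  sufficient for bistability; some ultrasensitive step is required.
* **Biochemical RhoA-NO network** (`build_initial_model()`): 31 reactions
  over 11 states (active RhoA, phospho-RhoA-Ser188, ROCK, Akt, phospho-Akt,
  eNOS mRNA, eNOS, phospho-eNOS-S1177, NO, cGMP, PKG activity) with a
  clamped constant HGF input that prevents the stimulated species from
  decaying to zero. The two antagonism arms are ROCK-catalyzed inactivation
  of phospho-Akt (rate constant `ki1`) and RhoA-catalyzed destabilization of
  eNOS mRNA (`ki2`); PKG activation by cGMP is the single ultrasensitive
  step (Hill, coefficient 2, half-saturation `Kmcgmp`).
* **Tension-extended network** (`build_extended_model()`): adds one
  dimensionless tension state coupled by three reactions — ROCK generates
  tension, PKG (the NO/cGMP effector) relaxes it, and tension feeds back to
  activate RhoA. The feedback saturates in tension (Michaelis-Menten with
  capacity `kt4` and half-saturation `KT`): an unsaturated linear
  ROCK-to-tension-to-RhoA loop has unbounded gain and diverges, so the
  saturation is a structural requirement, not a tuning choice. The extended
  model has 12 equations and 36 perturbable rate constants.

## Provenance of the rate laws and baseline parameters

The reaction-by-reaction kinetic forms follow the standard reading of each
step: mass action for bimolecular catalytic steps (phosphorylations,
inactivations), zeroth-order synthesis with catalytic activators for
production terms, first-order decay for turnover, and a Hill law only where
cooperative activation is documented (PKG by cGMP). Every reaction carries
exactly one rate constant; `k1`-`k15` name the production/conversion arm,
`kdeg1`-`kdeg11` the turnover arm, and `ki1`/`ki2` the two antagonism
reactions. The Hill coefficient (`npkg = 2`) is structural and is excluded
from perturbation analyses.

Baseline rate constants are **search-derived**: starting from an
order-of-magnitude sketch of the pathway (protein pools of tens of nM,
messenger lifetimes shorter than protein lifetimes), the package's own
parameter-space search and a closed-form steady-state reduction were used to
locate the bistable regime of the `ki1`/`ki2` plane, and the NO production
and clearance constants were scaled so that steady-state NO falls in the
low-nanomolar physiological range. The baseline deliberately sits close to
the biochemical model's lower `ki1` fold: at such a point bistability of the
purely biochemical network is brittle — small single-parameter perturbations
cross the fold — while the tension-extended network, whose bistable regime
is several-fold wider, remains robustly bistable at the same point. This
mirrors the qualitative contrast the analysis is designed to expose. The
absolute magnitudes are not predictive; the object of study is the
qualitative behavior (number of attractors, shape of the bifurcation
diagram, robustness of the bistable regime).

All provenance is recorded on the `rn_parameters` object and every bundled
model serializes losslessly to a JSON model file (`write_model_json()`), or
to SBML Level 3 Version 1 (`export_sbml()`) for cross-checking in external
simulators.

## Numerical machinery

**Integration and steady states.** Assembled networks are integrated with a
stiff-capable solver (deSolve's `lsodar`) with integrator tolerances
`rtol = atol = 1e-8` and a default horizon of 1e6 model time units (the time
unit is symbolic; the reported results are invariant to it). Integration
exits early when `max|dx/dt| < 1e-9 (1 + max|x|)` and the criterion is
confirmed over a trailing window of 1% of the horizon. Final states are
polished by damped Newton iteration (residual target 1e-10; damping
guarantees the residual never increases), and stability is classified from
the Jacobian eigenvalues with a margin of 1e-8 on the real parts;
eigenvalues inside the margin are "marginal" and never counted as
attractors. States are never clipped at zero: negative excursions beyond
the absolute tolerance are flagged instead.

**Attractor census.** `classify_attractors()` draws random initial levels of
all species, integrates each to steady state, and clusters the stable final
states at a relative max-norm tolerance of 1e-3 — far below the several-fold
separation between the attractors of interest and far above integrator
error. The default sampling box spans the attractors the model actually
visits: each protein pool is sampled log-uniformly over `[min/100, max*10]`
of the span of the steady states reached from the two extreme
initializations, while the rapidly equilibrating messenger activities (NO,
cGMP, PKG) are sampled from basal levels up to the geometric mid of their
span. The messenger cap reflects that second messengers are transient
activities rather than stores: initializing them at saturating levels
decides the race between the two arms before the slower protein pools can
act, which collapses the contractile basin to a few percent of the box and
makes ensemble-based detection at practical ensemble sizes unreliable. With
the default box the minority basin receives roughly 15-40% of random starts
in both RhoA-NO models, so a 100-start census (the headline experiment)
essentially never misses a basin, and the reduced ensembles used inside the
robustness grid (8 starts per cell) miss one only rarely.

**Bistability verdict.** `is_bistable()` is deliberately a conjunction of
two independent lines of evidence: the multistart census must find at least
two distinct stable attractors *and* the two extreme initializations
("NO-high" and "RhoA-high" corner states, synthetic constructions of this
package) must converge to distinct stable states. The conjunction is
stricter than either test alone and guards against basins missed by one
method.

**Continuation.** `continue_branch()` implements pseudo-arclength
equilibrium continuation: bordered-system tangents (the previous tangent as
the border row, which keeps the direction continuous through nearly singular
Jacobians), Newton correction orthogonal to the tangent, adaptive step
control (initial step 1% of the range, bounded to [1e-5, 5%]), and
per-component state scaling so that concentrations spanning four decades and
the swept parameter contribute comparably to arclength. Folds are detected
by reversal of the tangent's parameter component and refined by bisection to
a relative parameter tolerance of 1e-6. Branches are anchored at both ends
of the sweep range and merged, so interior folds cannot be missed. The
bistable interval is the parameter range over which at least two distinct
stable branch points coexist, computed by interpolating stable branch
segments to a common parameter grid (naive clustering of raw branch points
double-counts overlapping traces and over-extends the interval — a failure
mode caught by the cubic normal-form oracle). `hysteresis_sweep()` is the
independent cross-check: quasi-static up and down parameter sweeps whose
disagreement region must bracket the same interval within one step width.

**Robustness.** `single_parameter_robustness()` perturbs one rate constant
at a time by a signed percentage and re-tests bistability; a parameter
"retains bistability at p%" only if both the +p% and the -p% perturbations
remain bistable (the stricter both-signs reading; the raw signed columns are
kept so the one-sided convention remains computable). Cells whose
integrations fail are recorded as inconclusive (`NA`), distinct from
`FALSE`. Every cell derives its ensemble seed deterministically from the
root seed, so the matrix is bit-reproducible.

## What the default experiments show

At the search-derived baseline the biochemical model has two attractors —
NO around 11.6 nM with RhoA around 1.7 nM, versus NO around 0.17 nM with
RhoA around 41 nM — and the extended model deepens the contractile state
(RhoA around 109 nM, NO around 0.04 nM). Sweeping the antagonism constants
produces the S-shaped fold pair in both models; the tension-extended
regime is wider on the weak-antagonism side (the tension feedback keeps the
RhoA-high state alive when biochemical antagonism alone would lose it), and
across its wider regime the stable NO branches span a larger concentration
range. At ±15% single-parameter perturbation the biochemical model loses
bistability for the majority of its rate constants while the extended model
retains it for nearly all — the quantitative counts are recomputed by
`scripts/acceptance.R` rather than quoted here.

These are statements about *this reconstruction*: the synthetic ensembles
emulate random initialization and percentage perturbation protocols, not
measured cell-to-cell variability; the models omit Rho-GEF/GAP regulation,
post-translational modifications of RhoA beyond Ser188 phosphorylation,
spatial gradients, and time-varying stimuli. Passing tests demonstrate
internal consistency of the dynamical analysis, not quantitative agreement
with any particular cell type.

## Problem sizes and run times

The bundled experiments are sized for a single CPU: 100-start censuses for
the headline bistability claims, four continuation sweeps of a few thousand
corrector solves each, robustness grids at 8 starts per cell (36 parameters
x 3 levels x 2 signs for the extended model), and the full 5^6 two-node
grid via the closed form with a 25-combination dynamic subsample. The whole
acceptance script completes in roughly a quarter of an hour; the test suite
runs the same analyses at further reduced sizes.

## Known limitations

* Fold detection assumes fold (saddle-node) bifurcations; Hopf points would
  be labelled only as stability changes, and oscillatory attractors are not
  censused (none arise at the bundled baselines — all reported attractors
  pass the re-convergence check).
* The continuation corrector rejects solutions far from its predictor, so
  branches separated by extremely sharp kinks may terminate early with a
  step-size-collapse warning and a partial diagram.
* `is_bistable()` at small ensemble sizes can return a false negative when
  a basin is very small. Two mitigations are built in: the span-based
  sampling box, and one ensemble retry with a fresh derived seed before a
  single-basin verdict is accepted (a retry can only repair false negatives,
  since a monostable system never produces two stable clusters). Isolated
  non-monotone cells in a retention profile should still be read as sampling
  noise, not bifurcation structure.
* The JSON model dialect stores rate-law kinds, not arbitrary expressions;
  kinetics outside the five built-in families require a raw `rate_field()`.
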