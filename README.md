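# rhonobist

Bistability analysis of the mutual antagonism between the RhoA/ROCK
contractility pathway and the eNOS/NO/cGMP/PKG relaxation pathway, with an
optional cytoskeletal-tension feedback loop.

RhoA drives actomyosin contraction; nitric oxide drives relaxation. Their
cross-talk is antagonistic in both directions — ROCK suppresses
Akt-dependent eNOS activation and destabilizes eNOS mRNA, while NO-activated
PKG phosphorylates RhoA at Ser188 and inactivates it. A double-negative loop
of this kind is a net positive feedback and, with an ultrasensitive step, a
candidate bistable switch. This package builds the reaction-network ODE
models, detects multistability, maps the bistable regime, and quantifies its
robustness, for anyone studying switch-like behavior in cytoskeletal
signaling.

## What it computes

* **Typed reaction networks** (`rn_model()`, `rn_reaction()`, `assemble()`):
  zeroth-order synthesis, first-order decay, mass action, Michaelis-Menten
  and Hill rate laws, clamped inputs, compiled to an evaluable vector field
  with a finite-difference Jacobian. JSON round-trip and SBML L3V1 export.
* **Three bundled models**: the two-node mutual-antagonism motif (provably
  monostable under mass action — `two_node_steady_state()` gives the unique
  equilibrium in closed form); the biochemical RhoA-NO network (31
  reactions, 11 ODEs, constant HGF input); and the tension-extended network
  (12 ODEs, 36 rate parameters) in which ROCK generates tension, PKG
  relaxes it, and tension feeds back to activate RhoA.
* **Multistability** (`classify_attractors()`, `is_bistable()`,
  `search_bistable_parameters()`): seeded multistart ensembles with
  integrate-then-Newton steady-state location, attractor clustering,
  extreme-initialization cross-check, and log-uniform parameter-space
  search.
* **Bifurcation analysis** (`continue_branch()`, `hysteresis_sweep()`,
  `no_range_across_regime()`): pseudo-arclength equilibrium continuation
  with fold detection refined by bisection, cross-checked by quasi-static
  hysteresis sweeps; extraction of the bistable interval and the NO range
  across the regime.
* **Robustness** (`single_parameter_robustness()`, `count_retaining()`):
  one-at-a-time percentage perturbations of every rate constant, with the
  strict both-signs retention rule and black/white retention heatmaps.
* **Orchestration** (`run_experiment()`): YAML-configured experiments
  (simulate / classify / bifurcate / robustness / search / export-sbml)
  writing CSV/JSON results, figures, logs and a re-runnable manifest; a thin
  command-line wrapper lives in `inst/cli/rhonobist.R`.

## A worked example

```r
library(rhonobist)

built <- build_initial_model()     # 31 reactions, 11 ODEs, clamped HGF = 1
census <- classify_attractors(built$model, built$params,
                              n_starts = 100, seed = 1)
census
#> <rn_bistability> 2 attractor(s) from 100 starts (basins: 76, 24; nonconverged: 0)

round(sapply(census$attractors, function(a) a$state[c("RhoA", "NO")]), 3)
#>        [,1]   [,2]
#> RhoA  1.659 40.738
#> NO   11.620  0.175
```

One hundred random initializations converge to exactly two stable steady
states: a relaxed state (NO about 11.6 nM, RhoA low) and a contractile state
(RhoA about 41 nM, NO about 0.2 nM). Sweeping the antagonism constant `ki2`
shows the characteristic S-shaped fold pair bracketing the bistable regime:

```r
dg <- continue_branch(built$model, built$params, "ki2", c(0.005, 0.8))
dg
#> <rn_bifurcation> ki2 in [0.005, 0.8]: 2 branch trace(s), 2 fold(s), bistable in [0.09263, 0.4014]
plot(dg)                                    # NO vs ki2, folds marked
no_range_across_regime(dg)
#>        min        max
#> 0.03374004 12.13823664
```

The same sweep on the tension-extended model (`build_extended_model()`)
gives a wider bistable interval, and the robustness grid
(`single_parameter_robustness()`) shows the extended model retaining
bistability under percentage perturbations that break the purely biochemical
switch. The methods vignette (`vignettes/rhoa-no-bistability.Rmd`) documents
the models, the numerical machinery and the design decisions.

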