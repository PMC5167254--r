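---
title: "Modeling odor-mixture similarity with a mitral-granule bulb network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling odor-mixture similarity with a mitral-granule bulb network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfbulb)
```

## The model

`olfbulb` simulates how reward conditioning on an odorant mixture reshapes
the spatial response of the olfactory bulb's output layer, and uses the
reshaped responses to predict how discriminable other odors are from the
rewarded one. The circuit is a rate model with three stages.

**Glomerular front end.** A 2-DG-style activity image (357 x 197 pixels by
default) is partitioned into `n_alpha x n_beta` rectangular cells, one per
glomerular unit; the default `95 x 19 = 1805` units matches the
approximate glomerulus count of a mouse bulb. Each unit's value is the
mean z-score of its cell. Patterns are min-max rescaled to `[0, 1]` and
binarized at `theta = 0.60` (picking out the strongly activated part of
the map, roughly z > 2), and a k-component mixture's peak drive is the
per-unit mean of the component binary maps, so every peak is a multiple of
`1/k`. Respiration turns the static peaks `P_i` into a drive waveform: a
linear ramp up to `P_i` over the 220-ms inhalation, then exponential decay
with a 33-ms time constant until the cycle ends at 400 ms. The printed
form of this breath function in the source literature is self-referential
during inhalation and its decay exponent grows before the cycle end as
typeset; we implement the standard reading — ramp to the peak, decay
referenced to the inhalation end, continuity across the phase boundary and
across cycles (cycle 1 ramps from zero, later cycles from the previous
cycle's end value).

**Mitral-granule dynamics.** Each lattice unit holds one mitral and one
granule unit (columns of real cells), coupled by three random,
range-limited matrices on the wrapped lattice:

$$\dot X = -H\,g_y(Y) - X/\tau_x + c\,L\,g_x(X) + I(t), \qquad
  \dot Y = W\,g_x(X) - Y/\tau_y + I_c,$$

with `tau_x = tau_y = 7` ms. `H` (granule to mitral) is inhibitory, `W`
(mitral to granule) excitatory, `L` lateral mitral-mitral excitation.
`g_x` and `g_y` are two-branch tanh nonlinearities with threshold
`zeta = 1.0` and saturation constants `(S'_x, S_x) = (0.14, 1.4)`,
`(S'_y, S_y) = (0.29, 2.9)`; both branches have unit slope at the
threshold, so the curves are C1 and take the values 0.14 and 0.29 there.
Connectivity: a unit at lattice distance `0 < d < zeta_m` (mitral radius,
default 4) or `0 < d < zeta_g` (granule radius, default 15) is connected
with weight `N(1, 0.05)` truncated at zero and divided by the radius for
`H` and `W`; `L` keeps the undivided weight, exactly as the source rule
prints it. Distances wrap around both lattice edges (torus metric); an
alternative `"reflect-beta"` mode folds the short axis back with
reflection, since the real surface is closer to a sphere than a torus —
the printed distance equations do not reduce to either metric
unambiguously, so both are provided and the torus is the default. Note
that with the default factorization the granule radius (15) exceeds half
the short extent (9.5), so granule neighborhoods wrap onto themselves;
`build_synapses()` warns about this, and the warning is expected at the
default study scale.

**Dissimilarity read-out.** An odor's spatial response is
`S_i = \int_0^{400} x_i(t)/\max_t x_i(t)\,dt` over the last simulated
cycle (rectangle rule on the recorded grid; the internal state `x`, not
its activation, is integrated, as printed in the source model). Units
whose maximum stays below a small guard (`1e-9`) score zero; negative
excursions are integrated as-is. The dissimilarity between two odors is
`E = 1 - r` with `r` the Pearson correlation of their response vectors;
`E` is 0 for identical spatial patterns and 2 for anticorrelated ones.

**Hebbian conditioning.** Reward training adapts only `H`:
`dH_ij/dt = -eta1 H_ij^2 + eta2 g_x(x_i) g_y(y_j)` with `eta1 = 1e-5`,
`eta2 = 1e-3` per ms, co-integrated with the network by the same RK4
stepper. The update is restricted to the existing synaptic support by
default: the rule indexes existing connections, and unrestricted growth
would densify `H` against the range-limited anatomy (a
`mask_to_existing = FALSE` switch expands the support to every
off-diagonal pair for small-lattice experiments). Learning runs through
both respiratory phases — the source procedure does not gate it. The
source only states that training stops when the weights "converge"; we
quantify that as the per-cycle statistic
`max_ij |Delta H_ij| / max(H_ij, 1e-8)` dropping below `conv_tol = 1e-2`,
which terminates within five respiratory cycles on the default synthetic
panel, matching the behavior reported for the original simulations.

## Numerical choices

* **Integrator**: fixed-step classical RK4 (the source is silent on the
  scheme), `dt = 0.1` ms, so the 7-ms time constants are resolved by 70
  steps; halving `dt` moves a one-cycle endpoint by less than `1e-6`
  relative. The stepper is compiled (Rcpp) with sparse matrix-vector
  products; a full-scale cycle (1805 units, ~1M nonzero weights) takes
  roughly ten seconds on one core.
* **Initial state**: `X = Y = 0` at the start of every simulation; the
  first cycle's drive ramps from zero.
* **Drive sampling**: the breath waveform is generated on a 1-ms grid and
  interpolated linearly inside the stepper; the ramp is exact and the
  decay's interpolation error is O(1e-4) relative per sample.
* **Divergence guard**: any state magnitude above `1e6` aborts with an
  error naming the time; diverged replicates in `run_experiment()` are
  recorded and excluded with a warning, never silently.
* **Unvalued constants**: the lateral gain `c` is never valued in the
  source text; we default it to 1.0. The background and cortical drives
  are likewise unvalued (the source's parameter tables live in
  supplementary material not available to us); both default to 0.1,
  constant across units and time, and all package-level claims are
  designed to be robust to these choices.
* **Scoring window**: discrimination scoring simulates `score_cycles = 2`
  cycles and reads the last one, a steady-state reading; conditioning
  diagnostics use the per-cycle statistics directly.

## The two-step experiment

`run_experiment()` repeats the source protocol over replicate
connectivity draws (default 20, replicate r seeded with
`master_seed + r - 1`): draw `H`, `W`, `L`; condition on the rewarded
mixture (by default the full three-component mixture `A+B+C`); freeze
`H`; score every target odor (defaults: the six proper sub-mixtures
`A+B`, `A+C`, `B+C`, `A`, `B`, `C` — the study's discrimination panel)
plus the rewarded odor itself, whose self-dissimilarity ~0 is a pipeline
check. Per-odor means and standard deviations over seeds are reported;
supplied behavioral discrimination rates yield the Pearson correlation
with its exact t-based p-value, and pairwise Welch tests with Bonferroni
correction reproduce the comparison-table analysis (the source does not
name its underlying test; Welch's unequal-variance test across seed
replicates is our choice). `sweep_parameters()` maps the correlation over
a `zeta_m x zeta_g` grid (default 3..7 x 13..17, 25 cells), reusing the
same replicate seeds across cells for variance reduction.

## The synthetic panel

Measured glomerular maps come from a public database that this package
does not download; the synthetic generator stands in for them and defines
the package's test conditions. Each odorant is a sum of `n_foci = 12`
isotropic Gaussian foci (`focus_sd = 10` px) on the 357 x 197 canvas,
amplitudes uniform in 1.5-3.5 z-units, clipped at the upper amplitude.
Foci sit on lattice-cell centers so that the `overlap` parameter (default
0.25) — the fraction of each odorant's foci drawn from a panel-wide
shared pool — translates exactly into shared supra-threshold units after
filtering. With these defaults the binarized patterns activate a few
percent of the 1805 units, sparse enough to keep the dynamics in a
responsive regime. The generator emulates the sparse smooth foci and
z-score amplitude scale of 2-DG maps but not their spatial
autocorrelation or the modular organization of the real bulb, so passing
tests demonstrate the machinery, not biological fidelity of the input
statistics. Synthetic behavioral rates are a clipped noisy affine map of
true dissimilarities, used to verify that the correlation pipeline
recovers a known relationship.

Tests run the heavy dynamics at a reduced `19 x 10` lattice (with the
standard radii, hence the expected wrap warning) and the
enhancement/suppression check at the full 1805-unit scale over five
seeds; the replicated-experiment tests use 1-3 replicate seeds. These
sizes are the package's test design; the full 20-seed, 25-cell protocol
is available through `run_experiment()` and `sweep_parameters()`.

## A worked reduced-scale run

```{r example, eval = FALSE}
geom <- bulb_geometry(19, 10)
spec <- synth_spec(3, image_shape = c(60, 95), n_foci = 8, focus_sd = 4,
                   seed = 1, geom = geom)
panel <- synth_panel(spec)
cfg <- experiment_config(panel, n_seeds = 5, score_cycles = 1)
ex <- run_experiment(cfg)
ex$summary
plot(ex)
```

## Known limitations

* The printed distance equations and breath function of the source are
  internally inconsistent as typeset; our readings are documented above
  and as configuration switches (`mode`, `l_radius_follows_printed_eq`),
  but neither is a claim about the original code.
* The source asserts that dividing weights by the radius makes input
  strength independent of the connection range; neighbor count grows with
  the radius squared, so it does not — we follow the printed rule
  regardless.
* Mixture maps are linear combinations of binarized component maps;
  nonlinear glomerular mixture interactions are out of scope.
* The headline comparison against measured mouse discrimination rates
  needs the external map database and behavioral data; with synthetic
  inputs the package verifies the machinery (convergence, enhancement and
  suppression, correlation recovery, statistics), not the measured
  correlation value.
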