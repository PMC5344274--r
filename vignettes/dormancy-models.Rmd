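---
title: "Modeling EMT-driven exit from tumor dormancy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling EMT-driven exit from tumor dormancy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtdorm)
```

## The biological question

Micrometastatic tumors seeded by a single disseminated cancer cell can stay
dormant — clinically undetectable, at a stable small size — for years before
switching to rapid growth. `emtdorm` implements two complementary models of
this process built around the cancer stem cell paradigm: mesenchymal,
stem-like cells (M) divide asymmetrically, producing one stem cell and one
differentiated epithelial cell (E) per division; epithelial cells
proliferate with a finite lifespan; and epithelial-mesenchymal transition
(EMT) converts an epithelial cell back into a stem-like mesenchymal cell.
The question both engines address is which cellular rates hold a tumor in
dormancy and which perturbations let it escape.

## The deterministic engine

### Model forms

The population ODEs come in three nested variants
(`model_variants()`). With saturated epithelial feedback and EMT:

$$\frac{dM}{dt} = (\alpha_1-\alpha_2-\alpha_3)\,M + \beta_4 E, \qquad
\frac{dE}{dt} = \alpha_2 M + \Big(\beta_1-\beta_2-\beta_3-\beta_4-
\frac{kE}{1+mE}\Big) E.$$

The `linear` variant replaces the saturated loss $kE/(1+mE)$ by $kE$ and
drops EMT; the `saturated` variant keeps the saturation but sets the EMT
flux to zero. Without EMT the stem equation decouples and
$M(t)=M_0 e^{(\alpha_1-\alpha_2-\alpha_3)t}$ (`closed_form_M()`), so purely
asymmetric division without death ($\alpha_1=\alpha_2$, $\alpha_3=0$) keeps
a single pioneer stem cell as the tumor's only stem forever.

### Parameters

All rates are per cell division (1/div). The defaults of `emt_params()` are
the baseline simulation values:

| parameter | default | meaning |
|---|---|---|
| `alpha1` | 0.32 | proliferative capacity of M |
| `alpha2` | 0.32 | differentiation M→E |
| `alpha3` | 0.02 | death of M |
| `beta1` | 0.87 | proliferative capacity of E |
| `beta2` | 0.25 | senescence of E |
| `beta3` | 0.4 | death of E |
| `beta4` | 0.0025 | EMT rate |
| `k` | 0.0026 | carrying-capacity constant [1/(N div)] |
| `m` | 0.0036 | max per-capita growth constant [1/N] |

The proliferation rates are anchored to measured doubling times in cancer
cell lines: 0.725–3.31 days, i.e. 0.302–1.38 divisions/day
(`division_rate_from_doubling_time()`). `alpha1 = 0.32` sits at the slow
end (stem-like cells cycle slowly); `beta1 = 0.87` reflects faster
epithelial turnover. The remaining rates are order-of-magnitude estimates
chosen so the baseline holds a small dormant tumor.

### Equilibria, stability and the eradication threshold

`steady_states()` returns both analytic branches. Setting $dM/dt=0$ forces
$M^*=(\beta_4/\alpha_3)E^*$ — an algebraic identity tested property-style —
and substitution gives the closed form for $E^*$. At the defaults the tumor
branch is $(M^*, E^*) \approx (19.24,\ 153.9)$ cells: a micrometastasis of
a few hundred cells, overwhelmingly epithelial. The published equilibrium
expressions eliminate $\alpha_1$ using the asymmetric-division assumption
$\alpha_1=\alpha_2$; perturbing $\alpha_1$ alone leaves that regime, which
is why the analytic-derivative cross-check in the test suite is restricted
to the $\beta$ parameters.

`classify_stability()` evaluates the analytic Jacobian (including the
derivative of the saturated term) and classifies by eigenvalue real parts.
`beta_star()` gives the epithelial death rate at which the tumor and
tumor-free branches meet and exchange stability in a transcritical
bifurcation:

$$\beta^* = \frac{\beta_4\alpha_2}{\alpha_3} + (\beta_1-\beta_2-\beta_4)
= 0.6575 \text{ at baseline.}$$

Below $\beta^*$ every positive initial condition converges to the tumor
branch and the tumor-free state is unstable — dormant tumors are robust;
above it the tumor is eradicated from any starting size
(`bifurcation_scan()` traces both branches and can verify convergence by
integration). A zero Jacobian determinant at the origin pins the crossing
to $\beta_3=\beta^*$ exactly, which the tests verify algebraically.

### Sensitivity analysis

`sensitivity_scan()` perturbs each rate independently by a fraction
(default 5%) and reads out the change in M at `t_eval = 500` from a
single-stem start, as a finite-difference coefficient
$(M(p+\Delta p)-M(p))/\Delta p$ with $\Delta p = 0.05\,p$. The readout and
perturbation size are fixed by the study design; the difference scheme is
not, so forward differences are the default with central differences as an
option — both give the same ranking, which is the result the package
treats as ground truth: the EMT rate $\beta_4$ dominates by roughly an
order of magnitude, stem proliferation $\alpha_1$ is a distant second, and
all other rates have small effects. Only this ordering is asserted; the
magnitudes depend on the unpublished details of the original difference
scheme and are not reproduced by any standard scheme we tried (forward,
central, varying fraction), which give the same ordering at ~3x smaller
magnitude for $\beta_4$.

A note on the convergence flag: at $t=500$ the single-stem trajectory is
within 0.05% of the equilibrium but its residual derivative norm
($\approx 3\times10^{-4}$) still sits just above the strict steady-state
criterion $\lVert f\rVert < 10^{-6}(1+\lVert x\rVert)$, so the report
carries `converged = FALSE` there and `TRUE` by $t=1000$. The flag is
deliberately strict and informational rather than an error.

### Treatment scenarios

`simulate_treatment_scenario()` runs piecewise-constant parameter
schedules (`treatment_schedule()`) through pre/during/post phases. The
default window — 500 divisions pre-treatment, 250 under treatment, 500
after — is a design choice: each phase is long enough to approach its
steady state, which is all the qualitative claims need; the window is
fully configurable. The four canonical scenarios:

* **e_death_only** — `beta3` raised 33% (0.4 → 0.532). Since
  $0.532 < \beta^*$, both populations shrink to a smaller steady state but
  the tumor persists and returns to the original equilibrium after
  treatment.
* **resistance** — as above, but post-treatment `beta3` settles below its
  original value, modeling selection for death-resistant clones. The
  magnitude of that reduction is not fixed by the underlying analysis; the
  default is 90% of baseline (configurable), enough to move the tumor to a
  visibly larger equilibrium.
* **emt_block** — `beta4 = 0` during treatment. The stem pool decays at
  exactly $e^{-\alpha_3 t}$ while E barely declines (the during-treatment
  attractor is an epithelial-only boundary equilibrium); the tumor
  recovers fully afterwards. EMT blockade alone is nearly useless.
* **combined** — both at once: the mesenchymal population is eliminated
  and only a small epithelial remnant (~39 cells at defaults) survives —
  yet that remnant regrows the entire tumor once treatment stops.

`sweep_death_rates()` quantifies the complementary point for cytotoxic
therapy: per absolute unit of rate, raising mesenchymal death `alpha3`
shifts the epithelial steady state about twice as much as raising `beta3`
(≈1.8 vs ≈0.9 cells per 0.001 at baseline). For equal *relative*
perturbations the comparison reverses, because the baseline `beta3` is
twenty times larger; the sweep reports absolute shifts.

### Numerical choices

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) at
`rtol = 1e-8`, `atol = 1e-10`; the fixed-point convergence tests need
tight tolerances. Abundances are clipped at zero after each output step to
absorb solver undershoot. Schedules restart the integrator at interval
boundaries so parameter discontinuities are exact. Equilibrium residuals
are judged relative to the state magnitude, since the equilibrium fluxes
are O(100) and cancel to rounding error.

## The stochastic engine

### Model and semantics

For very small populations rates substitute poorly for probabilities, so
the second engine is an explicitly stochastic, generation-synchronous
branching model (`sim_config()`, `run_batch()`). Per generation: every
stem cell divides asymmetrically (persists, emits one fresh epithelial
cell); every live epithelial cell either undergoes EMT with probability
$\delta$ — converting to a stem cell *in place of* its division — or
divides into two daughters one division closer to senescence. Lineages
senesce after $g$ divisions (the *generational capacity*); senescent cells
are inert and leave the live count. Cell death is deliberately absent:
loss is by senescence only, matching the scope of the deterministic
model's stochastic counterpart.

Two semantic choices deserve justification because the underlying
description leaves them open:

* **EMT replaces the division.** Under this convention, until the first
  EMT event every trajectory coincides with the deterministic $\delta=0$
  trajectory, so the number of EMT opportunities is the deterministic
  division-event count $D$ and $P(\ge 1 \text{ EMT}) = 1-(1-\delta)^D$
  *exactly* (`expected_emt_fraction()`). This closed form reproduces the
  published occurrence and recurrence fractions to within binomial
  sampling error, which is the strongest available evidence for the
  convention.
* **EMT products are full stems**: they divide asymmetrically forever,
  emitting fresh full-capacity epithelial cells, starting the generation
  after their conversion. This is what makes the total-size law
  $T = 2^g(1+N_E)$ hold: each of the $1+N_E$ stem lineages sustains a live
  pedigree of exactly $2^g$ cells ($1 + 1 + 2 + \dots + 2^{g-1}$, the stem
  plus one full binary pedigree). "Tumor size" counts live cells only —
  the only accounting under which the plateau is time-invariant.

### Implementation and oracles

State is cohort counts (stems; live E by divisions completed; cumulative
senescent and EMT counts), and EMT draws are binomial per cohort — O(g)
per generation, so 1000 trials of the largest standard design (g = 18, 120
generations, ~260k live cells) run in about a second. Cohort-binomial
sampling is distributionally identical to per-cell Bernoulli draws; the
test suite verifies this against a naive per-cell reference implementation
(`run_trial_percell()`) at small g by comparing EMT-count distributions.

Each trial runs on its own RNG substream seeded deterministically from the
master seed, so batches are bit-reproducible and order-insensitive.

The standard experiments:

* **Occurrence** (`run_batch`): single stem, g = 18, 120 generations,
  1000 trials. Division events $D = 27{,}000{,}711$, so the oracle
  occurrence fraction is 23.7% at $\delta=10^{-8}$ and 2.66% at
  $\delta=10^{-9}$; at $\delta = 10^{-7}$ occurrence is near-certain. The
  empirical fractions match the oracle to within 3 binomial standard
  errors (so does the published 25% figure; the published 1.9% figure sits
  about 1.5 SE below the oracle — consistent at the 3-SE level, and the
  tests assert exactly that).
* **Recurrence** (`recurrence_experiment`): after a therapy that
  eliminated every stem cell, 10 fresh epithelial cells remain; the tumor
  recurs iff an EMT event fires before all lineages senesce ($g$
  generations, $D = 10(2^g-1)$ opportunities). At $\delta=10^{-7}$ the
  oracle gives 23.1% at g = 18, 12.3% (17), 6.3% (16), 3.2% (15), and
  under 1% for g < 14 — recurrence probability falls off steeply with
  generational capacity, but is far from negligible at the high end.

### What the generator does and does not emulate

The simulator realizes the idealized branching process the analysis is
about: synchronous generations, no cell death, no quiescence, EMT i.i.d.
per division, unlimited capacity restored by each EMT. Passing tests
demonstrate internal consistency with the closed-form oracles and the
published batch fractions under exactly these assumptions; they say
nothing about asynchronous division timing, microenvironmental
heterogeneity, stochastic death, or mutations altering g in real dormant
tumors — all explicitly out of scope.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from scratch
through the installed package: the g = 20 closed-form tumor size
(1,048,576 cells, cross-checked against a $\delta=0$ simulator run); the
single-stem occurrence percentages at $\delta = 10^{-8}, 10^{-9}$; and the
recurrence counts/percentages for g = 18...15 plus the sub-2% tail for
g < 14 (1000 trials each). Problem sizes match the published designs
throughout; the whole script runs in a few seconds.

## Known limitations

* The sensitivity magnitudes depend on the unpublished difference scheme;
  only the ranking is reproducible (and asserted).
* The analytic steady-state expressions assume $\alpha_1=\alpha_2$;
  sensitivity of the equilibrium to $\alpha_1$ is strongly nonlinear
  (denominator $\alpha_2+\alpha_3-\alpha_1$ near zero) and handled only
  through the time-domain finite difference.
* The deterministic and stochastic engines share biology but are not
  coupled: stochastic output does not feed back into the ODEs.
* No spatial structure, immune or vascular dormancy mechanisms, parameter
  fitting, or continuous-time (Gillespie) stochastic variant.
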