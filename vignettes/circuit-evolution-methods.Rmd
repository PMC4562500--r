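---
title: "Modeling the evolution of a positive-feedback stress-response circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of a positive-feedback stress-response circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfevolve)
```

## The system

`pfevolve` models the short-term laboratory evolution of budding yeast
carrying a synthetic two-gene positive-feedback (PF) module: the
tet-inducible activator rtTA drives both itself and a `yEGFP::zeoR`
fusion, so a single fluorescence readout `F` reports both the cost side
(rtTA squelching toxicity, engaged by the inducer doxycycline, `C` in
ug/ml) and the benefit side (ZeoR binds and inactivates the DNA-damaging
antibiotic zeocin, `Z` in mg/ml). Because the positive feedback is noisy
and bistable, an isogenic population splits into an Off mode (low `F`) and
an On mode (high `F`, two decades above Off on the log10 scale).
Environments are written `DxZy` (x ug/ml doxycycline, y mg/ml zeocin,
`Di` = 0.2 ug/ml).

The package provides four model layers plus the measurement emulators and
reconstruction/statistics utilities around them:

1. a cellular fitness landscape `gamma(F, C, Z)` (module `fitness_model`),
2. a two-state Off/On growth-and-switching model (`switching_dynamics`),
3. a lumped constant-population ODE model of ancestral plus
   knockout/tweaking/generic (K/T/G) mutant classes (`lumped_ode_model`),
4. a detailed stochastic allele-level simulator with serial-dilution
   bottlenecks (`evo_simulator`).

## The fitness model

A cell's division rate is
$$\gamma = \gamma_0\,\gamma_1(F, Z)\,\gamma_2(F, C),$$
with $\gamma_0 = 0.45\,\mathrm{h^{-1}}$ (a 92-minute doubling time,
typical for this strain background in synthetic drop-out medium).

**Zeocin survival** $\gamma_1 = 1/(1 + (Z_i/K_z)^{h_z})$ depends on the
steady-state *free internal* zeocin $Z_i$ of an uptake/sequestration
submodel: zeocin enters at $k_{in} Z$, is cleared at $k_{out} Z_i$, binds
free ZeoR ($k_{on}$, $k_{off}$), and the bound complex is cleared at
$k_{deg} B$, destroying the sequestered drug. The joint steady state
reduces to a quadratic in $Z_i$ whose unique non-negative root is used
(`bound_zeocin_steady_state()`). The clearance of the bound complex is
what makes protection rise with expression: without it the steady-state
free drug would be independent of `F` and expression could confer no
benefit, contradicting the circuit's defining trade-off.

**Squelching toxicity** $\gamma_2 = 1/(1 + (L/K_d)^{h_d})$ with
$L = F\,C/(C + K_C)$: rtTA level is taken proportional to `F` and loaded
by doxycycline with half-saturation $K_C$.

The exact published forms and fitted constants for this circuit are not
available in a transcribable form, so the defaults here were calibrated
once against the qualitative features all downstream predictions rest on,
and then frozen:

* monotone decreasing landscapes in D2Z0 and DiZ0, monotone increasing in
  D0Z2, and an interior fitness peak in DiZ2/D2Z2 (near
  $\log_{10} F \approx 2.7$);
* a D2 steady state in which most cells are On despite the toxicity cost;
* protection $\gamma_1$ saturating by mid-expression
  ($k_{deg} = 0.02\,\mathrm{h^{-1}}$), so that an intermediate-expression
  mutant is already almost fully protected — the property that lets
  fine-tuning mutations compete in peaked landscapes;
* doxycycline loading nearly saturated already at `Di`
  ($K_C = 0.15$ ug/ml), so both inducer levels engage toxicity while
  differing in switching drive.

All constants are plain arguments of `fitness_params()` and can be
refitted from data with `fit_fitness_params()` (growth-curve table plus
per-condition expression samples; two-stage weighted least squares with
eight fixed multi-starts, so results are deterministic).

## Switching dynamics

Population composition follows the linear system
$$\dot n_L = (g_L - r)\,n_L + f\,n_H,\qquad
  \dot n_H = r\,n_L + (g_H - f)\,n_H,$$
advanced exactly by a closed-form 2×2 matrix exponential
(`propagate_two_state()`), with a scaling-and-squaring fallback when the
eigenvalue gap is numerically degenerate. The Off-to-On rate is
doxycycline-driven, $r(C) = r_{max} C^{n}/(C^{n} + K^{n})$ with
$r_{max} = 0.15\,\mathrm{h^{-1}}$, $K = 0.51$ ug/ml, $n = 2$; memory loss
is slow and constant ($f = 0.005\,\mathrm{h^{-1}}$, a time constant of
about eight days). These values place the circuit where the study
conditions require: essentially no switching without inducer, a small
but non-zero On flux at `Di` (bimodal DiZ0 distributions and a slow DiZ0
takeover), and fast induction at `D2`. `fit_switching_rates()` infers
$(r_{max}, K, f)$ from On-fraction dose-response tables; with a single
timepoint only the $r/f$ balance is identifiable and the fit is flagged.

## The lumped ODE model

`simulate_lumped()` integrates replicator-with-mutation dynamics for the
ancestral fraction and three lumped mutant classes under constant
population size. Class fitnesses (`class_fitness()`): knockouts sit at
the null-expression end of the landscape; tweaking mutants at an
intermediate expression level (uniform in $\log_{10} F$ between the
modes); generic-resistance mutants uniformly between the ancestral level
and the zeocin-free ceiling. The deterministic default uses each class's
expected fitness (draws are available). The per-generation mutation rate
is converted to per-hour via the ancestral division rate
($\mu_h = \mu\,\gamma_{anc}/\ln 2$). Mutant classes are fed continuously
from the ancestral class and never mutate further — a single-step model
of the first evolutionary moves. Integration uses `deSolve` at
tolerances 1e-8/1e-10 with hourly output.

## The detailed simulator

`run_replicate()` tracks every mutant lineage explicitly over 20 days:
hourly drug-uptake and growth updates, Poisson mutation entry, and
resuspension to $10^6$ cells every 12 h by true multinomial sampling
(fresh medium resets external drug; internalized drug persists).

* **Hybrid determinism.** Lineages of at least $10^3$ cells advance by
  the exact two-state propagator; smaller lineages by tau-leap binomial
  division/death/switch events at $\Delta t = 0.05$ h, so establishment
  and loss of single-cell mutants are genuinely stochastic while bulk
  growth is exact.
* **Death versus arrest.** Zeocin kill is split: cells die at
  $d = k_{death}(1 - \gamma_1)$ and divide at $b = \gamma + d$, so net
  growth equals the fitness landscape exactly while small lineages
  experience a real birth-death process. $k_{death} = 0.01\,
  \mathrm{h^{-1}}$ encodes that zeocin primarily arrests the cell cycle;
  this matters for the pre-existing-mutation analysis, because division
  turnover of the arrested D0Z2 population is what supplies *new*
  competing mutants after the switch.
* **Mutation entry.** New mutants arise from ancestral divisions only, at
  $\mu_{-Z} = 10^{-6.2}$ (no zeocin) or $\mu_{+Z} = 10^{-5.4}$ (zeocin)
  per genome per generation, with type probabilities
  $P(K) = 0.225$, $P(T) = 0.025$, $P(G) = 0.75$
  (so $P(K) = 1 - P(G) - P(T)$). K mutants cannot switch On and enter the
  Off compartment (loss of the activator collapses expression within a
  generation). T mutants draw an rtTA-activity factor $u \sim U(0,1)$
  that scales both the switching rate and the On-state expression level
  (interpolated in $\log_{10}$ between the modes) — the same
  intermediate-expression reading the lumped model uses; without the
  expression effect a T mutant could never outcompete the ancestor in
  peaked landscapes. G mutants draw a resistance strength placing their
  zeocin survival uniformly between the ancestral value and the
  zeocin-free ceiling; T and G inherit the parent's Off/On state, so
  bistability can trap them On.
* **Pre-existing variant.** `run_preexisting_variant()` prepends 24 h of
  growth in D0Z0 — where every mutation type is selectively neutral by
  construction — at $\mu_{-Z}$, flags those alleles, then switches the
  environment and reports the fraction of day-20 mutant mass they carry.

Summary statistics per replicate: ancestral half-life (first crossing of
the daily ancestral-frequency series below 0.5, linearly interpolated,
`Inf` when not reached), alleles above 5 percent frequency at day 20, and
K/T/G mass fractions. `summarize_ensemble()` reports means and SEMs over
replicates (the package default, matching the study design, is
$N = 100$), with sentinel half-lives excluded from the mean and the
reached fraction reported alongside.

## Reconstruction and phenotyping

`reconstruct_timecourse()` implements the sequencing-era reconstruction
rules: per-day arithmetic mean when both Sanger and whole-genome calls
exist, the single method otherwise; linkage groups derived from
co-occurrence in clonal genotypes, with the linked-lineage estimate being
the mean of member whole-genome frequencies, then averaged with the
Sanger clone proportion; day-0 anchoring of mutant alleles at zero; the
ancestral series clamped at zero once it reaches zero (mutant knots are
left unnormalized); and second-order (quadratic) spline interpolation.
The spline is the interpolating quadratic spline with a linear first
segment as the closure condition; it passes through every knot, degrades
to a line for two knots, and overshoot is clipped to [0, 1] with the raw
curve kept alongside. Linkage groups larger than two generalize the
pairwise rule to the mean over all members.

`growth_rate_from_curve()` estimates exponential rates by log-linear
regression on the sliding window (at least four points) maximizing
$R^2$ — a documented choice, since no window rule is standard — and the
phenotyping metrics are the log10 fitness/fluorescence ratios with
two-sided Student's *t* tests (paired within condition, independent
between conditions) and Bonferroni correction (`compare_groups()`).

## What the synthetic data do and do not emulate

The generators (`gen_growth_curves()`, `gen_flow_sample()`,
`gen_sequencing_observations()`, `gen_dose_response()`) reproduce the
statistical structure the analysis assumes: exponential growth with 2
percent multiplicative lognormal noise over the 13-condition design
measured every 6 h for 72 h; bimodal log-normal fluorescence mixtures
(modes at $\log_{10} F$ = 1 and 3, sd 0.25, $10^4$ cells) with On weights
from the switching model; binomial whole-genome sequencing noise at
100× coverage and multinomial clone draws (20 isolates) that preserve
haplotype structure; and binomially sampled dose-response On fractions.
They are pure functions of their inputs and a seed. They do *not*
emulate plate-reader saturation or lag, autofluorescence background,
flow-cytometry gating artifacts, read-level sequencing error, or
non-genetic heritability — so green round-trip tests certify the
estimators against the model's own assumptions, not against every
artifact of real instruments.

## Numerical choices and problem sizes

Closed-form 2×2 exponentials (eigen form; series fallback below a 1e-12
eigenvalue-gap tolerance, with the mean growth factored out so
compositions stay finite even when counts overflow); the binding steady
state solved with the numerically stable quadratic root; bounded
Levenberg-Marquardt on log-transformed parameters with a fixed
multi-start grid in both fitters; hourly rate refresh in the simulator
(drug levels equilibrate within the first day and rates are cached once
stationary). The test suite runs the ensemble checks at the study's own
size ($N = 100$ replicates per condition, $10^6$-cell bottlenecks); unit
tests use reduced configurations (4 days, $10^5$ cells) where only the
mechanics, not the ensemble statistics, are under test.

## Known limitations

* The fitness and switching constants are calibrated stand-ins
  reproducing the study's qualitative structure, not transcriptions of
  the original fitted values; quantitative half-lives shift with them,
  which is why ensemble comparisons should be read at the tolerance of
  replicate SEMs.
* Mutant expression states are coarse-grained to the two modes (plus the
  T-interpolated On level); shifted-peak adaptation, which the study
  observed for one DiZ2 clone, is outside the allele model.
* No double mutants, no environment switching mid-run, and no
  mutation-rate plasticity beyond the zeocin/no-zeocin dichotomy.
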