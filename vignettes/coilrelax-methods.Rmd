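---
title: "Models and methods in coilrelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in coilrelax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilrelax)
```

`coilrelax` analyses the quantitative experiments used to characterise
lanthanide(III)-binding three-helix coiled coils developed as MRI
contrast agents: field-cycling relaxometry (NMRD), luminescence
titrations, challenge kinetics, circular dichroism, proteolytic
mapping, and hydration-shell statistics from simulation trajectories.
This vignette explains the models, their assumptions, the defaults, and
the limits of what the test suite demonstrates.

## The relaxivity model

The complexes studied here have no water molecule directly coordinated
to the Gd(III) (the inner-sphere hydration number is zero), so the
longitudinal relaxivity is modelled as the sum of just two terms,

$$r_1(\nu) = r_1^{SS}(\nu) + r_1^{OS}(\nu),$$

a *second-sphere* contribution from water molecules hydrogen-bonded
near the metal site and an *outer-sphere* contribution from freely
diffusing water.

**Second sphere.** `q_ss` water molecules sit at a Gd–H distance
`r_ss` (default 3.6 Å) and exchange with bulk water with mean residence
time `tau_M_ss`. Their motion is described by the Lipari–Szabo
model-free decomposition: slow global tumbling of the whole complex
(`tau_RG`) and fast local rotation of the bound water (`tau_RL`),
coupled by an order parameter $S^2 \in [0, 1]$ (0 = independent
motions, 1 = fully correlated). The spectral density is the
two-Lorentzian form

$$J(\omega) = \frac{S^2 \tau_g}{1 + \omega^2 \tau_g^2}
            + \frac{(1 - S^2)\,\tau_l}{1 + \omega^2 \tau_l^2},$$

where each effective correlation time combines rotation, chemical
exchange and electron relaxation,
$\tau_{g}^{-1} = \tau_{RG}^{-1} + \tau_M^{-1} + T_{ie}^{-1}$ (and
likewise for $\tau_l$ with $\tau_{RL}$). Following the standard SBM
convention, the $\omega_I$ spectral term pairs with $T_{1e}$ and the
$\omega_S$ term with $T_{2e}$; the bound-proton rate is the SBM dipolar
expression in $r_{ss}^{-6}$ and the per-mM relaxivity is the
mole-fraction form $(q_{ss}/55500)/(T_{1m} + \tau_M)$.

**Electron spin.** Gd(III) electron relaxation is modelled by the
transient zero-field-splitting mechanism with mean-square amplitude
$\Delta^2$ and modulation time $\tau_v$; both the $T_{1e}$ and the
companion $T_{2e}$ expression are implemented exactly as documented in
`electron_relaxation_rates()`, chosen for internal consistency over
empirical variants.

**Outer sphere.** The Freed model with closest approach `a` (default
4 Å) and relative diffusion coefficient `D` (default
2.3 × 10⁻¹⁰ m² s⁻¹) gives
$r_1^{OS} = C_{OS}/(aD)\,[3 J_F(\omega_I, \tau_D, T_{1e}) +
7 J_F(\omega_S, \tau_D, T_{2e})]$ with $\tau_D = a^2/D$. The constant
$C_{OS}$ carries one Avogadro factor because 1 mM is 1 mol m⁻³ in SI:
this normalisation makes a pure outer-sphere term with typical aqueous
parameters come out at a few mM⁻¹ s⁻¹, the magnitude every benchmark
agent shows. All constants are fixed in `physical_constants` so results
are bit-reproducible; internal arithmetic is SI, with MHz / Å / ns–ps /
mM⁻¹ s⁻¹ only at the user boundary.

The model is single-temperature (298 K metadata); no activation-energy
temperature dependence, no transverse ($r_2$) term, no Curie
contribution.

**Default electron-spin values.** The package defaults $S^2 = 0.5$,
$\Delta^2 = 10^{19}\,\mathrm{s}^{-2}$, $\tau_v = 20$ ps are stated
round-number conventions for self-consistent analyses, not fitted
values for any particular complex. Forward point predictions at a
single field depend strongly on this block, which is why the test suite
treats generate-then-refit consistency (which cancels the convention)
separately from absolute point predictions.

## NMRD fitting

`fit_nmrd()` minimises the inverse-variance-weighted residual sum of
squares over a user-declared free/fixed partition of
{`tau_RL`, `tau_M_ss`, `S2`, `delta2`, `tau_v`, `q_ss`}. Design
choices:

* positive parameters are optimised on log scale and $S^2$ on logit
  scale, which enforces bounds smoothly;
* the bounded PORT quasi-Newton routine (`nlminb`) runs with relative
  tolerance $10^{-10}$; the objective is multi-modal in
  $(\Delta^2, \tau_v)$, so 8 seeded log-uniform multi-starts are the
  default, and the result records how many starts agree within 0.1 %
  residual;
* uncertainties come from residual resampling on the fixed frequency
  grid (percentile bootstrap, 500 draws by default), appropriate
  because the design grid is fixed by the relaxometer;
* `scan_q_ss()` ranks integer hydration numbers by refitting with each
  candidate held fixed — the model-selection step that identifies how
  many second-sphere waters the dispersion supports.

Degenerate inputs are flagged rather than failing silently: a constant
profile yields an identifiability warning, and total non-convergence is
reported on the result object.

## Binding analysis

Two deliberately separate routes mirror the two experiments:

* **Direct titrations** are fitted with the Hill equation
  ($signal = b + A\,M^n/(K_d^n + M^n)$) by bounded least squares. The
  Hill $n$ from this route is never reused in the competition model.
* **Competition titrations** assume strict 1:1 binding of the metal to
  the peptide site (one Ln per three-helix bundle; concentrations are
  per-site) and to the competitor. `speciation_1to1()` solves the
  two-equilibrium mass balance for free metal by bracketed root finding
  on $[0, M_T]$ — the balance function is strictly monotone, so the
  bracket is guaranteed — with a Newton polish to meet a $10^{-10}$
  relative mass-conservation contract. Ligand depletion is always
  modelled; there is no free≈total shortcut, because the regime of
  interest is sub-nanomolar.

Because the predicted signal $b + s_P[MP] + s_E[ME]$ is linear in its
coefficients, `competition_fit()` profiles them out exactly by linear
least squares at each candidate $\log K_a$ and minimises the profiled
residual in one dimension; the uncertainty interval is read off the 1-D
residual profile. Both emission conventions are supported (competitor
complex emissive or dark); the default keeps $s_E > 0$. The conditional
metal–competitor constant is experiment metadata: the documented
default `egta_logKa_default = 14.0` (pH 7.5, I = 0.1 M) should be
overridden with the user's value, and in self-consistent
generate-then-fit analyses it cancels exactly — a property the test
suite verifies over three decades.

## Kinetics, helicity, digestion

The **ratio index** is the time for a challenge signal to fall to 80 %
of its initial value. The series is normalised internally, divided by a
matched control channel when one is present, and the crossing is
linearly interpolated between samples (the simplest defensible rule; no
smoothing). Never-crossing series are reported as censored at the last
time point rather than extrapolated.

**Helicity** converts mean residue ellipticity at 222 nm to fraction
folded with the chain-length-corrected convention
$\theta_{helix} = -40000(1 - 2.5/n)$, $\theta_{coil} = +640$
deg cm² dmol⁻¹. These constants are a documented default (alternative
conventions differ by a few percent) and are configurable; out-of-range
fractions are clipped and flagged.

**Tryptic digestion** cleaves C-terminal to Lys/Arg, skips sites
followed by Pro, and treats isopeptide cross-linked Lys side chains as
cleavage-resistant, which joins the two heptads flanking the
cross-link into a single fragment. Partial digestion is available via
`max_missed_cleavages`. The bundled default sequence
(`mb12_sequence()`) is reconstructed from the heptad architecture and
the observed digestion products and is documented as a synthetic
default.

## Hydration-shell statistics

`hydration_rdf()`, `shell_occupancy()` and `residence_lifetimes()`
post-process labelled trajectories around a single Gd centre. The shell
default $[3.0, 4.5)$ Å brackets the ≈3.6 Å Gd–H(water) second-shell
peak. A water counts as in-shell when *any* of its hydrogen atoms is in
range (per-molecule counting, keyed by the shared per-molecule label).
Lifetimes are maximal runs of consecutive in-shell frames; a single
out-of-shell frame ends a run (no grace period — the simplest reading
of "residence"), and runs touching either trajectory end are reported
as censored rather than mixed into the mean. RDF normalisation uses the
mean target density inside the analysis sphere, so a uniform gas gives
$g = 1$; periodic boxes use orthorhombic minimum image and restrict
`r_max` to half the shortest box length.

## Synthetic data: what it emulates and what it does not

The generators produce data with the statistical structure each
analysis assumes, under a single seeded RNG stream per call:

* `gen_nmrd()` — the forward dispersion plus optional multiplicative
  (relative) or additive noise; noise-free output is bitwise equal to
  the forward model. Default grid: 30 log-spaced points, 0.01–70 MHz.
* `gen_competition_titration()` — exact two-equilibrium speciation with
  a linear emission model; 3.3 µM sites and equimolar competitor
  co-delivered with the metal reproduce the study design.
* `gen_decay()` — first-order emission loss with optional flat control.
* `gen_trajectory()` — tethered waters whose shell membership is a
  symmetric telegraph process (per-frame switching probability
  $dt/\tau_{res}$, i.e. geometric dwells with mean $\tau_{res}$), plus
  ideal-gas bulk waters redrawn every frame. Defaults: 2 tethered
  waters at 3.6 Å, $\tau_{res}$ = 4 ns, 0.1 ns frames.

These generators deliberately do **not** emulate instrument baselines
and drift, correlated residuals, photobleaching, force-field artefacts,
concerted multi-water exchange, or anisotropic tumbling. Passing
round-trip tests therefore demonstrates correctness of the estimators
under their stated models, not robustness to every real-data
pathology.

## Problem sizes and numerical conventions

The shipped test suite uses problem sizes chosen to exercise every
statistical claim while staying quick on a single CPU: 100 random
models for the forward-model oracle equivalence (relative agreement
$< 10^{-8}$), 25 random generate-then-fit recoveries, a 40-replicate /
200-resample bootstrap coverage study (coverage ≥ 80 % at 90 %
nominal), a 10⁴-target × 100-frame ideal-gas RDF check (every bin
within 3 standard errors of 1), and a 500 ns telegraph trajectory for
the lifetime estimator (mean within 15 % of the configured 4 ns).
Speciation conserves mass to $10^{-10}$ relative everywhere.

Known limitations: absolute single-field relaxivity predictions are
only as good as the electron-spin block supplied (see above); the
competition model assumes a single conditional competitor constant
(pH-dependence is absorbed, not modelled); lifetime statistics exclude
censored runs, which slightly underweights long dwells on short
trajectories; and the Hill and competition routes are intentionally not
unified, so apparent cooperativity never leaks into affinity
inference.
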