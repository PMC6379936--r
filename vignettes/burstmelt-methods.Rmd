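---
title: "Models and methods: burst kinetics, thermal denaturation, and thermolability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: burst kinetics, thermal denaturation, and thermolability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstmelt)
```

`burstmelt` analyses two classes of measurement made on DNA glycosylases such
as human 8-oxoguanine glycosylase-1 (hOGG1): pre-steady-state excision assays,
in which a labelled 8oxoG:C duplex is cleaved by excess enzyme and the product
is quantified from quenched aliquots resolved on a gel; and circular-dichroism
(CD) thermal denaturations, in which the 222 nm ellipticity tracks the loss of
helical structure as temperature rises. A third layer quantifies
*thermolability*: how much excision activity survives a prolonged
pre-incubation at physiological temperature, and how much of the loss is
prevented when undamaged competitor DNA is bound. Because raw gel and CD data
of this kind are rarely deposited, the package ships a first-class synthetic
data generator so that every estimator can be validated by parameter
recovery: simulate from known ground truth, fit, and compare.

## The burst model

Under single-turnover-dominated conditions (enzyme in excess over substrate —
100 nM enzyme against a 20 nM duplex in the standard design), product
formation is biphasic:

$$[P](t) = A_0\,\bigl(1 - e^{-k_1 t}\bigr) + k_2\,t .$$

The exponential *burst* reflects the first round of catalysis by all active,
substrate-engaged enzyme: its amplitude $A_0$ (nM) counts active enzyme, and
$k_1$ (min$^{-1}$) is the rate constant of the chemistry-limited first
turnover. The linear phase $k_2$ (nM min$^{-1}$) reports the much slower
steady state, limited by release of the tightly bound product. The package
treats $k_2$ purely descriptively (no mechanistic decomposition into release
vs rebinding). The 1/10 labelled:unlabelled substrate mixing used with
radiolabelled duplexes is treated as transparent — the labelled fraction is
an unbiased sample of the reaction — and concentrations are reported on the
20 nM labelled-substrate scale.

`fit_burst()` minimizes the residual sum of squares with a bounded
trust-region Levenberg–Marquardt solver (`minpack.lm::nls.lm`) and the
analytic Jacobian of the model. Bounds ($A_0 \in [0, S_0]$,
$k_1 \in (0, 100]$ min$^{-1}$, $k_2 \in [0, 10]$ nM min$^{-1}$) prevent the
two phases from exchanging roles, which is the only failure mode this smooth
three-parameter model has in practice. Starting values are deterministic:
$k_2$ from the slope of the last third of the points, $A_0$ from the late
points after removing that line, $k_1$ from $\ln 2 / t_{1/2}$ of the
half-amplitude time; three fixed fallback starts guard against a degenerate
half-time estimate and the best of all converged starts is kept, so a fit is
reproducible run-to-run with no random restarts.

Two sources of uncertainty are reported. Standard errors come from the
Jacobian-based covariance scaled by residual variance; optionally a seeded
residual-resampling bootstrap (`n_boot`) adds percentile intervals, a more
honest statement at the small point counts typical of gel assays. Published
tables of this kind rarely state whether their ± values are fit standard
errors or across-replicate spreads, so the package exposes both and leaves
the choice to the reader.

Fitting a burst to burstless data would silently return nonsense, so
`fit_burst()` (and `compare_models()`) run an extra-sum-of-squares F-test
against the one-parameter line through the origin at $\alpha = 0.01$. When
the line wins, the result is reported as `linear_only` with $A_0$ and $k_1$
absent (`NA`), not as zeros with spurious standard errors. By default the
replicate-averaged curve is fitted — the conventional treatment of
triplicated assays — with per-replicate fitting available by splitting
replicates first (`split_replicates()`).

Comparative activity is summarized by `relative_activity()`, the ratio of
burst-phase rate constants in percent with first-order error propagation.
With the published wild-type and R154H rate constants this is
$100 \times 0.23/1.4 \approx 16\%$.

## Two-state thermal denaturation

CD melts are described by the minimal two-state equilibrium with
temperature-independent van't Hoff enthalpy ($\Delta C_p = 0$):

$$K(T) = \exp\!\left[-\frac{\Delta H_{vH}}{R}\left(\frac{1}{T} -
\frac{1}{T_m}\right)\right], \qquad f_{\text{folded}} = \frac{1}{1+K},$$

with absolute temperatures and $R = 8.314$ J mol$^{-1}$ K$^{-1}$. A single
melt cannot constrain $\Delta C_p$, and the reported quantity of interest is
$T_m$ alone, so the minimal model is the right one. `fit_melt()` fits six
parameters — $T_m$, $\Delta H_{vH}$ and two linear baselines — to the *raw*
ellipticities:

$$\theta(T) = f_{\text{folded}}\,(a_N + b_N T) + (1 - f_{\text{folded}})\,(a_D + b_D T).$$

The default generator/fit enthalpy of 200 kJ mol$^{-1}$ is typical
small-globular-protein cooperativity; it is configurable, and on real data it
is estimated, not assumed. Equilibrium (reversible) unfolding is assumed
throughout; the activity data suggest denaturation is at least partly
irreversible at long times, so fitted $\Delta H_{vH}$ values should be read
as apparent. This is a known limitation of fitting melts recorded on a
monotone ramp.

A second, non-parametric estimator, `tm_by_derivative()`, takes the
temperature of maximum $|d\theta/dT|$ after Savitzky–Golay smoothing
(default window 11 points, order 3 — a documented replacement for opaque
instrument-software smoothing; the parametric fit always uses raw data),
refined by quadratic interpolation around the discrete maximum. The peak is
searched only where the smoothing window is two-sided, because the filter's
one-sided endpoint transients amplify noise, and a prominence rule (peak at
least twice the median $|d\theta/dT|$) rejects monotone, transition-free
signals. The derivative method carries a small systematic bias: sloping
baselines pull the apparent peak, and even with flat baselines the $1/T^2$
prefactor in $df/dT$ puts the true derivative maximum about 0.2 °C below the
thermodynamic midpoint at $\Delta H_{vH} = 200$ kJ mol$^{-1}$. It is
therefore the initializer and cross-check (reported as `tm_derivative` in
every fit), never the primary estimate.

Replicates are handled by `average_melts()`: each replicate is fitted
independently, the per-replicate $T_m$ values are summarized as mean ±
sample SD, and the baseline-normalized fraction-denatured curves are averaged
on a common grid. Normalized curves are expected in $[-0.05, 1.05]$;
excursions beyond that are flagged, not clipped.

## Thermolability and DNA protection

Retention after thermal challenge is the ratio of a scalar activity metric
between challenged (37 °C, 90 min pre-incubation) and control (4 °C, taken
as lossless by convention) conditions. The default metric is the burst
amplitude $A_0$: denaturation removes active molecules, which scales the
amplitude of the first turnover, while $k_1$ — a property of the molecules
that remain folded — is unchanged. This choice is testable on the generator
(which implements exactly that scaling) and is the package default. When a
condition is so inactive that no burst can be fitted, *both* members of the
pair fall back to the mean product at the latest common time point, keeping
the ratio like-for-like; the `metric` field of every result records which
was used.

Uncertainty is bootstrap-based: each replicate is reduced to its metric once,
and replicates are resampled with replacement (default 2000 draws, seeded,
95% percentile intervals). `protection_effect()` compares retention with
versus without competitor DNA as $\Delta = r_{\text{DNA}} - r_{\text{no DNA}}$
with a joint bootstrap over all four replicate groups, calling the effect
protective when the interval excludes zero from above. The underlying study
made this comparison visually; the bootstrap is this package's quantification
of it, chosen over a parametric test because three replicates per cell do not
support distributional assumptions. `thermolability_panel()` assembles the
full variant × DNA-state table, reporting missing cells explicitly.

## The synthetic-data generator

`hogg1_variant_specs()` encodes the five study proteins with the published
burst parameters and melting temperatures as generative ground truth.
Around that fixed truth, the generator adds:

* **Time courses** (`gen_time_course()`): the burst curve plus Gaussian noise,
  SD 0.5 nM by default, truncated to $[0, 20]$ nM. The noise level was chosen
  once so that Monte-Carlo parameter scatter is comparable to the ± values in
  the published table; the sampling grid (0.5–30 min, dense early) resolves
  the burst of the fastest variant while still sampling the linear phase.
* **Gel lanes** (`gen_gel_lanes()` / `quantify_lanes()`): band intensities
  splitting a lane total by cleaved fraction, with multiplicative log-normal
  loading noise shared by both bands of a lane. Ratio-based quantification
  cancels the shared factor exactly — which is precisely why densitometry is
  done by ratio — so the pair is an exact inverse at any loading noise.
* **Melts** (`gen_melt()`): two-state curves on the 10–95 °C instrument grid
  (0.5 °C steps) with a strongly negative native 222 nm baseline
  ($-12000 + 20\,T$) relaxing to a shallower denatured baseline
  ($-4000 + 5\,T$), noise 2% of the transition amplitude.
* **Pre-incubation** (`gen_preincubated_time_course()`): first-order
  irreversible loss $f = \exp[-k_{den}(T)\,t]$ with
  $k_{den}(T) = k_{den,ref}\,e^{\alpha (T - T_m)}$, and competitor DNA
  multiplying $k_{den}$ by `dna_protection` (fully-bound limit at 1:1
  stoichiometry; no binding constant is modelled). This loss model is the
  generator's own invention — the simplest mechanism reproducing the
  qualitative pattern of the activity data. The defaults
  ($k_{den,ref} = 0.025$ min$^{-1}$, $\alpha = 0.7$ °C$^{-1}$,
  `dna_protection` $= 0.02$) were set once so that 90 min at 37 °C removes
  ≈95% of the activity of the destabilized R46Q ($T_m$ 0.4 °C below the
  challenge) but under 10% of wild-type, and DNA binding removes almost all
  of the loss. Survival scales $A_0$ and $k_2$, leaving $k_1$ untouched.
  R46Q is given the same noise as the other variants by default, although
  larger variance for it is plausible in practice; `noise_sd` is per-call
  configurable.
* **Mechanism** (`simulate_mechanism()`): the minimal scheme
  $E + S \rightleftharpoons ES \rightarrow EP \rightarrow E + P$ integrated
  with `deSolve`, observable $[EP] + [P]$ because an alkali quench reveals
  cleaved DNA whether or not it has been released. In the fast-binding,
  slow-release regime this reduces to the burst equation, giving an
  independent mechanistic oracle for the closed form.

`gen_study()` drives everything from one seed (kinetics triplicates, melt
triplicates, the 2 × 2 pre-incubation panel for all five variants) and is
byte-deterministic: the same seed yields identical CSV output.

What the generator deliberately does **not** emulate: detection-chemistry
differences between radiolabel and fluorophore readouts (both are treated as
calibrated product measurements), radiolabel decay, electrophoretic mobility
or imaging artefacts, scan-rate effects on the melt (the equilibrium model
ignores the 1 °C min$^{-1}$ ramp), and any secondary-structure
deconvolution of the CD spectrum beyond the 222 nm channel. Passing recovery
tests on this generator therefore demonstrates estimator correctness under
the stated noise model, not robustness to every artefact of real gels and
spectropolarimeters.

## Numerical choices and edge cases

* Times in minutes, concentrations in nM, temperatures in °C at the
  interface with Kelvin (offset 273.15) inside the thermodynamics.
* Solver tolerances are set to machine-level (`ftol = ptol = 1e-14`) —
  the problems are tiny, so there is no cost — which is what lets noiseless
  recovery reach $10^{-4}$ relative error and better.
* Model-comparison degeneracy: when the line already explains the data to
  numerical precision (RSS below $n\,(10^{-7}\,\mathrm{scale})^2$), the
  F-statistic is meaningless ($0/0$) and parsimony decides: `linear_only`.
  Constant-zero data land here with $k_2 = 0$.
* `fit_melt()` requires ≥ 20 points and errors with class `no_transition`
  when the derivative initializer finds no prominent interior peak or the
  fitted midpoint lands within 0.5 °C of the range edge.
* Near-singular normal equations fall back to an SVD pseudo-inverse for the
  covariance; eigenvalues are floored at zero before taking standard errors.
* Bootstrap intervals are widened, if necessary, to bracket the point
  estimate, so `ci_low <= retention <= ci_high` holds by construction.

## Problem sizes used in the validation suite

The shipped tests validate with 200-draw Monte-Carlo recovery for the
kinetics (triplicate-averaged fits, the published analysis design), 100-draw
recovery for noisy melts, 20 random datasets against a $30^3$ grid-search
oracle for the least-squares objective, and 2000-draw bootstraps for the
thermolability panel — sizes at which the whole suite runs in seconds while
standard errors of the checked means are several times tighter than the
tolerances being asserted.

## Worked example

```{r example, eval = FALSE}
study <- gen_study(seed = 1)

# kinetics: Table-shaped summary of one variant
fit <- fit_burst(aggregate_replicates(study$time_courses[1:3]))
print(fit)

# thermal: per-variant Tm
av <- average_melts(study$melts$R46Q)
print(av)

# thermolability: full panel
panel <- thermolability_panel(study$preincubation, seed = 2)
print(panel)
```
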