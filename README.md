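# burstmelt

Burst-phase excision kinetics and thermal-stability analysis for DNA
glycosylases.

DNA glycosylases such as human 8-oxoguanine glycosylase-1 (hOGG1) excise the
mutagenic oxidized base 8oxoG from duplex DNA, initiating base excision
repair. Two biochemical assays dominate their characterization: the
pre-steady-state excision assay, where excess enzyme cleaves a labelled
8oxoG:C duplex and quenched aliquots are quantified by gel densitometry, and
CD-monitored thermal denaturation, where the 222 nm ellipticity reports
unfolding as temperature rises. `burstmelt` is for biochemists analysing
such data — variant panels, stability screens, thermolability experiments —
and for anyone who wants the estimators validated by parameter recovery on
simulated data rather than taken on faith.

## Models

Product formation under enzyme excess is biphasic:

    [P](t) = A0 (1 - exp(-k1 t)) + k2 t

with burst amplitude `A0` (nM; counts active, substrate-engaged enzyme),
burst-phase rate constant `k1` (min⁻¹; the chemistry-limited first turnover)
and linear steady-state rate `k2` (nM min⁻¹; limited by product release).
`fit_burst()` estimates the triple by bounded trust-region least squares with
an analytic Jacobian, guards against burstless data with an
extra-sum-of-squares F-test, and reports covariance-based and optional
bootstrap uncertainty.

Thermal denaturation follows the two-state van't Hoff model (ΔCp = 0):

    K(T) = exp[-(ΔH_vH/R) (1/T - 1/Tm)],   f_folded = 1/(1 + K)

and `fit_melt()` fits Tm, ΔH_vH and two linear baselines to the raw
ellipticities, with a Savitzky–Golay derivative method as initializer and
cross-check.

Thermolability — activity surviving a 90-min pre-incubation at 37 °C versus
the 4 °C control, with or without stoichiometric undamaged competitor DNA —
is quantified as a retention ratio of burst amplitudes with seeded bootstrap
intervals, and the DNA-protection effect as the paired difference of
retentions.

A synthetic-data module generates everything the pipeline consumes from
known ground truth (time courses, gel-lane densitometry, melts,
pre-incubation panels, and a mechanistic `E + S ⇌ ES → EP → E + P` ODE
oracle), so every estimator is exercised by simulate–fit–recover tests.

## Worked example

```r
library(burstmelt)

study <- gen_study(seed = 1)   # five variants, full synthetic study

# kinetics: fit the replicate-averaged wild-type time course
fit_burst(aggregate_replicates(study$time_courses[1:3]))
#> Burst fit: WT / standard  [model: burst, n = 9]
#>   A0 = 14.1 +/- 0.16 nM   k1 = 1.48 +/- 0.063 min^-1   k2 = 0.1 +/- 0.01 nM min^-1
#>   RSS = 0.3528
```

The generating truth for this variant is A0 = 14.2 nM, k1 = 1.4 min⁻¹,
k2 = 0.09 nM min⁻¹; the fit recovers it within its reported uncertainty from
triplicates at 0.5 nM noise.

```r
# thermal: per-replicate melt fits summarized per variant
average_melts(study$melts$R46Q)
#> Melt average: R46Q, 3 replicate(s), Tm = 36.87 +/- 0.16 degC

# thermolability: retention after the 37 degC challenge, with/without DNA
panel <- thermolability_panel(study$preincubation, seed = 2)
panel$table[panel$table$variant == "R46Q", c("dna", "retention", "ci_low", "ci_high")]
#>     dna retention ci_low ci_high
#>   FALSE     0.080  0.049   0.127
#>    TRUE     0.979  0.963   0.996
panel$protection[panel$protection$variant == "R46Q", ]
#>      variant delta ci_low ci_high protective
#> R46Q    R46Q 0.899  0.855   0.939       TRUE
```

The destabilized R46Q variant (Tm ≈ 36.6 °C, barely below the 37 °C
challenge) retains ~8% of its activity after the challenge, but ~98% when
competitor DNA is bound — the bootstrap calls the protection effect real
(Δ ≈ 0.90, interval well above zero), while a stable variant shows nothing
to protect.

A command-line wrapper covering the same pipeline is installed at
`inst/scripts/burstmelt` (subcommands `simulate`, `fit-kinetics`,
`fit-melt`, `thermolability`, `report`).

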