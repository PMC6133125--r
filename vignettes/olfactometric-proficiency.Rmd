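---
title: "Evaluating olfactometric proficiency tests: consensus thresholds, z-scores and reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating olfactometric proficiency tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfpt)
```

## The measurement problem

Dynamic olfactometry determines the odor concentration of a gas sample, in
European odour units per cubic metre (ou~E~/m^3^), by presenting a human
panel with increasing dilutions until the odor is no longer detected. In an
inter-laboratory proficiency test, several accredited laboratories sample
the same stack gas, into which an odorant has been dosed at a known mass
concentration $c_{ik}$ (µg/m^3^), and each reports measured odor
concentrations $x_{ik}$. Because the response is a human perception, the
spread of results is large, and quantifying that spread — per laboratory and
across laboratories — is the point of the exercise.

The link between the two concentration scales is the odor threshold
$c_{0,k}$ of component $k$: the mass concentration that corresponds to
1 ou~E~/m^3^. Given a threshold, each dosage has an *assigned value*

$$X_{ik} = \frac{c_{ik}}{c_{0,k}} \;\mathrm{ou_E/m^3},$$

the odor concentration a perfectly accurate laboratory would report. For
n-butanol the threshold is fixed by EN 13725 at 123 µg/m^3^; for every other
odorant it has to be estimated from the participants' own results.

All statistics in this package operate on the log~10~ scale. Log
transformation makes olfactometric results near-symmetric and close enough
to normal for standard interpretation, and it turns multiplicative
deviations (the natural error structure of a dilution method) into additive
ones. Linear-scale values are derived on output only. Concentrations are
assumed to be expressed at olfactometric normal conditions (1013.25 mbar,
293.15 K); the package performs no temperature or pressure conversion.

## Robust consensus thresholds

Every measurement implies a threshold estimate
$\log_{10}(c_{ik}/x_{ik})$ — the mass concentration per odour unit that
the laboratory effectively observed (`implied_thresholds()`). Pooling these
across all participants and tests gives the raw material for a consensus
value. Because gross outliers are common, the location and scale are
estimated by the iteratively winsorized procedure of ISO 13528
(Algorithm A), implemented in `robust_mean_sd()`:

1. start from $m^* = \text{median}$, $s^* = 1.483 \cdot \text{MAD}$;
2. clamp all values to $m^* \pm 1.5 s^*$;
3. update $m^*$ to the mean and $s^*$ to $1.134$ times the standard
   deviation of the clamped values;
4. repeat until both estimates change by less than $10^{-4}$ in relative
   terms (at most 100 iterations).

The constants 1.483 and 1.134 make the estimators consistent for normal
data (they undo the bias of the MAD and of winsorizing at $1.5\sigma$).
Note a consequence: on data where nothing reaches the clamp, $m^*$ equals
the plain mean exactly, but $s^*$ equals $1.134$ times the classical
standard deviation — the factor assumes winsorization has removed
variance. Agreement with classical estimates therefore holds exactly for
the mean and only approximately (at the few-percent level) for the scale.

Degenerate inputs are handled explicitly: identical values return
$(v, 0)$ without iterating; a zero MAD with non-identical values (more
than half the sample at one point) seeds the first iteration with the
classical standard deviation instead.

The standard uncertainty of the consensus value follows the ISO 13528
convention $u = 1.25\, s^*/\sqrt{n}$. What $n$ should count is genuinely
open when all results of all tests are pooled: the package implements both
`n_basis = "measurements"` (every individual result; the convention
matching a pooled n-of-456 analysis) and `n_basis = "participant_means"`
(one unit per participant–test combination). Since individual results of
one laboratory share that laboratory's bias, the per-measurement basis
understates the uncertainty of the consensus mean whenever between-lab
variance dominates; Monte-Carlo calibration against the generator (below)
shows its $k=2$ interval covering the truth in only roughly 85–90% of
studies, while the per-participant basis is mildly conservative (≥ 95%).
The calibration tests therefore use `"participant_means"`; the default for
reporting remains `"measurements"` for continuity with the pooled
convention, and the choice is always explicit in the output (`n_basis`
column).

On the linear scale the $k=2$ interval
$[10^{m^*-2u},\, 10^{m^*+2u}]$ is geometrically symmetric, hence skewed
upward in absolute terms; the relative standard uncertainty of the
threshold is accordingly defined from the upper limit,
$u(c_{0,k}) = (c_{0,\text{high}}/c_0 - 1)/2$. An alternative log-scale
convention $u = 10^{u_{\log}} - 1$ is available behind the
`u_convention` flag of `score_study()`; the two differ only in the second
order but the choice is documented in every criteria table.

## Proficiency scoring

Each measurement receives a z-score on the log scale,

$$z_{ik} = \frac{1}{\sigma_k}\log_{10}\frac{x_{ik}}{X_{ik}},$$

with $\sigma_k$ the criterion for proficiency assessment. The base
criterion is $\sigma_k = 0.10$ log~10~ units, under which $|z| < 3$
corresponds to recoveries strictly inside $10^{\pm 0.3}$, i.e. roughly
50–200% of the assigned value (the glossed band is exact only up to
rounding: $\log_{10} 2 / 0.10 = 3.0103$, so a recovery of exactly 200%
scores just above 3; the strict rule is kept).

A z-score is only actionable if the assigned value itself is accurate. Its
relative uncertainty combines the dosing uncertainty and the threshold
uncertainty in quadrature, $u_k = \sqrt{u(c_k)^2 + u(c_{0,k})^2}$ (here
$u(c_k) = 1.01\%$ for all components, a property of the dosing rig). The
criterion is then floored at $(1/0.3)\log_{10}(1+u_k)$: if the floor
exceeds the base criterion the criterion is *adapted* (widened) so that
assigned-value uncertainty can never dominate a verdict
(`adapt_sigma()`).

Verdicts follow the replicate structure: the mean of the three absolute
z-scores per participant and component must be strictly below 3
("passed"); a mean of exactly 3 fails; a participant passes overall only
if every component passed (`verdicts()`). For n-butanol the fixed
EN 13725 threshold (123 µg/m^3^) is used for assigned values even though
the consensus estimate differs — configurable via `component_config()`
and the `use_fixed` switch. `reference_correlation()` correlates
participants' mean component scores with their n-butanol scores, the
standard probe of whether the reference substance predicts performance on
other odorants.

## Recoveries and reproducibility

Descriptively, the recovery $x_{ik}/X_{ik}$ of every single measurement
(`recoveries()`), its per-dosage summaries (mean assigned and measured
concentration, relative standard deviation; `recovery_summary()`) and the
share of recoveries within 50–200% (`within_margin_fraction()`, bounds
inclusive) locate each laboratory and component. Quartiles of log
recoveries use the linear-interpolation (type 7) quantile definition.

The formal reproducibility analysis is a one-way ISO 5725-2 decomposition
of the log~10~ implied thresholds with the laboratory — the
(test, participant) combination — as grouping factor
(`estimate_variance_components()`):

* $s_w^2$: pooled within-laboratory mean square (repeatability, including
  the sampling step);
* $s_L^2 = \max\!\big(0, (MS_\text{between} - s_w^2)/\bar n\big)$ with the
  unbalanced-design effective replicate count
  $\bar n = \big(\sum n_i - \sum n_i^2 / \sum n_i\big)/(p-1)$;
* $s_R^2 = s_w^2 + s_L^2$: reproducibility variance.

Negative between-laboratory estimates are truncated at zero (the usual
convention for method-of-moments variance components). Data from all tests
in which a component was dosed are pooled into a single decomposition; a
per-test decomposition followed by pooling would weight tests differently
and is not implemented.

On the odor-level scale (decibel, $10 \log_{10}$ of a concentration
ratio) the expanded $k=2$ uncertainty of a single measurement is
$U_{0.95} = 20\, s_R$ dB, and on the linear scale the relative interval
$[100 \cdot 10^{-2 s_R},\, 100 \cdot 10^{2 s_R}]$ percent — reciprocal
bounds by construction (`expanded_uncertainty()`). The EN 13725
repeatability limit $s_r \le 0.1721$ corresponds to 3.44 dB, i.e. about
45–220%. The 95% bound on the ratio of two single measurements under
reproducibility conditions is $10^{2\sqrt{2}\, s_R}$
(`reproducibility_factor()`). For reporting, dB values are rounded to two
decimals and percent bounds to the nearest integer; nothing is rounded
internally.

## The synthetic study generator

Raw participant data from real proficiency-test campaigns are rarely
publishable, so the package ships a generator whose draws have exactly the
structure the evaluation assumes (`generate_study()`):

* per participant, one standardized laboratory effect, scaled by the
  component's $s_L$ (a single shared bias per participant is the simplest
  structure consistent with the per-participant clustering seen in such
  campaigns; independent per-component biases are available via
  `bias_per_component`);
* per measurement, a dosed mass concentration drifting uniformly within
  ±2% of nominal (dosing is instrument-controlled and continuously
  surveilled, hence bounded rather than Gaussian), and a log-normal
  replicate error with scale $s_w$;
* one root seed spawning an independent substream per
  (test, participant), so adding tests or participants never perturbs the
  other draws.

`default_study_config()` reproduces the layout of a six-test
stack-emission campaign: 38 participants (9/7/5/4/6/7 per test), four
components per test, three replicates — 456 measurements; n-butanol and
tetrahydrothiophene dosed in all six tests, the two mixtures in four, amyl
acetate and limonene in two. Its noise defaults are the reproducibility
magnitudes observed for these odorants ($s_w$ 0.060–0.094, $s_L$
0.198–0.350 log~10~ units) and its nominal dosings are the per-test
assigned concentrations times the component thresholds.

What the generator does **not** emulate: individual panelists, dilution
steps and YES/NO response curves (it works at the level of reported odor
concentrations); heavy-tailed outliers or transcription blunders (errors
are log-normal, so robust and classical estimates nearly coincide on its
output — passing calibration tests shows correctness of the chain under
the assumed model, not robustness to real-world contamination, which the
dedicated outlier tests cover separately); correlation between a
participant's replicates beyond $s_w$; and any drift of laboratory
performance over time.

## Calibration and test sizes

The test suite verifies the chain at three levels. Exact oracles: the
variance decomposition is compared against a brute-force two-loop ANOVA on
an exhaustive grid of small balanced designs (2–5 labs × 2–4 replicates,
agreement to $10^{-10}$) and on random unbalanced ones; the winsorized
consensus is compared against an independent step-by-step transcription of
the iteration on fixed vectors (to $10^{-6}$). Monte-Carlo calibration:
200 seeded studies of 40 laboratories × 3 replicates at $s_w = 0.07$,
$s_L = 0.20$ recover both scales within three Monte-Carlo standard errors,
and across 200 seeded six-test studies the consensus $k=2$ interval
(per-participant basis) covers the generator truth in at least 90% of runs
per component at nominal 95%. These sizes keep the whole suite around half
a minute on a single core while leaving the Monte-Carlo standard errors
well below the effects being checked. Closed-form spot checks: the
EN 13725 limit and the dB/percent conversions of the reproducibility
table.

## Limitations

* The consensus procedure assumes one common threshold per component
  across tests; a component whose perceived threshold drifts between
  campaigns would inflate $s_L$ rather than show up as a trend.
* The uncertainty basis for the pooled consensus ($n$ = measurements vs
  participants) is a convention, not an estimate; both are reported rather
  than adjudicated.
* The 50–200% gloss of the $|z|<3$ band and the integer-percent rounding
  of interval bounds are presentation conventions; tests pin the unrounded
  values.
* With laboratories nested in tests and anonymized per test, a laboratory
  participating in several tests is treated as distinct laboratories; if
  stable identities were known, a crossed model could separate
  lab-by-test interaction from pure between-lab variance.
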