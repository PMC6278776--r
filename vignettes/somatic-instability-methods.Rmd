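---
title: "Quantifying somatic instability of interrupted CTG expansions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic instability of interrupted CTG expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somamosaic)
```

## The problem

Myotonic dystrophy type 1 (DM1) is caused by an expanded CTG repeat
(roughly 50 to several thousand units) in the 3' UTR of *DMPK*. The
expansion is somatically unstable: repeat length keeps changing in the
patient's cells throughout life, with a bias toward further expansion, at
a pace that grows with both the inherited allele length and age. A small
fraction of patients carry *repeat interruptions* — non-CTG units (CCG,
CTC, GGC, CAG, or CCGCTG hexamer runs) embedded at the 3' end of the
expansion — and these patients tend to present later than their expansion
size alone would predict.

`somamosaic` implements the quantitative machinery needed to test whether
interruptions act by *stabilizing* the expansion in somatic cells:
per-sample statistics of single-molecule small-pool PCR allele
distributions, a linear-model suite that defines *expected* instability
and *expected* age at onset, a nonparametric comparison matrix, and a
synthetic-cohort simulator that generates data with the statistical
structure the analysis assumes.

## Distribution statistics

Each sample is a set of allele lengths (trinucleotide repeat units, one
per amplified molecule; at least 200 molecules per sample is the working
quality criterion — smaller samples are flagged, not discarded). From the
empirical allele frequency distribution (AFD) the package computes:

* **ePAL**, the estimated progenitor allele length: the 10th percentile
  of the AFD. The inherited allele sits near the lower edge of the
  somatic distribution because mutation is expansion-biased; the 10th
  percentile is a robust estimate of that edge.
* **SI**, the observed somatic instability: the difference between the
  90th and the 10th percentile of the AFD.
* **the modal allele length**: sizes are rounded to whole repeats and
  the mode is the argmax of the integer histogram, optionally smoothed
  with a Gaussian kernel (bandwidth from Silverman's rule by default,
  `bandwidth = 0` for the raw histogram). Ties break toward the smaller
  length. Smoothing emulates reading the centre of a diffuse band on a
  blot; whether to smooth is a user choice, and modes of diffuse
  distributions can shift by a repeat or two with the bandwidth.
* **5'-end views**: for interrupted expansions, subtracting the length
  of the interrupted 3' part (from the first non-CTG block to the 3'
  end) from every sized allele gives the distribution of the remaining
  pure 5' tract. SI is invariant under this shift; ePAL and the mode
  move down by the constant.

Percentiles use linear interpolation at rank $h = (n-1)q/100 + 1$
(`stats::quantile` type 7). The convention is configurable because
half-integer percentile values in practice depend on it; the package
treats it as a reporting convention, not a scientific claim.

The interrupted-part length is normally derived from the interruption
pattern string — e.g. `(CTG)n CTC (CTG)26` contributes $1 + 26 = 27$
repeats, with hexamer CCGCTG blocks counting two trinucleotides per
repeat and internal pure CTG runs between interruptions included.
Patterns with an unparsable or unknown internal block length require an
explicit per-patient override, and an override always wins over pattern
arithmetic: sizing-based estimates of the interrupted part (mode minus
5'-end mode) can legitimately differ from block arithmetic by a couple
of repeats, and the package does not guess which is right.

## The model suite

Expected values come from ordinary least squares on per-subject
summaries, refit on a large reference cohort of uninterrupted-expansion
patients pooled with the study patients, separately per sampling
timepoint:

| model | response | predictors |
|-------|----------|------------|
| M8    | log10 SI | ePAL, age at sampling |
| M8 (5' variant) | log10 SI of the 5' view | 5' ePAL, age at sampling |
| M9    | age at onset | ePAL |
| M10   | log10 age at onset | ePAL |
| M11   | log10 age at onset | ePAL, standardized M8 residual |
| INCR  | modal increment | mode at t1, interval |

The exact functional forms of the historical models are not public, so
the transforms above are this package's defaults, chosen for the
right-skew of SI and age at onset; every model is declared through
`model_spec()` and can be overridden (including fixing coefficients from
a config instead of fitting). M9 and M10 differ only in the response
transform — the package needed two distinct "onset vs progenitor
length" forms and uses the untransformed response for the weaker one.
R-squared is reported unadjusted.

Residuals live on the transformed scale and are standardized to mean 0,
SD 1 (enforced to 1e-9 in tests). The standardized M8 residual is the
working definition of a subject's *individual-specific* instability —
what ePAL and age cannot explain — and feeds M11 as a covariate via
`attach_si_residual()`. Because in-sample R-squared never decreases when
a predictor is added, M11's fit is at least M10's by construction; the
scientific question is whether the interrupted group's *onset* residuals
shrink toward the reference spread once the instability residual is in
the model.

## The comparison matrix

`run_comparison_matrix()` emits, per the analysis design: per-patient
blood-vs-buccal and t1-vs-t2 AFD rank-sum tests; per-group
observed-vs-expected SI and increment signed-rank tests; per-model
standardized-residual rank-sum tests of the interrupted and control
groups against the reference group; and within-group M11-vs-M10
residual signed-rank tests. All tests are two-tailed at 0.05 with no
multiplicity correction — the analysis is a small, pre-specified family
of confirmatory contrasts, and corrections would change the published
convention it mirrors.

Conventions (all configurable): the rank-sum statistic W is the
Mann-Whitney U of the first sample (orientation recorded, since the
reflection $W \mapsto n_1 n_2 - W$ makes either direction recoverable);
exact p-values by enumeration when $n_1 n_2 \le 400$ with no ties,
otherwise normal approximation with tie and continuity correction;
signed-rank zeros are dropped before ranking, midranks for ties, exact
enumeration of the $2^n$ sign patterns for $n \le 25$ without ties. The
Shapiro-Wilk gate is recorded but never switches the analysis to a
parametric test: AFDs are non-normal by construction, and keeping one
test family makes results comparable across samples.

## The simulator

The generator exists so that every statistical property of the pipeline
can be tested against a world whose ground truth is known.

**Somatic process.** Each of `n_lineages` (default 200) cell lineages
carries a repeat length. Per year, a lineage of length $L$ suffers
$\mathrm{Poisson}(r f L)$ mutation events; each event expands with
probability $1 - c$ (default $c = 0.3$) or contracts, by a geometric
step of mean 3 repeats; lengths are floored at 50. Defaults:
$r = 0.02$ events/repeat/year, giving a net drift of about
$1.2\,r L \approx 2.4\%$ of the allele length per year — modal growth
of order 10–25 repeats per year for typical adult alleles, in the range
reported for blood. The resulting AFDs are right-skewed (length-
proportional rates make long alleles mutate faster), and spread grows
with both $L$ and age — the three qualitative facts the analysis relies
on. Interruptions enter as the single multiplicative factor $f \le 1$
on the event rate of the whole allele: a deliberately coarse encoding
of an in-cis stabilizing effect that extends beyond the interrupted
block itself.

**Observation.** Small-pool PCR is modelled as repeated reactions
contributing Poisson(7.5) molecules each (5–10 genome equivalents),
sampled uniformly from the population until 200 molecules are retained,
with 2% lognormal sizing noise and censoring below 50 repeats.

**Cohorts.** `generate_reference_cohort()` draws ePAL ~ U(100, 750) and
age at first sampling ~ U(20, 60) for 136 subjects, simulates and
observes both timepoints (resampling interval U(2, 11) years — spanning
the follow-up intervals of short prospective study groups so that
increment predictions interpolate rather than extrapolate), and then
draws age at onset from
$\log_{10} AO = 1.72 - 0.00033\,\mathrm{ePAL} - 0.061 z + \varepsilon$,
$\varepsilon \sim N(0, 0.168)$, where $z$ is the subject's standardized
M8 residual. The coefficients were calibrated once, before freezing,
so that refitting the suite on generated cohorts reproduces the
variance-explained structure the analysis assumes: close to 90% for M8
(the packaged acceptance script recomputes this number), and onset
models rising from roughly 40% (M9) through 50% (M10) to the mid-50s
(M11) — i.e. the instability residual carries real, but modest,
information about onset. 15 of 136 subjects get a missing onset age,
mimicking an asymptomatic fraction. `generate_study_cohort()` produces
a small clinical series (default 7 interrupted subjects with
$f = 0.4$, representative interruption patterns and subtraction
overrides, 2.5–4-year follow-up, buccal samples for a subset with a
slower tissue rate and +100-repeat progenitor offset; 4 uninterrupted
controls with $f = 1$) in the exact file formats the readers consume.
All randomness flows from the config seed; equal seeds give identical
cohorts.

**What the generator does not emulate** — and what passing tests
therefore do not show about real data: PCR stutter and heteroduplex
artifacts; family clustering of instability modifiers; tissue-specific
interruption effects (the tissue contrast is a fixed rate/offset pair);
germline transmission; any mechanistic DNA-repair biology; and the
historical cohort's exact covariate distribution. One visible
consequence: because the walk's expected increment is close to
proportional to mode × interval, the *additive* increment model (INCR)
is only a local approximation in the synthetic world and can predict
negative increments for small alleles over short intervals; on
generated cohorts it explains roughly two-thirds of increment variance
rather than the ~56% seen in real data, and observed-vs-expected
increment contrasts on synthetic study groups should be read with that
in mind.

## Numerical choices and degenerate inputs

* Quantile type 7 by default; all conventions accepted by
  `stats::quantile` are reachable through the `type` argument.
* Mode ties break toward the smallest length; a single-valued sample is
  its own mode and has SI 0.
* A 5'-end subtraction constant at or above the smallest sized allele
  is an error (it would create non-positive lengths), as is a
  non-positive response under a log transform (the offending subjects
  are named).
* Signed-rank tests require at least one nonzero difference; constant
  samples are rejected by the normality gate.
* Rank-deficient designs abort the fit rather than silently dropping
  columns.

## Problem sizes

The packaged defaults are the study conditions: 136-subject reference
cohorts with 200 lineages and 200 molecules per sample. The
Monte-Carlo-heavy test properties (type-I error over 400 simulated
cohorts, stabilization-effect separation over 200 replicates) run on
reduced configurations — 30–40 subjects, 40–50 lineages, 60–80
molecules — which preserve the statistical structure being tested while
keeping the whole suite in the low minutes on a single core.

## Known limitations

The simulator's rate constants are calibration knobs, not measured
biology; only their qualitative consequences (age/length dependence,
expansion bias, stabilization) are asserted. ePAL estimated from the
10th percentile drifts upward with age in the simulated world, as it
does in real blood data, so "progenitor" is a modelling convention.
With the reference group simulated under the same process as everyone
else, pooled-fit expected values are slightly contaminated by the
interrupted group (as in any retested-model design); the reference
group's own observed-vs-expected contrast is therefore more sensitive
to small systematic offsets than a real, externally fitted model would
be.
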