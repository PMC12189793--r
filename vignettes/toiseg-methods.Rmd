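---
title: "Segmenting intervention-perturbed perfusion signals: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting intervention-perturbed perfusion signals: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toiseg)
```

## The problem

Continuous perfusion recordings (e.g. laser speckle contrast imaging of the
rodent brain microcirculation) are measured through a sequence of
experimental states: a basal period, then one state per intervention (a
cold stimulus, a warm stimulus, ...). The interventions are applied
manually, and the minutes around each application contain instrumentation
artifacts that can dwarf the biological response. The experimenter marks
which state each sample belongs to, but those markers are approximate: the
signal stabilizes some time after the manipulation, not at the moment the
marker changes.

`toiseg` treats this as a segmentation problem. It detects where the
signal's piecewise-linear structure changes, uses those changepoints to
(a) locate the effective intervention times and (b) carve out symmetric
exclusion windows around them, and then compares only the clean,
stabilized segments — each subject normalized against its own basal state.

## Signal model and segmentation

Within a subject, the working model is a piecewise-linear mean observed
with noise: between consecutive changepoints the signal is well
approximated by its own least-squares line. The segmentation minimizes the
penalized objective

> sum over segments of OLS-line RSS + β · (number of changepoints),

subject to a minimum segment length, solved exactly by the PELT dynamic
program. Two properties matter for correctness:

* **Pruning validity.** PELT's pruning is exact when the segment cost is
  subadditive under splitting. The OLS-line RSS is: a single line is an
  admissible (if suboptimal) fit on each half of a split segment. With a
  minimum segment length the pruning must additionally be *delayed* by
  `min_len − 1` steps: a candidate dominated at time *t* is provably
  useless only once a changepoint at *t* itself becomes admissible. The
  implementation keeps dominated candidates alive exactly that long; the
  test suite checks equality of the penalized optimum against exhaustive
  enumeration over hundreds of randomized short signals.
* **Determinism.** Cost ties are broken toward fewer changepoints, then
  the leftmost last changepoint. Note that a *continuous* slope change
  (a kink) always produces a two-way tie: the vertex sample lies on both
  lines, so splitting just before or at the kink costs the same. Only
  discontinuous changes have a unique optimal position.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `beta` | `2 σ̂² log nᵢ` | squared perfusion units | BIC-flavored; scales with noise variance so segmentation geometry is invariant to signal rescaling |
| `σ̂` | `1.4826 · MAD(Δy) / √2` | perfusion units | robust to the mean shifts and artifact bursts the signal is assumed to contain; first differencing removes slowly varying structure, √2 undoes the variance doubling |
| `min_len` | 3 samples | — | any 2-point segment has zero line RSS and would be degenerately favored |
| `cost` | `"linear"` | — | the approximation family is piecewise linear; a constant-mean cost is available for step-like signals |

A noise-free input makes σ̂ = 0; the package warns and applies a small
positive floor to β so the search still prefers parsimony. The penalty is
deliberately fully overridable: it is a modeling choice, not an estimated
quantity.

## From changepoints to optimal TOIs

Detected interior changepoints are assigned to TOIs by the marker of the
sample at their position (a changepoint is a boundary *after* its sample;
one sitting on the first sample of a block belongs to that block). The
intervention time of TOI *j* is the earliest changepoint in its block; if a
post-basal block contains none, the marker boundary is used with a warning
— the markers are error-prone, but they are the only information left in
that case.

The window half-width *k* is the total number of post-basal interior
changepoints. The rationale: each manipulation typically generates a small
burst of changepoints (artifact onset, artifact end, stabilization), so
their count reflects how disturbed the transitions are; the window
`[IT − k, IT + k]` then scales its safety margin with that disturbance.
Note that *k* is computed from the detected changepoints, i.e. from the
data — it is re-estimated per subject and surfaced in every report and log
precisely so that its variability is visible.

All window arithmetic is in 1-based sample-index space, which is why
records must be uniformly sampled: only there are expressions like
`IT − k − 1` well defined regardless of the sampling interval.

Degenerate geometry (windows that would overlap or empty a TOI) is an
error by default, naming the offending TOI. An optional clamp mode instead
reduces *k* to the largest admissible value, with a warning. Clamping by
shrinking *k* — rather than truncating individual windows — was chosen
because it preserves the two invariants everything downstream audits:
windows stay symmetric about their intervention times, and OTOI ∪ OTT
remains an exact partition of `1..nᵢ`.

## Normalization and differences

Reference statistics (mean, sample sd with the n−1 divisor; the divisor is
a convention choice with negligible effect at TOI lengths of ~100) are
computed over the *optimal* basal TOI only — never over the experimenter's
marker block, since excluding artifact samples from the reference is the
point of the segmentation. The normalization is then applied to all
samples, transitions included, so full records can be plotted on the
normalized scale; but no statistic ever consumes transition samples (the
test suite tampers with them and asserts every downstream quantity is
unchanged).

The piecewise-linear approximation is fitted independently per segment (no
continuity constraint — the approximation is intentionally step-like at
changepoints) and normalized by its own reference statistics. One
consequence worth stating: the PLA's reference sd is smaller than the raw
one, so the *normalized* PLA is not guaranteed to have smaller within-TOI
variance than the normalized raw signal, even though the un-normalized PLA
is smoother segment by segment (a least-squares projection property, which
is what the tests assert).

Between-state differences align two TOIs by within-TOI sample order and
truncate to the shorter one. Padding alternatives were rejected: invented
values would enter rank statistics. Because both states share the
subject's reference statistics, the difference series equals the raw
between-state difference divided by the basal sd — this identity is
asserted to 1e-12 across simulated cohorts.

## Comparative statistics

The omnibus test is Kruskal–Wallis (tie-corrected, chi-square reference).
The pairwise post hoc is Dunn's rank test on the pooled ranking with
family-wise correction. The correction is configurable (Holm by default,
Bonferroni available) and recorded in every report: published analyses of
this kind rarely state their exact post-hoc procedure, so reproductions
must be able to vary it. Holm dominates Bonferroni (it rejects a superset),
which gives a deterministic coherence check between the two runs.

Per-subject difference counts (total, split by the other subject's group)
summarize the significance matrix; totals always decompose exactly into
the group splits. Box summaries use linearly interpolated `(n+1)p`
quartiles (quantile type 6) and Tukey 1.5·IQR whiskers.

## What the synthetic cohorts emulate — and what they do not

`simulation_design()` defaults describe the cohort structure the method
was designed around: N = 33 subjects (16 control, 17 experimental, split
by sex 8/8 and 9/8), three states (basal, cold, warm) of 120 samples each,
baseline 250 perfusion units, a cold-induced drop of 40 PU with full warm
recovery in controls, a flat profile in the experimental group, stationary
AR(1) noise (marginal sd 10 PU, coefficient 0.3 — perfusion traces are
visibly autocorrelated), and a square artifact burst of 80 PU amplitude
and half-width 3 samples centered on each intervention boundary. Real
recordings' sampling rate and lengths are not standardized; 120 samples
per state keeps every validation run fast while leaving two orders of
magnitude between segment length and `min_len`. Burst shape (square /
triangle / exponential) and white-noise mode are available switches.

The generator is a statistical emulator, not a hemodynamics model. It does
not produce: slow drifts within states, responder heterogeneity inside a
group, unequal state lengths across subjects, marker misplacement, or
heavy-tailed artifacts away from boundaries. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes — clean
piecewise responses contaminated only near interventions — not that it is
robust to every failure mode of real data.

One property of the emulator deserves emphasis because it looks like a bug
and is not: the Kruskal–Wallis test across *individuals* on raw basal
values pools ~100 autocorrelated samples per subject. Under AR(1) noise
the subject means vary more than iid pooling implies, so this test is
anti-conservative by construction and can reject even though all subjects
share one true baseline. The group-level test on normalized basal values
does not suffer from this (each subject's basal z-mean is exactly 0), and
it is the basal comparison the validation suite asserts. Real cohorts with
genuinely identical baselines and weaker autocorrelation need not show the
effect.

## Validation problem sizes

The shipped validation runs use: 200 randomized signals of length ≤ 20 for
the search-vs-enumeration equivalence; 500–1000 simulated subjects for the
exact-cover and intervention-time recovery rates; one 33-subject cohort
for the full comparative analysis; and 50 replicate cohorts for the
response-pattern recovery rates (cold-to-basal rejection at p < 0.001
together with basal non-rejection at α = 0.05). These sizes were chosen so
the whole suite completes in about a minute while keeping Monte-Carlo
standard errors well inside the asserted margins.

## Known limitations

* Uniform sampling is required; resample upstream if needed.
* The per-subject `k` couples window width to the *total* post-basal
  changepoint count: a subject with genuine within-state dynamics (extra
  changepoints) gets wider exclusion windows everywhere, and a very
  disturbed recording can make the windows inadmissible (surfaced as an
  error, or shrunk in clamp mode).
* No multiscale or online changepoint machinery; signals are processed
  whole, per subject.
* Pooled rank tests treat samples as exchangeable within groups; with
  strong within-subject autocorrelation their p-values at the individual
  level are optimistic (see above). Interpret them, as here, as
  qualitative separation evidence rather than calibrated error rates.
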