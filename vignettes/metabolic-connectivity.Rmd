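---
title: "Correlation network analysis of whole-body dynamic PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation network analysis of whole-body dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccnets)
```

## The problem

Whole-body dynamic PET delivers, for every subject, a time-activity curve
(TAC) in each delineated organ, expressed in standardised uptake value (SUV)
units — tissue activity normalised for injected dose and body weight. With a
cohort of subjects scanned under two conditions (here: a baseline control
condition and one in which rifampicin, a potent inhibitor of the hepatic
OATP uptake transporters, has been infused before a glyburide-like tracer),
the data form a subjects x regions x time array. Correlation-network
analysis treats the pairwise Pearson correlation coefficient (PCC, written
`r`) as a similarity measure over that array and asks which structures in
the resulting graphs distinguish the two conditions.

`pccnets` implements three complementary constructions:

* **d-networks** (dynamic, intersubject): within a single region, correlate
  every pair of subjects' TACs. Nodes are subjects; an edge means two
  subjects' regional kinetics agree (`r > 0.65`, `p < 0.001`), weighted by
  `r`, then sparsified by k-nearest-neighbour (k-NN) edge reduction with
  `k = 3`.
* **s-networks** (static, intersubject): reduce each subject to a
  "fingerprint" — the vector of static SUVs across regions — and correlate
  fingerprints between subjects (`r > 0.65`, `p < 0.05`, `k = 3`). Regions
  known to carry treatment-independent noise can be excluded first, which
  is what makes this an *informed* method.
* **ΔPCC networks** (static, intrasubject): correlate *regions* over the
  `n` control subjects (the reference matrix `PCC_n`), append a single
  treated subject, recompute (`PCC_{n+1}`), and take the element-wise
  difference `ΔPCC = PCC_{n+1} - PCC_n`. One matrix is produced per treated
  subject; after a significance threshold is applied, the matrices are
  averaged into a group-level result. No region curation is needed — the
  method is *uninformed*.

## Standardisation

All scans are linearly interpolated onto a common grid of 240 equally
spaced points from 14 s to 2416 s post-injection (about 40 minutes sampled
roughly every 10 s). Linear interpolation is used deliberately: unlike
spline-type schemes it does not smooth the data, and it reproduces raw
samples that fall on grid points exactly. No extrapolation is permitted —
scans that do not cover the full span are rejected rather than padded.

The *static* SUV of a curve is the arithmetic mean of the grid samples in
the final ten minutes (times `>= t_end - 600 s`, inclusive), which on the
default grid is exactly 60 samples. Composite signals are unweighted
element-wise means of regional TACs; the blood pool is the mean of aorta
and ventricle. An unweighted mean was chosen because the relative volumes
of the contributing structures are not part of the data model; since the
PCC is scale-invariant, any fixed positive weighting would change the
result only marginally.

## Correlation and edge significance

Both Pearson and Spearman (rank) correlation are supported; Pearson is the
default everywhere. Edge p-values use the classical transform
`t = r * sqrt((m - 2)/(1 - r^2))` with `m - 2` degrees of freedom, two-sided.
Two caveats are intentional and documented rather than "fixed":

* For TAC correlations, `m = 240` interpolated samples are strongly
  autocorrelated, so these p-values are nominal, not effective. The network
  definition therefore couples the p gate with a direct threshold on `r`
  (`r > 0.65`), which dominates in the dynamic case.
* No multiple-testing correction is applied to edge p-values, matching the
  way these networks are defined and read.

A zero-variance input is an error, never a silent zero correlation: a
constant curve carries no information and should be caught upstream.

For the s-network the fingerprints contain only `m = ` (number of included
regions) observations; with nine regions minus one exclusion, `m = 8` or 9.
At those sizes `r = 0.65` sits near the classical `p = 0.05` critical value,
so both gates genuinely bite and are applied jointly. The observation count
is always the number of regions actually included.

## k-nearest-neighbour edge reduction

`knn_reduce()` keeps an edge if it ranks within the top `k` by weight for
*at least one* of its endpoints, with all edges tied at the k-th weight
retained. The "either endpoint" (union) semantics was chosen because it is
the only reading under which a node can never lose its own strongest edge;
an intersection variant is available as an option. The reduction is
idempotent and monotone in `k`, and never invents edges — properties the
test suite asserts over randomly generated graphs.

## ΔPCC significance: Monte-Carlo calibration

Appending one subject to a reference cohort of size `n` moves each
interregional correlation by a random amount even when the new subject is
drawn from the same population. The significance threshold for `|ΔPCC|` is
therefore calibrated under exactly that null: per replicate, draw `n`
pairs from a bivariate normal with correlation `rho`, compute the sample
PCC, append one further pair from the same distribution, recompute, and
record the absolute change. The critical value at level `alpha` is the
`(1 - alpha)` quantile of the recorded changes. The draw is vectorised, so
100,000 replicates take well under a second:

```{r calibrate}
calibrate_threshold(n_reference = 13, rho = 0, alpha = 0.05,
                    n_replicates = 1e5, seed = 1)
```

For 13 reference subjects and `rho = 0` this gives about 0.18. The
threshold falls as `n` grows (one subject has leverage of order `1/n`) and
as `|rho|` grows (a tight elliptical cloud pins the correlation down;
in the limit `rho -> 1` an added point cannot change `r` at all).
`threshold_curve()` tabulates the full surface.

Two design points were genuinely open and are resolved as follows:

* **Per-pair vs global threshold.** Because the critical value depends on
  the reference correlation, `deltapcc_pipeline()` by default calibrates a
  separate threshold for every region pair, plugging in that pair's
  *observed* reference correlation as `rho`. A single global threshold
  (e.g. 0.18, the `rho = 0` value — conservative for every correlated
  pair) can be requested for figure parity.
* **Population vs conditional null.** The calibration conditions on the
  population `rho`, not on the realised reference sample. A conditional
  variant (holding the observed reference points fixed and redrawing only
  the appended subject) would answer a subtly different question and is
  not implemented. One consequence of the marginal null is worth knowing:
  for a *fixed* reference sample whose realised correlation deviates from
  `rho`, every appended subject pulls the correlation back toward `rho`
  with the same sign, so per-pair exceedances are correlated across
  subjects and occasional consensus false positives can survive averaging
  on tightly correlated pairs. This is intrinsic to the perturbation-network
  construction, not a bug in the calibration.

Sub-threshold entries are set to zero (not dropped) before averaging, so
the group average is taken over *all* perturbation subjects at every
element; subjects without significant change attenuate the mean rather
than being excluded, which is the intended group-level reading.

## The synthetic cohort generator

No scan data ships with the package; `generate_cohort()` produces cohorts
with the statistical structure the pipelines are built to detect, and every
end-to-end test runs on them. The default `cohort_spec()` encodes the study
design: 13 control and 9 rifampicin subjects over nine regions (left and
right kidney, liver, aorta, aorta wall, ventricle, myocardium, gallbladder,
pancreas), sampled on an irregular schedule (10 s frames to 3 minutes, then
coarser frames to ~42 minutes) so the interpolation path is always
exercised.

Per subject, curves are built from two shapes: a normalised blood input
(gamma-variate first-pass peak plus slow recirculation tail) and a
saturating uptake term `1 - exp(-t/tau)`. Each region mixes the two with
fixed amplitudes chosen to give realistic static SUVs (liver ~10 under
control conditions, other organs ~1-2). Three stochastic layers create
inter-subject structure:

* a shared log-normal *global* factor (`subject_noise = 0.15`) that scales
  all of a subject's regions — this is what induces positive interregional
  correlations in the reference matrix;
* an independent log-normal *per-region* factor (`region_noise = 0.12`);
* multiplicative per-frame measurement noise (`measurement_noise = 0.02`).

Mild per-subject kinetic jitter (peak time, uptake constant) scales with
`subject_noise`, so a zero-noise specification yields identical curves —
a limit the tests assert.

The two scientifically meaningful contrasts:

* **Liver effect.** The perturbation group's liver *uptake* amplitude is
  multiplied by `liver_effect = 0.15`, reflecting the published ~85%
  reduction in hepatic uptake under OATP inhibition. Only the uptake term
  is scaled, so the rifampicin liver curve also changes *shape* (the blood
  component becomes relatively dominant) — necessary because the PCC is
  scale-invariant and a purely multiplicative reduction would be invisible
  to a d-network. The effect also drops the rifampicin liver static SUV
  into the band of the other organs, which is what lets the
  gallbladder-free s-network separate the groups into two pure components,
  as the real cohort did. Note the static-SUV group ratio is slightly
  above `liver_effect` because the blood-borne component is unaffected.
* **Gallbladder hypervariability.** The gallbladder fills along a ramp
  with a random onset and a log-normal amplitude with `gallbladder_cv = 1`
  on the log scale (median static SUV ~6, 95% range roughly 0.8-45),
  independent of group — emulating bile storage and release that depends
  on digestion, not on the drug. Its coefficient of variation dominates
  every other region's; its absolute variance is the largest in most, but
  not every, random cohort (heavy-tailed variance estimates from 13
  subjects occasionally fall below the liver's).

Presets: `"paper-default"` is exactly the above; `"null"` removes all group
effects *and* resets the gallbladder to ordinary variability, giving a
fully exchangeable, approximately multivariate log-normal cohort on which
the ΔPCC false-positive rate can be checked against its nominal level
(the bivariate-normal calibration requires the null model to hold);
`"strong-effect"` deepens the liver reduction (`liver_effect = 0.08`) and
quietens region noise so the s-network separation holds with a wide margin
in every seed.

What the generator does **not** emulate: physiological pharmacokinetics
(no compartment model, no plasma metabolite correction), radioactive-decay
or scanner noise statistics, organ-volume effects, or any real-data
artefact such as motion. Passing tests therefore demonstrate that the
pipelines detect the *kind* of structure described — a shape-changing
group effect in one organ, a group-independent hypervariable organ, a
group-invariant vascular reference — not that they reproduce any
particular subject's data.

## Numerical choices

* Thresholds use strict inequalities (`r > r_min`, `p < alpha`,
  `|ΔPCC| > threshold`), so boundary values are excluded.
* Correlation matrices are symmetrised (`(R + t(R))/2`), clamped to
  `[-1, 1]`, and given an exact unit diagonal before use.
* The Monte-Carlo calibration uses the empirical type-7 quantile; its
  sampling error at 100,000 replicates is ~0.001 at the `n = 13, rho = 0`
  point, far inside the tolerance of any comparison made with it.
* `calibrate_threshold()` and `generate_cohort()` seed a local RNG scope
  and restore the caller's stream, so pipelines are reproducible without
  side effects.
* Exports: GraphML carries node groups, edge weights and threshold
  provenance as typed attributes (weights at ~15 significant digits);
  edge-list CSVs serialise weights with `%.17g`, making write/read
  round trips value-exact.

## Problem sizes in the test suite

End-to-end tests run on cohorts of 22 subjects x 9 regions x 240 grid
points; calibration checks use 20,000-100,000 Monte-Carlo replicates;
structural claims (component separation, mixing vs permutation null,
signal confinement) are evaluated over 20 generator seeds with 500-1000
label permutations each; brute-force oracle comparisons cover 1000 random
instances per operation at up to 12 entities. The full suite runs in about
a minute on one CPU.

## Known limitations

* The t-based edge p-values on dynamic data are nominal (autocorrelation
  is not corrected); conclusions in the dynamic case should rest on the
  `r` threshold and the permutation diagnostics, as they do here.
* ΔPCC matrices of different perturbation subjects share the same
  reference and are therefore not independent; the method supports
  group-level statements, not subject-vs-subject comparison.
* The per-pair calibrated threshold plugs in an *estimated* reference
  correlation; with 13 reference subjects that estimate is noisy, and the
  realised per-pair false-positive rate is near, not exactly at, the
  nominal level (the suite checks 5% ± 2%).
* Graph layout and interactive visual analytics are out of scope; exports
  are designed to load into dedicated graph tools.
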