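---
title: "Modeling MRI network progression along healthy-brain architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling MRI network progression along healthy-brain architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In unilateral mesial temporal lobe epilepsy (mTLE), seizures originate in
one hippocampus and the disease reorganizes functional and structural
brain networks far beyond the focus. `netprog` implements a quantitative
framework for asking *where* and *when* those changes occur: are network
alterations larger in regions that are "close" to the anterior
hippocampus in the healthy brain, and do they grow with duration of
disease?

"Close" is operationalized by four healthy-brain topologies, each built
from a control cohort:

* **T~LEN~** — mean streamline length between regions (physical distance
  proxy); bin 1 = shortest length.
* **T~SC~** — volume-scaled streamline count (structural connectivity);
  bin 1 = strongest connection.
* **T~FC~** — Fisher-z functional connectivity; bin 1 = largest |z|.
* **T~RSN~** — membership in four resting-state networks ordered along
  the transmodal-to-unimodal cortical gradient (default mode >
  attention > primary visual > motor/sensorimotor), five bilateral
  region pairs each.

The matrix topologies are control averages computed per hemisphere over
the 54 hemisphere regions plus the brainstem (55 x 55); cross-hemisphere
structural connections are too often undetected to support a distance
model. The model vector of a seed region is simply its row of the
topology matrix; the anterior hippocampus is the seed throughout.

## The deviation statistic

Each patient's hippocampal network is compared with the control
population bin by bin. For the `k` edges of a bin, with `s` the
patient's age-residualized edge values, `mu` the control mean and `C`
the control covariance,

```
M = (s - mu)' C^-1 (s - mu)
```

a squared Mahalanobis deviation (kept squared, as the field's usage of
this statistic in normative modeling does not take the root; a
`squared = FALSE` switch exists). `C` is a Ledoit-Wolf shrinkage
estimate toward a scaled identity, which is positive definite at any
subset size used here, so the statistic is always defined.

Bins contain 10-11 edges but `M` is only comparable at a fixed `k`, and
some structural edges are undetected in some subjects. Both problems are
handled by permutation subsampling: 500 random subsets of 7 edges, each
crossed with 500 random subsets of 50 of the 70 controls. An edge subset
is skipped for a patient missing any of its edges; a control subset is
discarded when fewer than 45 controls carry all seven edges. The final
`M` is the mean over retained pairs (a mean-of-outer-means variant is
reported alongside, for the case of unbalanced discards).

Two implementation choices deserve a note:

* **Shared permutation streams.** Draws derive deterministically from
  `(seed, modality, hemisphere, bin)` and are shared across patients.
  The control-side work (subset covariance, shrinkage, inversion) is
  patient-independent, so sharing reduces the nested loop from
  `patients x outer x inner` covariance factorizations to
  `outer x inner`, and it removes between-patient Monte-Carlo noise from
  the bin comparisons. The shared component this introduces into bin
  means shrinks as 1/sqrt(retained pairs) and is an order of magnitude
  smaller than the irreducible control-cohort effect discussed under
  *Calibration* below.
* **RMSE convention.** Age standardization divides by the control fit's
  root mean squared error with the biased 1/n denominator (a literal
  reading of "root mean squared error"); a 1/(n-2) switch exists.

## Age normalization

Edge values drift with age, so all deviations are measured against
age-matched expectations: per edge, ordinary least squares of the
control values on age (structural connectivity on the natural-log scale;
undetected edges stay missing rather than receiving a pseudocount).
Residuals (`_res`) feed the Mahalanobis statistic; residuals divided by
the fit RMSE (`_corr`, in control-SD units) feed the whole-brain ICA.
The correction is fitted and applied in native left/right orientation;
patients are flipped to ipsilateral/contralateral (focus hemisphere into
the left-slot block) only afterwards, for pooling. Controls' own
corrected values use the model fitted on all controls; no leave-one-out
is attempted (a configurable choice).

## The gradient hypothesis test

The hypothesis "deviation decreases with healthy-brain distance" is
accepted only when three criteria hold simultaneously:

1. one-way repeated-measures ANOVA with bin as the within-subject factor
   reaches the family threshold (0.0125 when four topologies are tested,
   0.0167 for the three structural-modality topologies; no sphericity
   correction, matching the conventional degrees of freedom);
2. group means decrease monotonically from bin 1 to the last bin;
3. uncorrected paired t tests show no higher-index bin significantly
   above a lower-index bin at 0.05.

For temporal progression, patients are grouped by duration of disease at
10 and 30 years (<=10 short, 11-30 medium, >30 long) and the battery is
repeated per group, plus a mixed ANOVA reporting the bin-by-group
interaction.

## Whole-brain hybrid ICA

The whole-brain stage concatenates each patient's `FC_corr` and
`SC_corr` upper-triangle edges (ipsi/contra orientation) into a
patients-by-edges matrix; structural edge columns missing in more than
10% of patients are dropped and remaining holes imputed at 0 (the
age-expected control level). After column centering, PCA retains the
smallest dimension reaching 90% variance and FastICA (symmetric
orthogonalization, logcosh contrast) is run 40 times from seeded random
initializations. Edge-space components are scaled so patient weights
have unit SD — component values are then in control-SD units per 1-SD
weight variation, the scale on which the thresholds below operate.

Run-to-run component matching uses connected-component clustering of the
|r| > 0.8 graph with sign alignment, repeated until the merged set is
pairwise below the threshold; this is an order-independent replacement
for greedy pairwise merging and its result does not depend on run
ordering. Each merged component records an identification frequency
(distinct contributing runs / configured runs).

Only components identified in at least half the runs are eligible for
the duration analysis. This mirrors established connectome-ICA practice
of keeping run-replicable components only, and it is statistically
necessary: with ~30 retained PCA dimensions, most single-run components
reflect the rotational ambiguity of near-Gaussian directions, and
Spearman-testing hundreds of them against duration would make a
spurious selection certain. Eligible components are selected at the
Bonferroni-corrected level 0.05 / n_eligible (sign-flipped so the
correlation is positive) — a decomposition can yield a dozen replicable
components, and the family-wise correction is what keeps the
permuted-duration negative control near its nominal level; the
strongest correlation is the primary component.

The primary component's FC and SC blocks are thresholded at |0.55| and
|0.175| respectively (a density-targeted alternative can be had by
passing the threshold that achieves ~20% density), and each region's
weighted degree — the signed sum of surviving incident edges, "net
connectivity" — is correlated with the four model vectors (Pearson for
the matrix models, Spearman for the ordinal RSN model) at the
Bonferroni threshold 0.0125. Model distances are averaged over the left
and right hemispheres because the component lives in ipsi/contra space
while the models are built in native orientation.

FastICA on data whose retained dimensions are mostly near-Gaussian
oscillates just above any strict convergence tolerance; as in the
reference implementations, the estimate at the iteration cap (200) is
used, and a run is dropped only on numerical failure. The merging stage
is what turns the unstable individual runs into stable components.

## The synthetic cohort generator

No patient data are distributable, so the package ships a generator
whose defaults are the study conditions: 70 controls, 40 patients (29
right-/11 left-sided focus), ages 18-71, duration of disease ~ N(21,
15^2) truncated to [2, 50] years. Its generative model produces the
statistical structure the analysis assumes:

* 3-D region coordinates, mirror-symmetric across hemispheres up to 1 mm
  jitter; streamline length = 1.2 x Euclidean distance (a tortuosity
  allowance), log-normally jittered per subject (sigma = 0.03).
* Mean Fisher-z FC decays exponentially with length (0.8 x
  exp(-LEN/60 mm)); mean log-SC decays linearly (-0.03/mm). Per-edge
  intercept and slope perturbations are shared between homotopic edge
  pairs (bilaterally symmetric connectivity), which is what makes the
  left- and right-hemisphere topologies agree as they do in real
  control cohorts.
* Every edge has its own linear age slope (SD 0.002 z/yr for FC, 0.004
  log-units/yr for SC); subject noise is Gaussian on the Fisher-z scale
  (SD 0.15) and log-normal for SC (sigma = 0.4).
* Cross-hemisphere structural edges are undetected with probability 0.4
  per subject — strong enough that RSN bins (which mix hemispheres)
  lose structural coverage, reproducing why the structural analysis
  drops that topology.
* Patient effects are planted on the edges of the ipsilateral anterior
  hippocampus, binned by the generator's own latent streamline length:
  FC and log-SC shift by `effect_profile[bin] x (duration/30)^e` control
  SDs (default profile (3, 2.25, 1.5, 0.75, 0), e = 1, direction =
  decrease; the direction is a parameter because the deviation statistic
  is unsigned).
* A separate planting step adds a rank-1, duration-linked edge pattern
  (sparse sign-consistent support across the FC and SC blocks, loading
  built on a Gaussian copula over duration ranks) in ipsi/contra space
  — the ground truth for the ICA stage.

What the generator does *not* emulate: spatial autocorrelation between
neighboring edges, non-Gaussian heavy tails of real FC, motion and
scanner confounds, hemispheric asymmetries of disease, and any genuine
coupling between the FC and SC noise of an edge. Passing recovery tests
therefore demonstrates that the pipeline detects the planted class of
structure at realistic noise levels — not that real mTLE cohorts carry
that structure.

An optional switch couples age of onset negatively with duration
(r = -0.59) to let users probe the confound that duration partially
proxies onset age; it is off by default so planted effects have a single
cause.

## Calibration and problem sizes

The test suite and the acceptance script run the full pipeline on
cohorts of the default size. Permutation counts are reduced from
500 x 500 to 100 x 100 (effect recovery; verdict rates are unchanged at
either count) and 50 x 50 (200-replicate null calibration); `full = TRUE`
in `run_pipeline()` restores the full counts. The ICA recovery
study uses 10 runs per replicate; merging makes the result insensitive
to the exact count once the planted component is found in most runs.

One calibration finding is a property of the statistic itself and is
documented rather than "fixed": under a global null, the
repeated-measures main effect of bin is anticonservative, because every
patient is scored against the *same* finite control cohort — the
per-bin covariance estimation error of those 70 controls becomes a bin
offset common to all patients, inflating the bin mean square. Permuting
more, or drawing per-patient permutation streams, does not remove it;
only a much larger control sample would. The bin-by-group interaction
used for the duration analysis is unaffected (offsets cancel between
groups) and its null p-values are uniform, which the suite verifies.
In practice this means a significant bin main effect should be read
together with the monotonicity and pairwise criteria — which is exactly
what the three-criterion verdict enforces; its false-verdict rate on
null cohorts stays below nominal because the monotone-decrease gate is
itself a 1-in-120 event under exchangeability.

## Numerical choices and degenerate inputs

* Ties in model-vector ranking break by region id (stable, deterministic
  binning).
* Bin chunking gives earlier bins the extra edge (54 edges in 5 bins ->
  11/11/11/11/10).
* Edges fit on fewer than 3 controls are unfittable; exact fits
  (RMSE ~ 0 relative to the data spread) are degenerate — both propagate
  as missing rather than producing infinities.
* An all-discarded bin yields `M = NA` with recorded reasons; patients
  with undefined bins are dropped from the gradient test with a warning.
* The Ledoit-Wolf intensity is computed with the closed-form dispersion
  identity in the C++ kernel and the textbook sum in the R reference;
  the two paths agree to 1e-10 and are cross-checked in the tests.
* All randomness flows from named seeds through a deterministic stream
  derivation, so every pipeline stage and the end-to-end run are
  bitwise reproducible.

## Known limitations

* The generator's edges are independent given the latent geometry;
  spatially correlated alteration fields would make bin recovery easier
  than reality, sharp bin boundaries make it harder. Both biases are
  second order for the planted-gradient tests.
* The RSN membership of the default atlas is an idealization (exactly
  five pairs per network, no overlap).
* The mixed ANOVA reports conventional interaction degrees of freedom;
  no sphericity correction is applied anywhere, by design.
* `M` is unsigned: the framework detects deviation, not direction, of
  network change.
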