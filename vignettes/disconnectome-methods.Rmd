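---
title: "Methods: disconnectome mapping and contrast-driven behavioral PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disconnectome mapping and contrast-driven behavioral PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, which choices
were genuinely open, and what the synthetic cohort does and does not show
about real data.

## The disconnectome model

A focal lesion disrupts every fiber that passes through it. Direct
per-patient tractography is rarely available, so disconnection is estimated
indirectly against a normative sample: for each of N control tractograms
(streamlines in world mm, pre-normalized to the analysis template grid),
the streamlines intersecting the patient's binary lesion mask are selected,
converted to a binary visitation map (a voxel is visited if any streamline
point maps into it), and the N maps are averaged. Voxel values are exact
multiples of 1/N in [0, 1]: the fraction of the normative sample in whom
that voxel is connected through the lesioned tissue.

Assumptions worth making explicit:

- **Single grid.** All volumes of one analysis must share shape and affine
  (tolerance 1e-4); a mismatch is a hard error rather than a silent
  resample. Voxel indices are 0-based; the affine maps indices to world mm.
- **Pre-normalized tractograms.** The original procedure registers each
  lesion into each control's native space before tracking; this package
  instead requires tractograms already in the common template space — an
  equivalent composition of transforms, and the only option for synthetic
  phantoms. TRK's voxel-mm conventions are normalized to world mm at read
  time; no downstream code sees format-specific coordinates.
- **Intersection by dense resampling.** A streamline intersects the lesion
  iff, after resampling so consecutive points are at most `step` apart
  (default: half the smallest voxel edge, i.e. 1 mm on a 2 mm grid), some
  point maps to a lesion voxel. Resampling keeps every original vertex and
  subdivides each segment evenly, so it is idempotent and bit-reproducible.
  The test is exact for chords longer than the step; a segment clipping a
  voxel corner with an intersection shorter than the step can be missed.
  Empirically on the phantom bundles, halving the step below the default
  changes about 1–5% of bundle voxels per halving (the convergence test
  bounds it at 8%); axis-aligned geometry is exact at any step.
- **Rounding convention.** World-to-voxel mapping rounds half away from
  zero, not half-to-even, so visitation maps are identical across platforms
  and languages.
- **Lesion voxels get no special treatment**: they hold whatever visitation
  value the selected streamlines give them, since the construction averages
  visitation maps only.

## The PLS model

Behavioral (correlation-scale) PLS with fixed, a-priori contrasts — no SVD
rotation. Both blocks are column-z-scored (sample SD, denominator n − 1);
the cross-block matrix is `R = Yz' Xz / (n − 1)`, so with identity
contrasts each salience map equals the mass-univariate Pearson correlations
between one behavioral variable and every voxel. This equivalence is the
suite's strongest oracle (agreement to 1e-10) and is the reason the
z-scoring convention was chosen: the reference toolbox's behavioral-PLS
mode is correlation-scaled, and the paper trail of any other scaling is not
recoverable. Open choices, decided as follows:

- **Contrasts are applied as given** (unit-normalized). No Gram–Schmidt
  orthogonalization is applied; the default identity contrasts are already
  orthogonal, and non-orthogonal user contrasts are treated as separate
  one-dimensional questions. Documented limitation rather than hidden
  behavior.
- **No Procrustes alignment in the bootstrap.** With fixed contrasts there
  is no axis-rotation or sign ambiguity across resamples, so raw resampled
  saliences are directly comparable; the alignment step of rotated PLS
  would be a no-op at best.
- **Permutation p-values are add-one smoothed**,
  `p = (1 + #{s_perm >= s_obs}) / (1 + n_perm)`, never exactly zero.
- **Bootstrap degeneracies.** A resample in which a *behavioral* column is
  constant (e.g. all-female) is redrawn and counted. Brain-block columns
  constant within a resample get z-score 0 for that resample instead:
  sparse voxels (nonzero in one subject) are constant in a third of all
  resamples, so redrawing on them would never terminate. Voxels whose
  bootstrap SE is exactly zero get bootstrap ratio 0 and are flagged rather
  than dropped silently.
- **Analysis mask.** A voxel enters the PLS iff it is nonzero in at least
  one subject and varies across subjects (relative variance tolerance
  1e-12, guarding float cancellation). Subjects with missing behavioral
  values are dropped and logged before the analysis.
- **Sex coding**: `female` = 1 for female, 0 for male.

## Clusters, battery, cohort models

The pseudo-z (bootstrap ratio) map is thresholded *strictly* (a voxel at
exactly 3 is excluded — the threshold is quoted as "> 3"), labeled under
26-connectivity by default (6 and 18 available), with no minimum cluster
size (the reported source table contains a 37 mm³ cluster, so any filter
would have destroyed information). Positive- and negative-tail clusters are
extracted separately and both reported: on the correlation scale used here,
"more disconnection, lower score" is a *negative* salience, so the
effect-carrying tail of the MoCA map is the negative one; sign handling is
explicit rather than folded into an absolute value. Ties in cluster
ordering (equal sizes) break on the smallest voxel linear index, making the
table deterministic. Peak coordinates are reported in 0-based voxel indices
and in world mm via the affine.

Cluster disconnectivity is the per-subject mean disconnection proportion
over each cluster's voxels; battery correlations are Pearson over
pairwise-complete subjects, with cells reported missing (with a reason)
below 3 complete pairs or under zero variance.

Cohort models are ordinary least squares (`stats::lm`): MoCA on the
recovery-phase factor (acute < 7 days, subacute 7–180, chronic > 180;
reference level acute; overall F reported), and MoCA on lesion volume plus
number of lesions. The impairment cutoff "at 26" is implemented as
*score < 26*, the standard MoCA convention. The outlier-sensitivity rule
is made explicit where the source procedure removed "one extreme case"
without stating a rule: flag every subject with log-lesion-volume z-score
above 4 (all of them, not exactly one), refit, and always report both
fits. The phase-group model is unadjusted (no age/sex covariates), matching
the stated model; covariates can be added by the caller on the cohort
table.

## What the synthetic cohort emulates

The generator builds a desk-scale world shaped like the study it emulates:
a 32×32×32 grid of 2 mm voxels; two tube bundles (radius 4 mm, 30
streamlines per bundle per control) — one target, one background; 20
controls perturbed by rigid control-level (SD 0.5 mm) and streamline-level
(SD 0.4 mm) jitter; 102 subjects with 1–3 spherical lesions, radii
log-uniform on 2–10 mm so lesion sizes span two orders of magnitude; 35%
of subjects lesioned on the target bundle; age ~ N(66.3, 12.3) truncated
to 24–87, 25.5% female, phase groups drawn at the cohort's
acute/subacute/chronic proportions via simulated onset days against the
7/180-day thresholds. Cognition follows
`moca = clip(round(28 − 10·d + eps), 0, 30)` with `d` the true mean
disconnection of the target footprint and `eps ~ N(0, 1.5)`; six battery
subtests load negatively on `d` (loadings 6–12 points per unit
disconnection, residual SD 4) and are observed in an 80% subsample. The
slope, noise and on-target fraction were chosen so that roughly a third of
subjects fall below the impairment cutoff and the brain-behavior coupling
is strong, mirroring a cohort with a robust, clearly detectable effect;
the jitter SDs were calibrated once so that the truly-coupled halo around
the target stays close enough to the noise-free footprint for spatial
recovery (Dice ≥ 0.5) to be achievable at this scale, and were not revisited.

Everything is deterministic from one master seed via per-component derived
sub-seeds; the generator writes its ground truth (noise-free target
footprint — the visitation map of the unjittered bundle — and per-subject
true disconnection) so recovery tests have an oracle, and a manifest of MD5
hashes so a written cohort is tamper-evident and bit-reproducible.

What it deliberately does **not** emulate: realistic lesion shapes or
spatial priors (spheres suffice to exercise every operator), realistic
white-matter geometry, registration error, diffusion signal, or any
dependence of cognition on raw lesion volume. Consequently, passing the
recovery tests shows the *pipeline* recovers a planted effect under known
geometry at realistic n — it says nothing about sensitivity in real
cohorts, where effect sizes are smaller, geometry is shared across
networks, and registration noise is correlated with lesion size.

## Problem sizes and runtime choices

The shipped analyses use the study-shaped defaults: 102 subjects, 20
controls, ~1400-voxel analysis mask, 1000 permutations and 1000 bootstrap
resamples. The test suite exercises the same code at the same cohort scale
but with 200–500 resamples where only calibration or determinism (not
precision of a specific p-value) is at stake; permutation type-I
calibration uses 200 independent null datasets of 40 subjects × 500
voxels. The end-to-end pipeline caches each stage by content hash of its
inputs, and a cached rerun is verified byte-identical to a cold run.

## Known limitations

- Distance- or count-weighted disconnection, region-to-region
  disconnection matrices, and cluster-extent permutation inference are out
  of scope.
- The streamline-intersection test is exact only up to chords shorter than
  the resampling step (see above).
- Nonrotated PLS here covers the fixed-contrast behavioral case only; no
  rotated (SVD) or mean-centered group-contrast variants.
- TRK reading requires a version-2 header with a usable `vox_to_ras`
  affine; files without one (all-zero affine) are rejected rather than
  guessed at.
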