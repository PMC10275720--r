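---
title: "Mapping DBS outcomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping DBS outcomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models it implements,
the parameters that matter, what the synthetic generator does and does
not emulate, and the numerical choices made where the design was open.
It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The two statistical models

**Sweetspot (T-model).** The clinical outcome is the percentage
improvement on a severity rating scale, `100 * (pre - post) / pre`;
worsening yields a negative value and is used as such — weights are
signed and uncapped. Every binary stimulation volume is weighted by its
patient's improvement, and at each voxel the improvements of the
*covering volumes only* are tested against zero with a one-sample t-test
(`t = mean / (sd / sqrt(n))`, n−1 denominator). Non-coverage is treated
as missing, not as an implicit zero: if it were zero, the coverage gate
below would serve no statistical purpose. The null hypothesis at each
voxel is that stimulating it is unrelated to outcome.

*Coverage gate.* A voxel enters the model only when its coverage is
**strictly greater** than `min_coverage * n` volumes (default fraction
0.2; with n = 20 this is the "more than 4 patients" rule). The two
plausible readings of a 20 % exclusion rule — `>=` versus `>` at the
boundary — differ for exactly 4 of 20; we adopt the strict reading,
which is the more explicit of the two conventions this analysis family
uses. A t-score additionally needs at least 2 covering volumes; with
n ≥ 5 and the default fraction the strict gate already guarantees this.

*Scoring and validation.* A patient's score is the sum of t over the
included voxels inside their volume (signed t, not only positive t —
penalizing overlap with reliably-harmful voxels is part of the model).
The validation correlates scores with improvements. Because the map is
fit on the same improvements it is scored against, the permutation test
recomputes the *entire* statistic under every shuffle of the
improvements: re-weighted t-map, new sum-of-t scores, null correlation.
Observed and null values then share the in-sample circularity and the
test is exact under exchangeability. (Permuting against a fixed map is
anti-conservative here: on null cohorts it rejects at ~8× the nominal
rate, which is why the fixed-map shortcut is not offered.) The p-value
is one-sided for a positive correlation — the model's hypothesis is that
more overlap with the high-t region predicts more improvement — and uses
the add-one rule `p = (1 + #{null >= observed}) / (1 + n_perm)`, so p is
never zero. Display thresholding (e.g. t ≥ 3, or the upper quartile of
positive t used by `sweetspot_cog()` callers) is a reporting choice,
never part of scoring.

**Network model (R-map).** Each patient's stimulation volume, resampled
to the connectome grid by nearest neighbour, seeds a connectivity
fingerprint: in every connectome subject, the Pearson correlation of the
seed-average BOLD course with every in-brain voxel's course; the
per-voxel average over subjects is then Fisher-Z transformed.
Average-then-transform is deliberate (it is how this analysis family
defines the group fingerprint) even though transform-then-average is the
more common statistical convention; `group_fingerprint(order =
"z-then-average")` provides the alternative. The R-map is the voxel-wise
Pearson correlation, across patients, between fingerprint values and
improvements; voxels with zero across-patient variance are excluded.
Spatial similarity between a fingerprint and the R-map is a plain
Pearson correlation over all jointly included voxels — no gray-matter
restriction and no suprathreshold masking, since nothing in the model
requires one. Validation again recomputes R-map and similarities under
every permutation. A leave-one-out variant (`loo_similarities()`) exists
as a stricter optional check; it is not the default procedure.

## Stimulation-volume model

The electric field of an active contact is modeled analytically as a
spherical source in a uniform medium, replacing a finite-element solve
of the static Laplace equation whose scientific contract here is only
the thresholding step:

* current mode: `|E|(r) = I / (4 pi sigma r^2)` with I in mA, r in mm and
  sigma in S/m (default 0.14) — these mixed units cancel to V/mm exactly;
* voltage mode: `|E|(r) = V r0 / r^2`, the field of a sphere of radius
  `r0` held at potential V. `r0` defaults to 0.635 mm, a typical DBS
  contact radius, and is configurable.

Multi-contact configurations superpose *vectorially* with polarity signs
(physics of linear media), and inside the contact sphere the magnitude
is held at its surface value. The stimulation volume is the set of
voxels with `|E|` **strictly above** 0.2 V/mm; a field of exactly
0.2 V/mm does not activate. Left and right volumes combine by voxel-wise
union. Heterogeneous or anisotropic conductivity, encapsulation layers
and axon models are out of scope. Both stimulation modes are supported
per patient; clinical cohort tables often omit which controller type
each implant used, so the generator defaults to voltage control.

*Oracle.* The tests check the analytic model against a brute-force
finite-difference Laplace solve on a 41³ grid (h = 2 mm): a single
Dirichlet node at the centre, grounded boundary, Jacobi iteration. A
discrete point source has a known effective electrostatic radius,
`h / (4 pi G0)` with `G0 = 0.252731` the simple-cubic lattice Green's
function at the origin — 0.630 mm here, matching the model's default
contact radius. The comparison takes |E| from the FD potential by
4th-order central differences and restricts itself to the 10–20 mm
annulus (5h–10h): closer in, the oracle's own lattice-discretization
error exceeds the 5 % tolerance; further out, boundary-image effects do.
These bounds are properties of the oracle's validity, not a loosened
tolerance — inside the annulus the maximum relative deviation must stay
below 5 %.

## Connectome preprocessing

Stage order: motion QC → motion regression → spatial smoothing →
temporal filtering → nuisance regression → matrix extraction.

* **Framewise displacement** uses the Power convention — the sum of
  absolute backward differences of the three translations plus 50 mm
  times the sum of absolute rotation differences (radians as arc length
  on a 50 mm sphere); FD of the first volume is 0. The exclusion
  criterion is strict on both boundaries: a subject is dropped iff FD
  **> 0.5 mm** in **> 50 %** of volumes, so a subject sitting exactly on
  either limit is retained.
* **Motion regression** residualizes every voxel against an intercept, a
  linear trend and the 6 motion parameters (no derivative/expansion
  terms — the minimal model the criterion implies), re-adding voxel
  means. Collinear columns (e.g. an all-zero trace) are dropped with a
  warning.
* **Smoothing** is a separable Gaussian with FWHM 6 mm
  (`sigma = fwhm / (2 sqrt(2 ln 2))`), converted to voxels per axis from
  the affine, kernel truncated at 4 sigma and renormalized at grid edges
  so constants are preserved exactly.
* **Temporal filtering** is a second-order Butterworth band-pass at
  0.01–0.08 Hz applied forward–backward (zero phase). The printed
  cutoffs are, by the Butterworth definition, the −3 dB points of the
  *single-pass* design; the zero-phase application squares the magnitude
  response, so the pipeline's effective attenuation at the cutoffs is
  −6 dB. The acceptance measurement therefore characterizes the
  single-pass response. Per-voxel means are re-added after filtering.
* **Nuisance regression** removes the mean CSF course, the mean WM
  course and, by default, the global (whole-brain-mask) mean. The
  global-signal flag defaults to on because the procedure this package
  implements states that global-signal regression was performed; it
  remains a flag because the literature treats it as a variant. Nuisance
  regression runs *after* temporal filtering, following the stated stage
  order; the known mismatch (unfiltered regressors can reintroduce
  filtered frequencies) is inherited deliberately rather than "fixed".
* **Matrix extraction** stores in-mask voxels × volumes with rows in the
  grid's native raster order (x fastest), making volume ↔ matrix round
  trips exact.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has planted ground truth.

*Cohort.* A phantom atlas holds mirror-symmetric ellipsoidal "pallidal"
targets on a 48×56×48, 2 mm grid. A 4 mm sphere planted at the
right target centre (21, −7, −5) mm defines the true sweetspot;
`improvement = max_improvement × (covered fraction of the sphere) +
N(0, noise_sd)`, by default 60 % maximal effect and 10 % noise — chosen
so the cohort's improvement distribution (mean ≈ 17–24 %, sd ≈ 16–30 %,
including worseners; no clipping) resembles a realistic pediatric
dystonia cohort. Coverage is measured on a 1 mm sub-grid of the sphere
through the analytic field, keeping it effectively continuous: the
2 mm-voxel fraction quantizes to steps of ~1/33, and at `noise_sd = 0`
those ties produce zero-variance voxel samples (sentinel t-scores) that
have no analogue in continuous data. Electrodes have 4 contacts at 2 mm
pitch; the planted side draws targeting jitter (sd 2 mm), amplitude
U(2, 5) V and a random active contact per patient, while the
contralateral electrode is held at fixed cohort-standard settings
(middle contact, 3 V). Holding the reference side fixed keeps the
planted association unilateral and identifiable: with all-positive
improvements (the noise-free case), mirror-hemisphere voxels covered by
outcome-*independent* but *variable* stimulation acquire t-scores
comparable to the true sweetspot's, and no improvement-weighted
statistic could then meet a parameter-recovery contract. Pre/post
severity scores are drawn around 71.7 ± 26.5 points and made exactly
consistent with the improvement.

*Connectome.* 24×28×24 voxels at 3 mm, concentric ellipsoidal tissue
zones (CSF core, WM shell, gray matter), `n_networks = 3` planted
networks as Gaussian blob pairs in gray matter (network 1 sits on the
bilateral pallidal stand-in so stimulation seeds engage it), smooth
latent time courses (Gaussian-filtered white noise, so the band-pass
retains them) against white voxel noise, injected CSF/WM/global courses,
a motion-coupled artifact, and motion traces in which subjects with
index < `n_violators` exceed FD 0.5 mm in 70 % of volumes while all
others stay ≤ 0.2 mm. Defaults (20 subjects, 120 volumes, TR 2 s,
amplitude 3, noise 1) keep a single subject's preprocessing around a few
seconds.

*Not emulated:* anatomy, hemodynamics, scanner artifacts, spatial
normalization error, electrode localization error. Passing the planted
tests therefore shows the *statistics and preprocessing* behave as
specified, not that the pipeline is robust to registration or
acquisition pathology in real data.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based; the affine maps voxel to world mm (NIfTI
  convention); out-of-footprint voxels resample to 0 so masks stay
  binary; nearest neighbour is mandatory for masks.
* Zero-variance t samples: t = 0 when the mean is also 0, otherwise a
  signed sentinel of magnitude 1e6 flagged `degenerate` (constant
  non-zero samples must outrank any finite t).
* `fisher_z` clamps |r| ≥ 1 to ±(1 − 1e−7) with a warning; constant
  BOLD voxels get fingerprint r = 0 with a flagged count rather than NA.
* Permutations are independent uniform shuffles (not exhaustive), seeded;
  every generator consumes its own seed via a save/restore wrapper, so
  library calls never disturb the caller's RNG stream.
* Problem sizes in the test suite (chosen as the smallest that exercise
  each property cleanly): micro-cohorts of 8–10 patients on 8³ grids for
  brute-force oracle equivalence (tolerance 1e−10); the full 20-patient
  default cohort for planted recovery; 250 null replicates (n = 20,
  199 permutations) for type-I calibration of the fixed-scores engine
  and 120 null micro-cohorts for the refitting validators, with the
  acceptance band 0.02–0.09 at nominal 0.05; 6–12 connectome subjects
  for network separability checks.

## Known limitations

* The analytic field model ignores tissue heterogeneity and electrode
  geometry beyond spherical contacts; absolute volumes are therefore
  approximate even though the 0.2 V/mm thresholding contract is exact.
* The in-sample design (map fit and validated on the same cohort) is
  inherited by construction; the whole-statistic permutation controls
  validity, not optimism of the effect size. `loo_similarities()` offers
  an out-of-sample check for the network model only.
* The connectome stage consumes motion parameters as given;
  slice-timing, realignment and normalization are out of scope.
* With heavy-tailed improvement noise the sum-of-t validation loses
  power long before the COG estimate degrades; the two diagnostics are
  deliberately reported together.
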