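---
title: "Trajectory-shape analysis of markerless upper-limb motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-shape analysis of markerless upper-limb motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajkin)
```

## The problem

Depth cameras report a crude stick skeleton: ~20 joint centres at 30 Hz, no
segment orientations, centimetre-level jitter, occasional tracking loss.
Rehabilitation exercises recorded with them are minutes long, non-cyclic and
free-form, so the classic gait-lab toolchain (cycle normalisation, joint-angle
curves) does not transfer. `trajkin` instead summarises each joint's
*trajectory as a geometric object* — its length, swept angle, velocity
distribution, principal-axis extents, best-fitting sphere and reachable-hull
workspace — and compares those summaries between a patient and a reference
population as dimensionless ratios.

This vignette documents the model, the conventions chosen where the method
leaves them open, the numerical safeguards, what the synthetic generator does
and does not emulate, and the problem sizes used by the test suite.

## From stream to relative trajectories

**Frame timing.** Sequences are modelled at fixed frequency: frame `i` lives
at `(i-1)/f` s. Irregularly-timestamped input should be regularised with
`resample_sequence()` first; all hodograph formulas assume constant `f`.

**Units.** Everything is metres internally. Readers convert from declared
mm/cm; the 41-parameter vector converts to reporting units (mm, cm², cm³,
deg, m/s, deg/s, sr) only at assembly.

**Gaps.** Trackers drop joints. Runs of at most `max_gap` missing frames
(default 5, ≈0.17 s at 30 Hz — our choice, conservative against inventing
motion) are filled by linear interpolation per coordinate; longer runs, and
runs touching either end of the recording, are data-quality errors rather
than silently fabricated data.

**Segment-length correction.** The stick model's *directions* are usable but
its link lengths breathe with depth noise. Per-subject reference lengths are
the median child–parent distance over three static poses (T, wide, upright;
3 s each). Motion frames are then rebuilt root-outward: each child is placed
at `parent + L_ref · unit(child_raw − parent_raw)`. The operation is
idempotent and preserves directions exactly. A zero-length raw link in a
frame carries the previous frame's direction (an error in the first frame,
where no direction exists).

**Local coordinate systems.** Nineteen segment LCSs are built per frame.
The construction is configuration data (`default_lcs_convention()`), not
code, because a sparse 20-point skeleton cannot realise full anatomical
frames: per LCS we take Y along the segment's longitudinal axis
(distal→proximal), a plane-reference vector W (shoulder line for axial
segments, trunk line for arm segments), X = unit(Y × W) and Z = X × Y. This
is ISB-*compatible* (Y proximal, X anterior in the neutral pose) and, being a
table, swaps cleanly to a 25-joint vocabulary or an alternative numbering.
The child/parent topology is likewise a shipped CSV with 17 entries; the
mapping of origin numbers to joints is deliberately overridable because the
published numbering is ambiguous between its table and its text.

Relative trajectories are `p_i = R_parentᵀ (o_child − o_parent)` per frame.
Because both origins and orientation rotate with the subject, relative
trajectories are invariant under rigid transforms of the whole scene — the
property the test suite checks with random rotations/translations at 1e-9 m.

## The 41 parameters

For one trajectory `p_1..p_N` at frequency `f`:

- **1–9, hodograph.** Speeds are forward differences `v_i = f‖p_{i+1}−p_i‖`
  (the source formulas fix only the shape of the speed series, not the
  differencing scheme; we repeat the last value so the series has length N).
  Travel is the cumulative chord sum. Swept triangle areas
  `S_i = ‖p_i × p_{i+1}‖/2` give per-step angles
  `α_i = arcsin(h_i/‖p_{i+1}‖)`, `h_i = 2S_i/‖p_i‖`; the arcsin argument is
  clamped to ±1 against floating-point overshoot, and the construction caps a
  single step at 90° — faster steps are under-counted, which we document
  rather than correct. Parameter 9 is the radius-based mean angular velocity
  `(180/π)·V_mean/mean‖p_i‖`. A point exactly at the parent origin makes the
  ray angle undefined and is an error.
- **10–30, principal axes.** The cloud inertia is the point-mass form
  `I = Σ (qᵀq)E − qqᵀ` (the literature formula as printed is dimensionally
  inconsistent; this is the standard reading). The first axis G1 is the
  *minimum-inertia* (maximum-spread) eigenvector — equivalently the leading
  covariance axis. G2 = unit(p_mean × G1) ties the second axis to the line of
  sight from the parent origin; G3 completes the right-handed triad. When
  p_mean is parallel to G1 (or near zero) G2 is undefined; a deterministic
  smallest-component perpendicular is substituted and the result flagged.
  Signs are fixed (largest-magnitude component of G1 positive) so results are
  reproducible. Extents are min/max projections; end points, angles of view,
  axis sizes, rhomboid area `L₁L₂/2` and diamond volume `SL₃/3` follow.
- **31–37, sphere fit.** Kåsa algebraic least squares (a 4-unknown linear
  system) initialises a geometric Levenberg–Marquardt refinement of
  `‖p_i − c‖ − r`. Parameter 33 is the mean *absolute* radial residual,
  34 the standard deviation of signed residuals. A coplanar or collinear
  cloud makes the system singular: the fit is flagged `degenerate` and the
  radius reported as `NA`, never as a silently huge number — planar wrist
  trajectories are common in practice. (The radius is reported in mm; the
  source table prints "deg" for it, which we treat as a typo.)
- **38–41, workspace hull.** The 3D convex hull is built by incremental
  insertion with outward-oriented facets (implemented in the package; no
  suitable hull library is available in the target environment). Surface area
  is the facet-area sum. The conic volume with apex at the parent origin is
  the *signed* accumulation of origin-apex tetrahedra, which telescopes to
  the enclosed hull volume for any apex position — this reproduces the
  shifted-unit-cube check (area 6, volume 1). The sphere solid angle is the
  closed-form cap `2π(1−√(1−(r/d)²))` for centre distance `d > r`, else the
  full sphere 4π. The surface solid angle sums unsigned van
  Oosterom–Strackee angles over origin-facing facets, capped at 4π; an
  origin strictly inside the hull subtends exactly 4π and is reported as
  such. Coplanar clouds yield the planar 2D hull area, zero volume, and a
  `degenerate_coplanar` flag.

The total swept area `Δ_N = ΣS_i` is computed and exposed as an attribute of
the feature vector but is not one of the 41 parameters: the standard panel
has no trajectory-area row (its areas are the rhomboid and hull surfaces).

Degenerate geometry never poisons the vector: affected entries are `NA` with
a parallel flag channel, and scoring excludes flagged entries from
aggregates with a warning.

## Scoring

The per-parameter score is the ratio `s = p_reference / p_patient`, so 1 is
"matches the reference" and values above 1 mean the patient under-performs
on magnitude-type parameters. Raw ratios are kept for longitudinal tracking;
the display channel clamps to ±100% for the star plot. Aggregates are
weighted means — per trajectory over a parameter selection, per star sector
over trajectories, per Ang/Len/Vol group, and one total score. All weights
default to 1: no weight values are published for this method, so the package
ships the unweighted mean and accepts user tables.

The 17-parameter star panel itself is also unpublished; the shipped default
(angular {2, 6, 9, 12, 13, 40}, length {1, 3, 5, 14, 15, 32}, volumetric
{10, 11, 31, 38, 39}) is an editable CSV asset chosen to cover each family
with positive, magnitude-like parameters. Signed coordinates (16–30, 35–37)
are excluded by default because a ratio of signed coordinates is not a
meaningful score; they can be opted in explicitly.

Contralateral scoring reuses the machinery with the unaffected limb's
features as the reference after mirroring the `_l`/`_r` labels; swapping
the roles of the two sides inverts every raw score.

## Validation statistics

Device agreement uses Pearson's R, the reproducibility coefficient
RCP% = 100·1.96·SD/base and the coefficient of variation CV% = 100·SD/base.
The published description fixes neither the SD's argument nor the percentage
base; we default to the method-comparison convention — SD of the paired
differences over the pooled mean — with a `basis = "values"` switch. Group
comparison is one-way ANOVA plus all pairwise pooled-variance t tests with
multiply-and-cap Bonferroni correction and significance flags at α = 0.05.
Shapiro–Wilk is delegated to `stats::shapiro.test()` behind input
validation.

## The synthetic generator

`generate_wipe_sequence()` emulates the screen-wiping exercise: the trunk
stands still while each wrist traces a frontal-plane Lissajous path relative
to its shoulder, the elbow placed by two-link inverse kinematics (0.30 m
upper arm, 0.25 m forearm, downward bend). Defaults are the study
conditions: 30 Hz, 60 s trials, amplitudes 0.18 m (mediolateral) × 0.12 m
(inferior–superior) at 0.25/0.5 Hz, isotropic Gaussian jitter of 5 mm per
joint per frame, and group speed scales 1.00/0.57/0.43 for
adult/elderly/stroke-like cohorts — the ratios of typical wrist velocities
reported for those populations (≈0.23/0.13/0.10 m/s) — with mild workspace
shrinkage (×0.9/×0.8) and seeded lognormal between-subject variability
(15% speed, 10% amplitude).

A Lissajous path was chosen over recorded-data playback because it has
closed forms: the tests check the generated wrist travel against an
independent quadrature of the programmed path speed, and a degenerate
(single-axis) recipe against a line-segment cloud. The noise model is
deliberately simple — i.i.d. Gaussian, no temporal correlation, no soft
tissue, no pathological synergies, no tracking dropouts. Passing tests on
this generator therefore demonstrate pipeline correctness, *not* clinical
validity on real recordings; group differences are encoded purely as
speed/amplitude scaling.

## Numerical choices and limitations

- Visibility and degeneracy tests in the hull use tolerances scaled by the
  cloud diameter (1e-9 relative); orientation matrices are validated to
  1e-9; oracle-equivalence tests run at 1e-12 relative (1e-9 for the
  view angles, whose arccos amplifies rounding near collinear end points).
- Eigen-decomposition ties (isotropic clouds) and the G2 fallback are
  resolved deterministically and flagged.
- The per-step 90° cap in the swept-angle formula under-counts very fast
  rotations between frames; at 30 Hz and physiological speeds this is
  negligible, but the limitation is inherited from the formula.
- Smoothness metrics (normalised jerk) and frequency-domain descriptors are
  out of scope, as are live capture, C3D parsing and anthropometric
  skeleton reconstruction beyond the link-length correction.

## Problem sizes in the test suite

The suite keeps runtimes in tens of seconds by choosing desk-scale sizes:
oracle equivalence on 100 random clouds of N ≤ 50; geometry fixtures of
10²–10³ points; power checks on 20 synthetic cohorts of n = 16/17/10
subjects with 10 s trials and null checks on 50 cohorts of n = 6 with 8 s
trials (mean speeds are time averages, so shorter trials change estimator
noise only marginally); the acceptance script uses one 30 s trial. These
sizes are the package's own defaults for its checks, chosen to exercise
every code path with comfortable statistical margins.
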