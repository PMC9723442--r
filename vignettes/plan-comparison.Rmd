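---
title: "Single vs double planning for bilateral lung SBRT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single vs double planning for bilateral lung SBRT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrteval)
```

## The problem

A patient presents with one peripheral lesion in each lung, both to be
treated with SBRT to 50 Gy in 5 fractions, prescribed to roughly the
70% isodose line. On a robotic platform there are two ways to plan
this:

* **Plan S (single planning)** — combine both planning target volumes
  (PTV1 ∪ PTV2 = PTV12) and optimize one plan covering both;
* **Plan D (double planning)** — optimize each target in its own plan
  and superimpose the two dose distributions.

`sbrteval` implements the full evaluation methodology needed to compare
the two arms: DVH computation and metric extraction, target-centric
quality indices, fractionation-corrected gEUD, constraint auditing, and
a paired cohort comparison — plus a synthetic phantom cohort so the
pipeline is exercised end-to-end without clinical data.

## Voxel model

Dose grids and masks are point samples at voxel centers; a voxel
belongs to a structure iff its center is inside the contour solid, with
no partial-volume weighting (error bounded by the voxel size). Indices
are (x, y, z) with physical position `origin + (index − 1) × spacing`
(mm); doses are 64-bit doubles in Gy, volumes in cc.

Two deliberate strictness choices:

* `sum_doses()` **never resamples silently** — superposition of the
  double-plan components is only legal on an identical geometry, and
  `resample_like()` (trilinear, zero-filled outside the source extent)
  is a separate, explicit step. Dose summation correctness must be
  auditable.
* "receiving x Gy" is the **closed** comparison `dose ≥ x`, and
  V~<x~ is its strict complement, so `Vx(cc) + V<x(cc)` equals the
  structure volume exactly, and a target voxel exactly at the
  prescription counts as covered.

## DVH and metric conventions

Cumulative DVHs are exact voxel-counting histograms (default bin width
0.01 Gy). Every reported metric is computed from raw voxel values, not
from bins: D~max~/D~mean~/D~min~ are true voxel statistics (not D2%/D98%
surrogates), V-queries are voxel counts, and D~x cc~ sorts the
structure's voxel doses descending, accumulates volume in voxel steps
and interpolates linearly between voxel boundaries — voxel-exact at
integer multiples of the voxel volume, with ties broken by linear index
for reproducibility. Queries larger than the structure volume are
errors, not extrapolations. DVHs round-trip through a plain-text CSV
(`write_dvh_csv()`), and gEUD can be computed from the CSV alone.

## Plan-quality indices

The published index families for CyberKnife-style SBRT do not always
print their formulas, so the conventions were chosen to satisfy the
printed arithmetic of the reference cohort bundled in
`reference_cohort_summary()`:

* **HI = D~max~/PD.** Every printed HI cell equals its printed
  D~max~/50 at two decimals (e.g. 70.21/50 = 1.40, 74.42/50 = 1.49),
  which rules out D2%/D98% forms. PIDL = 100·PD/D~max~ is its exact
  reciprocal, targeted at ~70%.
* **CI = PIV/TV~PIV~ and nCI = (TV·PIV)/TV~PIV~²** — the
  CyberKnife/MultiPlan convention, under which nCI = CI ÷ coverage
  fraction exactly. The printed triples satisfy this identity
  (1.20/0.9632 → 1.25; 1.14/0.9558 → 1.19; 1.19/0.9618 → 1.24) and
  would not under an RTOG CI = PIV/TV with a Paddick nCI. The identity
  is asserted on every evaluated plan in the test suite.
* **GI = V~50%PD~/V~PD~** over the body mask (Paddick gradient index);
  the half-maximum variant is available via `gi_reference = "maximum"`
  but the prescription-based form matches the 5–6 range of the
  reference cohort and is the shipped default.
* PIV for Plan D is computed on the **superimposed** dose, not per
  component, because the clinical question concerns the combined
  distribution.

Indices are kept at full precision internally; printing rounds to two
decimals to mirror clinical tables.

## Radiobiology

The gEUD is the phenomenological (Gay–Niemierko) power mean

$$EUD = \Big(\sum_i v_i\,EQD_i^{\,a}\Big)^{1/a},$$

over differential-DVH bins with fractional volumes $v_i$, after
converting each bin's total dose to its 2 Gy-per-fraction equivalent

$$EQD = D\,\frac{\alpha/\beta + D/n_f}{\alpha/\beta + 2},$$

assuming the total dose is delivered uniformly over $n_f = 5$
fractions (single-course SBRT; no per-fraction data exist). Shipped
parameters: PTV (a = 10, α/β = 10), lung (1, 4), heart (3, 3.7),
spinal cord (20, 3), esophagus (16.67, 4.9).

Three consequences worth making explicit:

* the tabulated **tumor exponent is positive** (a = +10), which makes
  the target gEUD hot-spot-seeking rather than cold-spot-penalizing;
  the tumor-conventional negative exponent is available via
  `tumor_a_negative = TRUE`, but the default follows the tabulated
  parameters as printed;
* **trachea and bronchus get no gEUD** — no accepted parameter values
  exist for them, and `eud_params_for()` refuses rather than guessing;
* zero-dose bins with a negative exponent are floored at 10⁻⁶ Gy to
  keep the power mean finite (irrelevant for the all-positive shipped
  parameters); the power mean itself is evaluated in log space so
  a = ±20 is numerically safe.

The binned path (0.01 Gy) agrees with the unbinned voxelwise path to
better than 0.1% in the test suite; `geud_from_doses()` keeps the
voxelwise route available for validation.

## Constraint audit and statistics

`default_constraints()` encodes the 50 Gy/5 fx planning objectives
(target coverage ≥ 95%, lungs V5 < 60% and V20 < 25%, protected-lung
volumes, heart/cord/trachea/bronchus/esophagus maxima and hot-volume
limits). Comparators are strict as written — a cord D~max~ of exactly
27 Gy fails "< 27 Gy" — except the ~70% PIDL objective, which is a
soft band (±10 points by default). Missing structures yield
"not evaluable" rows, never crashes.

The cohort comparison uses the classical paired t on per-patient
differences with two-sided p values (matching the magnitudes of the
published p's), sample SD (n − 1), significance flagged at p < 0.05,
and no multiple-testing correction — mirroring the reference analysis;
`glance()` reports how many tests were run so a reader can apply their
own correction. All-equal differences give a flagged undefined t, not
±∞. `stats::t.test()` serves as an independent oracle in the tests;
the implementation itself is the closed form.

## The synthetic cohort: what it states and what it cannot show

`generate_cohort()` builds seeded bilateral thorax phantoms: body and
lung ellipsoids, a heart between the lungs, cord/trachea/bronchus/
esophagus tubes, and one spherical GTV per lung expanded isotropically
by 5 mm to its PTV. PTV volumes are drawn log-uniformly within the
clinically observed ranges (1.67–62.31 cc left, 4.49–26.21 cc right, a
heavy-tailed spread compatible with the published medians); targets are
placed peripherally, fully inside their lung, and are always disjoint.
Default grid: 2.5 mm isotropic voxels.

The dose model is a phenomenological kernel, not a beam model — the
analysis needs DVH structure, not physics. Per target: a hot core at
PD × peak over the inner 30% of the PTV radius, a Gaussian ramp that
meets exactly PD at the PTV surface (emulating prescription to the
~1/peak isodose surface), and a Gaussian shell
`exp(−(r − R)²/(2σ²))` beyond it; plus a low-dose bath over the body
(apodized toward the surface) and Gaussian noise clipped at 0 Gy. With
zero noise, coverage is exactly 100% and PIDL is exactly 100/peak —
two closed-form limits asserted in the tests. An earlier flat-plateau
interior (PD × peak across the whole PTV) was rejected because it
produces conformity indices of 3–6 and target mean doses near 72 Gy,
unlike any plan prescribed to a 70% line.

The arm contrast is **stated, not fitted**: Plan D uses a steeper
falloff (σ = 5.5 vs 7 mm), a smaller bath (2.5 vs 3.5 Gy, split evenly
between its two component plans so each component is a valid plan),
and a slightly hotter peak (1.46 vs 1.40 — the printed HI means of the
two arms, reflecting that superimposing two component backgrounds
heats the targets). Each patient's single-plan dose and double-plan
components derive from one child seed, and the double-plan total is
produced by the package's own explicit `sum_doses()` step.

A green end-to-end test therefore establishes that the *pipeline*
reproduces the directional findings this world encodes — double
planning lowers GI, lung V5/V20 and organ-at-risk gEUDs while slightly
heating the targets, with every plan passing the constraint audit and
≥ 95% coverage. It does **not** establish the published per-patient
magnitudes (those depend on ten real anatomies and a commercial
optimizer and are out of reach by construction), and because the
phantom anatomy is fixed across patients (only targets and noise
vary), between-patient variance of organ-at-risk metrics is far
smaller than clinical — p values from the synthetic cohort are
demonstration output, not evidence.

## Numerical choices and degenerate inputs

* Geometry comparisons use a 10⁻⁶ mm absolute tolerance; any mismatch
  names the differing field (frame, dims, spacing, origin).
* A target with no voxel at the prescription dose makes CI/nCI
  undefined: flagged error, not NaN. Same for GI when no body voxel
  reaches the prescription dose.
* Empty masks are errors that name the structure.
* D~cc~ queries below one voxel volume return the hottest voxel's dose
  (no extrapolation above D~max~).
* DVH bin edges start at 0 with constant width; the first cumulative
  entry always equals the structure volume.
* `run_compare()` derives per-patient child seeds from one master seed
  via a seeded `sample.int()`; reruns are byte-identical, and report
  files embed the seed.

## Known limitations

* No DICOM I/O in this build — no DICOM-capable R package is available
  in the target environment; the native raw + JSON-sidecar format and
  the DVH CSV are the interchange paths. From DVH CSVs alone, all
  DVH-derivable metrics and gEUD are available, but grid-only
  quantities (PIV, CI, nCI, GI) are not.
* No TCP/NTCP modeling, no BED reporting, no alternative index
  families (CN, COIN, RTOG CI) — the nCI/CI conventions above were
  chosen because the reference arithmetic pins them down; others would
  not reproduce it.
* Lung metrics use the lungs as contoured; lungs-minus-PTV is
  available through `difference_masks()` but is not the default, as
  the reference convention is unstated.
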