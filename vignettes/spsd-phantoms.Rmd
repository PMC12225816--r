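---
title: "Stochastic parametric skeletal phantoms: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic parametric skeletal phantoms: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsd)
```

## The model

Internal dosimetry of active (red) bone marrow needs computational phantoms
that resolve the spongiosa microarchitecture, because for bone-seeking beta
emitters such as the strontium isotopes the electron mean free path in bone
(~1.3 mm) is comparable to cortical thickness, and the bone volume fraction
of spongiosa (BV/TV) controls both spongiosa density and the fraction of
energy absorbed in marrow. The stochastic parametric approach replaces
image-based cadaver models with a parametric one: each hematopoietic skeletal
site is divided into *segments* of near-uniform microarchitecture, each
segment is stylized by one of six geometric primitives (box, elliptic
cylinder, deformed cylinder, triangular prism, ellipsoid, tube), and its
interior is filled with rod-like trabeculae drawn from a stochastic process.
A segment record therefore consists of

* macro-architecture: the primitive and its linear dimensions (mm), plus a
  face-selective cortical thickness Ct.Th (mm) — cylinder bases are not
  covered, boxes and prisms may be covered on a subset of faces, and two
  parallel faces may carry different thicknesses;
* micro-architecture: BV/TV (fraction), mean trabecular thickness Tb.Th (mm)
  and separation Tb.Sp (mm), with intra-specimen variabilities
  `sigma_Tb.Th`, `sigma_Tb.Sp` (percent).

The shipped database holds 289 unique segment parameterizations covering
eight reference individuals (newborn, 1, 5, 10, 15 years and adult; the two
oldest ages sex-specific), the age-specific distribution of active marrow
over skeletal sites, elemental compositions, and media densities.

```{r census}
db <- spsd_db()
segment_count(db)
shape_census(db)
```

## Raw versus curated tables

The printed source tables contain typographic slips (a 240 mm clavicle
width, sternum plate heights one decade too small, a misspelled segment
name, stray upper-base axes on cylinder rows, a shifted ellipsoid row).
`spsd_db("raw")` reproduces the print; `spsd_db("curated")` applies the
correction list shipped as `curation.tsv`, where every entry records the
printed value, the curated value and its justification. The two modes differ
on exactly those rows, and `validate_db()` passes every internal-consistency
check only in curated mode.

Male and female tables of the sex-specific ages largely coincide;
`segment_count()` counts a record once when the full normalized parameter
set is identical between the sexes. Five print-identical pairs are
nevertheless flagged sex-specific in the curation table because the per-age
census printed in the source (18 + 18 sex-specific at 15 years, 24 + 24 for
adults, with fixed per-shape counts) requires it; the choice of rows among
the print-identical candidates follows sexual dimorphism (rib, cervical
vertebra and scapular dimensions) and is recorded as curation entries
C24–C28 rather than hidden in code.

## Voxelization and cortical shells

Phantoms are rasterized on isotropic grids by centre-point sampling (a voxel
belongs to the shape iff its centre does), which makes box volumes exact and
gives first-order convergence of voxel counts to the closed-form volumes for
the curved shapes. The working resolution is `0.7 * Tb.Th`, clamped to
40–250 µm (`default_voxel_size()`).

Cortical layers are grown inward from the designated faces, so printed
dimensions are outer dimensions. Both the voxel path and the analytic path
define the spongiosa as the erosion of the shape by the face thicknesses:
box and prism interiors shrink per face (the prism interior triangle is
computed from the three offset edge lines), the cylinder family erodes its
axes by twice the lateral thickness, the ellipsoid erodes all three axes,
and the tube erodes its outer wall only. Sharing one definition makes the
analytic closed forms an independent oracle for the voxel path: total
volumes agree within 2% at the default resolution for every record in the
database. For very thin plates the *split* between cortex and spongiosa is
bounded by the ±1-voxel realization of the shell rather than by a relative
tolerance — a 1.3 mm spongiosa slab sampled at 0.2 mm voxels can only be
resolved to one voxel layer — and the tests encode exactly that bound.

The deformed cylinder is interpreted as the ruled solid between two
parallel, coaxial elliptic bases whose axes interpolate linearly along the
height, giving the closed form `V = (pi h / 24)(2ab + 2cd + ad + cb)`; the
truncated cone is its circular special case. The source's remark about
perpendicular planes is read as describing the placement of the base axes,
not an axial twist; nothing in the printed dimensions could parameterize a
twist. Two adult clavicle rows print a deformed-cylinder shape code without
upper-base axes; they are curated to the degenerate equal-bases case.

## The trabecular generator

Spongiosa is filled with finite cylindrical rods: centres from a homogeneous
Poisson process, orientations uniform on the sphere, diameters lognormal,
lengths lognormal around `3 * Tb.Sp` with CV `sigma_Tb.Sp`. Overlapping rods
union, and rods are clipped at the spongiosa boundary; there is no rod–rod
exclusion. Three choices deserve explanation:

* **BV/TV is binding.** The triple (BV/TV, Tb.Th, Tb.Sp) over-determines a
  rod model. BV/TV drives dose formation, so the rod intensity is calibrated
  until the voxel-counted BV/TV matches the record's target within 2%
  relative; Tb.Th is enforced through the diameter distribution; Tb.Sp is
  emergent and only reported (a deviation beyond 25% of the nominal value
  raises a warning).
* **Calibration by monotone coupling.** Because converted-voxel count is
  monotone in the rod count, the generator draws the rod sequence once at an
  upper-bound intensity and keeps the shortest prefix whose count reaches the
  target — a bisection on intensity with shared randomness, in a single pass.
  The crossing rod is kept or dropped, whichever lands closer. If the
  tolerance cannot be met (granularity: each rod converts more than 2% of the
  target, as in sub-millimetre regions with thick rods) the generator fails
  naming the best achieved value.
* **Volume-weighted diameters.** Voxel morphometry measures thickness
  volume-weighted, so rod diameters are parameterized so that the
  *volume-weighted* mean equals Tb.Th (number-mean `Tb.Th * exp(-2 s^2)`
  with `s` the lognormal sdlog). Without this, a CV-22% diameter law would
  read ~10% thick.

Everything is reproducible from the seed: identical (record, seed,
voxel size) gives bit-identical label arrays.

```{r generator}
rec <- db$segments[grep("adult/male/Femur/Neck", db$segments$key), ]
ph <- generate_segment_phantom(rec, voxel_size = 0.15, seed = 42)
ph$generation[c("bvtv_target", "bvtv_measured", "rods_used")]
```

## Morphometry

`measure_morphometry()` verifies generated structure the way micro-CT
software would: BV/TV from voxel counts; Tb.Th and Tb.Sp as the mean local
thickness (diameter of the largest inscribed sphere through each voxel) of
the bone and marrow phases. The implementation uses an exact Euclidean
distance transform followed by sphere painting; balls provably nested in a
neighbour's ball are pruned, which leaves the result exact. Thickness is
reported as `2r - 0.5` voxels to compensate the half-voxel overshoot of
centre-to-centre distances, a constant calibrated on analytic cylinders.
Discretization sets the accuracy floor: at the default resolution trabeculae
are 1/0.7 ≈ 1.43 voxels thick, so thickness accuracy statements apply only
when trabeculae span at least ~2 voxels (the package tests use `Tb.Th / 5`
grids for those checks, where randomly oriented rods measure within 10%;
grid-aligned rods are the worst lattice case at up to ~1.5 voxels low).

## Inter-individual variability

`sample_cohort()` draws individualized parameter sets around a record:
linear dimensions normal and positively correlated (default: one shared
scale factor, i.e. correlation 1), Tb.Th and Tb.Sp lognormal with a negative
Gaussian-copula correlation (default −1, Spearman rank correlation −1),
Ct.Th an independent normal truncated at zero, BV/TV uniform in a
per-segment admissible band (default ±25% of the record value). Only the
correlation *signs* are established anatomically; the default magnitudes are
the extreme values, the simplest model consistent with those signs, and both
are configurable. The per-parameter CV magnitudes are placeholders: the
published per-segment inter-specimen CVs live in supplementary material not
shipped here, so cohort CV outputs should be read as methodology
demonstrations until real CVs are supplied via `variability_config()`.
Draws violating record invariants (non-positive dimensions, cortex
swallowing the segment) are resampled up to a bound, then fail loudly.
`cohort_media_cv()` evaluates media volumes per draw through the analytic
path only — no voxelization — so 10^4-draw cohorts take seconds.

## Aggregation, multiplicities and truncation

Segment media volumes (TBV = trabecular bone, CBV = cortical bone, BMV =
marrow) scale by two corrections before skeleton roll-ups: `n_s`, the number
of similar models in the skeleton (paired bones ×2, vertebra-level
multiplicities such as 2 transverse processes × 5 lumbar levels, 24 rib
models, and so on), and `k_s`, the truncation factor for segments modelled
as ≤30 mm fragments of larger structures (shafts, ribs, skull and iliac
plates). Neither is printed in the main source tables, so the shipped
defaults are anatomical estimates, stored per row and overridable in
`skeleton_totals()`: `k_s` for skull plates is the calvarial area over the
9 cm² modelled window (28 for the newborn rising to 72 for the adult, from
head circumference), rib `k_s` is mean rib length over 30 mm (1.5 to ~9),
shaft `k_s` is the unmodelled diaphysis length over 30 mm, and the adult
iliac ala uses the 91.2/9 ≈ 10.1 area ratio quoted in the source. With these
defaults the hematopoietic-skeleton totals land within roughly ±30% of the
published reference volumetrics; the tests assert the documented
order-of-magnitude claim (within a factor of two) plus exact linearity in
the multiplicities, and exact reproduction is explicitly not claimed.

Effective dose-forming parameters weight each site by its active-marrow
fraction and each segment within a site (or pooled site group, resolved by
marrow-volume share rather than an invented split) by its corrected BMV.
Effective Ct.Th uses area-weighted means over covered faces — the source
does not state whether its averaging is area-weighted or per-segment, and
area weighting was chosen because dose to marrow scales with the shared
interface; cortex-free segments contribute zero. With the default weights
the effective BV/TV decreases strictly from newborn to adult in both sex
chains, reproducing the expected age trend.

```{r effective}
vapply(c("newborn", "1y", "5y", "10y", "15y", "adult"),
       function(a) effective_parameters(db, a, "male")$bvtv, 1.0)
```

## Problem sizes used by the test suite

The suite regenerates every one of the 340 database rows in a cubic test
region of `min(8 mm, segment extent)` at the default resolution for the
BV/TV-recovery sweep (the calibration contract is region-size independent:
each rod converts far less than 2% of the target there), verifies
analytic-versus-voxel volumes for every record at default resolution,
and runs the thickness-accuracy checks on representative segments at
`Tb.Th / 5` grids in 6–8 mm regions. Cohort recovery uses 10^4 draws.

## Known limitations

* `n_s`/`k_s` defaults are estimates; skeleton totals inherit their
  uncertainty (by design, a factor-2 claim only).
* The rod process does not model plate-like trabeculae, anisotropy or
  connectivity; only the (BV/TV, Tb.Th-distribution) contract is guaranteed,
  and emergent Tb.Sp typically reads low against the nominal value.
* Whole-body assembly, radiation transport and dose factors are out of
  scope; the phantoms are per-segment label volumes plus skeleton-level
  summaries.
* Sub-2-voxel trabeculae (every record at the default 0.7 × Tb.Th
  resolution) are below the morphometric thickness floor; BV/TV is
  resolution-robust, thickness statements are not.
* The synthetic cohorts emulate inter-individual variability as correlated
  parametric scatter around the reference record; they do not emulate
  age-continuous growth, pathology, or covariance between different segments
  of one individual beyond the shared dimension factor.
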