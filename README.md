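# spsd — stochastic parametric skeletal dosimetry phantoms

`spsd` builds labelled voxel phantoms of hematopoietic bone segments for
internal dosimetry of active (red) bone marrow — the dose target for
bone-seeking beta emitters such as ⁸⁹Sr/⁹⁰Sr, whose electrons travel about
1.3 mm in bone, so dose to marrow is controlled by cortical thickness
(Ct.Th), by the bone volume fraction of spongiosa (BV/TV), and by segment
size. It is aimed at radiation dosimetrists and medical physicists who need
morphometrically explicit skeletal models with quantified population
variability, as an alternative to image-based reference phantoms.

The package ships a curated database of **289 unique bone-segment
parameterizations** for eight reference individuals (newborn, 1 y, 5 y,
10 y, 15 y ♂/♀, adult ♂/♀). Each segment is one of six geometric primitives
(box, elliptic cylinder, deformed cylinder, triangular prism, ellipsoid,
tube) with:

* linear dimensions *h, a, b* (+ upper-base axes *c, d* for the deformed
  cylinder), in mm;
* a face-selective cortical shell (cylinder bases are never covered; box and
  prism faces are designated *ha*, *hb*, *ab*, *abb*, … with per-face
  thicknesses);
* spongiosa microarchitecture: BV/TV, mean trabecular thickness Tb.Th and
  separation Tb.Sp, and their intra-specimen variabilities σ_Tb.Th, σ_Tb.Sp.

From a record the package rasterizes the shape at 0.7 × Tb.Th resolution
(clamped to 40–250 µm), grows the cortical shell inward, and fills the
spongiosa with rod-like trabeculae — a Boolean process of finite cylinders
with uniformly random orientations, lognormal diameters around Tb.Th, and
intensity calibrated so the voxel-counted BV/TV matches the record's target
within 2 % relative. Voxel morphometry (local-thickness Tb.Th/Tb.Sp,
BV/TV), correlated-parameter cohort simulation, skeleton roll-ups of media
volumes and masses, and active-marrow-weighted *effective* dose-forming
parameters complete the pipeline. See `vignette("spsd-phantoms")` for the
model, numerical choices, and limitations.

## Worked example

```r
library(spsd)
db <- spsd_db()                 # curated mode (print typos corrected)
segment_count(db)
#> [1] 289
shape_census(db)
#>   b   c  dc   p   e   t
#> 142  83  56   5   1   2

ph <- generate_segment_phantom("adult/male/Femur/Neck", db = db, seed = 42)
ph
#> <spsd_phantom> cylinder, 271 x 241 x 226 voxels @ 0.133 mm
#>   background 3197448 | marrow 7560788 | trabecular 1548594 | cortical 2453456
ph$generation$bvtv_measured     # calibrated to the record's BV/TV = 0.17
#> [1] 0.17
write_nrrd(ph, "femur_neck.nrrd")   # reproducible bit-for-bit from the seed
```

The femoral neck phantom above is a 30 × 36 × 32 mm elliptic cylinder with a
1.9 mm lateral cortex; trabecular voxels make up 0.17 of the spongiosa
(marrow + trabecular) voxels, i.e. exactly the record's BV/TV target.

Skeleton-level summaries:

```r
skeleton_totals(db, "newborn", "male")$totals
#>    tbv    cbv    bmv  spongiosa  total
#>   48.0   24.2   71.7      119.7  143.9    # cm^3, hematopoietic skeleton
vertebral_body_fraction(db, "adult", "male")
#> [1] 0.685                                 # body / whole lumbar vertebra
effective_parameters(db, "newborn", "male")$bvtv
#> [1] 0.3853                                # AM-weighted effective BV/TV
```

Effective BV/TV decreases strictly with age (0.385 at birth to 0.189 for
the adult male), reflecting the age trend of skeletal density; skeleton
totals depend on anatomical multiplicity/truncation defaults (`n_s`, `k_s`)
that are documented estimates, so they are order-of-magnitude summaries,
not reference values.

A thin command-line front end is installed at `inst/cli/spsd.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/spsd.R", package = "spsd"))')" \
    list --age newborn
```

with commands `list`, `generate`, `cohort`, `summarize`, `export-tables`,
`validate` (exit codes: 0 ok, 2 usage, 3 validation failure, 4 generation
failure).

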