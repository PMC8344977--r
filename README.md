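# peristroma

Quantitative spatial analysis of the tumor stroma for collagen-rich
(desmoplastic) cancers such as pancreatic ductal adenocarcinoma (PDAC),
built for researchers working with second-harmonic-generation (SHG)
collagen imaging and immunofluorescence cell masks. The package answers
three questions per image:

1. **How far does the tumor reorganise its surrounding collagen?** Fibers
   near a tumor-cell cluster align parallel to its borderline. `peristroma`
   delineates each cluster's *peritumoral stroma region* from the
   distance-resolved fraction of boundary-parallel fibers.
2. **How are T-cells distributed with respect to that region?** Area-based
   densities and distribution coefficients inside vs. outside the region.
3. **Does collagen alignment direct T-cell migration in vitro?** Track
   velocity and axial directionality versus matrix alignment.

## The model

The stroma around each cluster is split into 11 distance bands of width
*w* = 22.4 µm (the dataset's mean fiber length; 246.4 µm total range). Per
band, *R* is the fraction of fibers whose axial orientation is within 15°
of the local tumor-boundary tangent. With the plateau mean *R̄* taken over
the five outermost bands, each band's deviation is

    |R − R̄| / R̄

and the peritumoral extension is *w* times the length of the contiguous
run of bands (from the boundary outward) whose deviation exceeds 0.05.
T-cell occupancy of the resulting regions is quantified as

    density_r = 100 · tcell_area_r / area_r            [%]
    coeff_r   = (tcell_area_r / tcell_area_total) / area_r   [1/mm²]

and in-vitro directionality per track as Σ|Δy| / Σ|Δx| (1 = no preference
for the 90° matrix axis). Fiber populations are summarised by the five
collagen parameters: length, width, straightness, density, and the
alignment coefficient — the doubled-angle mean resultant length, 0 for
isotropic and 1 for perfectly parallel fibers.

All inputs are standard artifacts: single-channel PNG/TIFF binary masks,
CSV fiber tables (polyline vertices, or precomputed per-fiber summaries),
and CSV track tables. Seeded generators (`simulate_tissue()`,
`simulate_tcells()`, `simulate_tracks()`, `simulate_matrix()`) produce
synthetic datasets with known ground truth, so the full pipeline is
testable without raw microscopy.

## Worked example

```r
library(peristroma)

# synthetic PDAC-like image: one cluster, orientation change in 3 bands
spec <- tissue_sim_spec(true_extension_bands = 3, seed = 42)
sim  <- simulate_tissue(spec)

part <- delineate_regions(sim$tumor, sim$fibers)
part
#> stroma_partition: peritumoral extension 67.2 um (3 bands)
#>   pixels: tumor = 18672, peritumoral = 65226, distant = 402014,
#>           excluded = 0, beyond = 316904

part$profile
#> band_profile: 11 bands x 22.4 um, Rbar = 0.7466 (bands 7-11)
#>  band    n      R    ratio
#>     1 3000 0.8200 0.098312
#>     2 3000 0.8300 0.111706
#>     3 3000 0.8373 0.121529
#>     4 3000 0.7553 0.011697
#>     ...
```

The three innermost bands deviate from the distant plateau by more than
5%, so the peritumoral region extends 3 × 22.4 = 67.2 µm — exactly the
extension built into the generator. T-cells placed at 5% (peritumoral)
and 2% (distant) target density are recovered by the quantification:

```r
tc <- simulate_tcells(part, tcell_sim_spec(5, 2, seed = 42))
quantify_tcells(tc$mask, part)
#> T-cell quantification
#>   areas (mm^2): total 0.007009, peritumoral 0.002053, distant 0.004936
#>   density: peritumoral 5.174%, distant 2.018%
#>   coefficient (1/mm^2): peritumoral 7.383, distant 2.879
```

Unbiased persistent-random-walk tracks show no axial preference:

```r
ts <- summarize_tracks(simulate_tracks(track_sim_spec(n_tracks = 200,
                                                      bias = 0, seed = 42)))
median(ts$velocity_um_min)    #> 4.76  um/min
median(ts$axial_orientation)  #> 0.974 (1 = axially unbiased)
```

A thin command-line wrapper with `simulate`, `regions`, `tcells`,
`tracks` and `report` subcommands is installed at `inst/cli/peristroma`;
see `?peristroma_cli`.

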