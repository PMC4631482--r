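# mxmesh

Multi-crystal serial synchrotron crystallography at desk scale: scoring of
mesh-scan diffraction frames, heat-map ranking of collection positions,
simulation of partial rotation-wedge reflection datasets, hierarchical
cluster analysis of pairwise dataset correlations for isomorphous-subset
selection, reference-based resolution of merohedral indexing ambiguities,
and relative scaling, inverse-variance merging and quality statistics.

## Who it is for

People building or studying multi-crystal data-collection workflows —
where many small (or small-beam regions of large) protein crystals on one
cryocooled support each contribute a 10° wedge (100 images of 0.1°), and
the computational problem is to find the crystals, rank them, decide which
partial datasets are isomorphous enough to merge, and quantify the merged
result. The package contains the full computational chain plus a seeded
simulator of both frame stacks and reflection-dataset families, so every
stage can be exercised and property-tested without beamline data.

## The core algorithms

**Per-frame diffraction score.** On each frame, pixels are binned into
resolution shells of equal reciprocal volume; the background `B(h)` is an
iteratively sigma-clipped azimuthal mean (with a refinement pass that
excludes signal pixels and corrects the truncation bias); sharp rings
(ice/salt) are flagged by spike tests against moving-median references and
a fine 150-bin median scan; Bragg spots are 8-connected components above
`B + 4√B` passing size and eccentricity checks. The mean Bragg intensity
per shell, `Ī(h) = Σ(I − B)/N(h)`, is fitted by the Wilson-type model

    log Ī(h) = log k − 2 B s²  + log Σ_p(h),     s = h/2 = sinθ/λ,

with `Σ_p` a tabulated standard protein intensity curve, and the quality of
fit `CC_powder` is the correlation of observed and fitted log intensities.
The diffraction-strength score is

    score = max(CC_powder, 0) · Σ_h Ī(h) V(h),

zero whenever no spots are found.

**Dataset selection.** For partial datasets i, j, the Pearson correlation
`CC_I(i,j)` over their common unique reflections maps to the distance
`dist(i,j) = √(1 − CC²)`; average-linkage agglomeration produces a
dendrogram that is cut at `dist = 0.15`, and the best-populated cluster is
merged. Merohedrally ambiguous indexing choices are resolved against the
first dataset as reference before correlating, which prevents artifactual
twinning in the merge (checked with the Yeates H-test,
`α = ½ − mean |I₁−I₂|/(I₁+I₂)`).

**Merging statistics.** Completeness, multiplicity, `R_merge`,
`R_pim = Σ_h √(1/(n_h−1)) Σ_i |I_i − Ī_h| / Σ I`, `CC_1/2` over seeded
random half-splits, mean `I/σ`, and a Crick–Magdoff-style theoretical
anomalous diffraction ratio `⟨ΔF/F⟩`.

## Worked example

Score a simulated mesh frame, then run the whole workflow:

```r
library(mxmesh)

geom <- detector_geometry(30, 0.2, c(80, 80), 1.0, 160, 160)
frame <- render_frame(frame_recipe(n_spots = 150, spot_scale = 2e4,
                                   wilson_B = 20, seed = 1), geom)
dozor(frame)
#> <dozor_result> score = 2.663, 72 spots, CC_powder = 0.950, B = 14.5 A^2
```

The frame was simulated with a Debye–Waller B of 20 Å²; the fit recovers
14.5 Å² on this single frame (the median over seeds lands within ±15%),
`CC_powder = 0.95` says the resolution profile looks like protein, and the
score is the CC-gated, volume-weighted total mean Bragg intensity used to
rank mesh positions.

```r
report <- run_pipeline(pipeline_config(), seed = 11)
report
#> <pipeline_report> 6 x 5 grid, 10 positions planned
#>   merged 10 sets: completeness 98.9%, multiplicity 3.54, R_pim 0.0245, CC1/2 0.996
```

Ten planted crystals were found on the 6 × 5 mesh, all ten wedges survived
the cluster cut at 0.15 (one isomorphism class was planted), and the merge
reaches 98.9% completeness with `R_pim` 0.0245. `autoplot()` draws the heat
map, `plot_dendrogram()` the cluster tree, and `report_json()` serializes
the whole run.

The anomalous-signal estimator, for a 316-residue chain holding one Zn
(f'' = 3.9 e at the Zn K edge) and three Ca (f'' = 1.4 e):

```r
anomalous_ratio(316, data.frame(count = c(1, 3), f_pp = c(3.9, 1.4)))
#> [1] 1.965122   # ~2%
```

A thin CLI over the same functions lives in `inst/cli/mxmesh.R`
(`score`, `mesh`, `simulate-reflections`, `cluster`, `merge`, `run`).

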