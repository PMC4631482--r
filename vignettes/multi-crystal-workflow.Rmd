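---
title: "Scoring, clustering and merging multi-crystal diffraction data with mxmesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, clustering and merging multi-crystal diffraction data with mxmesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxmesh)
```

## The problem

Serial synchrotron crystallography collects small rotation wedges — here 10°
in 100 images of 0.1° — from many crystals held on one cryocooled support. A
low-dose mesh scan is rastered across the support first, every frame is
scored for protein diffraction, and the per-position scores form a heat map
from which collection positions are ranked and selected. Each selected
position then yields one partial reflection dataset. Because the crystals
differ in quality, scale, overall B factor and sometimes in unit-cell
detail, the partial datasets must be screened for mutual isomorphism before
merging: pairwise intensity correlations are turned into distances,
clustered hierarchically, and only the best-populated cluster is scaled and
merged into the final dataset. `mxmesh` implements this entire computational
chain at desk scale, together with a seeded simulator of both mesh-scan
frame stacks and families of partial reflection datasets that serves as its
test bed.

## The per-frame diffraction score

For a frame with detector geometry mapping pixel `(x, y)` to diffraction
vector length `h = 1/d = 2 sin(theta) / lambda`, the scoring chain is:

1. **Background.** Pixels are binned into resolution shells (by default 24
   shells of equal reciprocal volume, i.e. equal increments in `h^3`, so the
   shell volumes `V(h)` are uniform). Each shell's background `B(h)` is the
   iteratively sigma-clipped mean (reject above `mean + 3 sd`, recompute,
   until stable). A second pass re-estimates `B(h)` with all pixels above
   `B + 2.5 sqrt(B)` excluded (dilated by 2 px) and corrects the resulting
   upper-truncation bias analytically by `sqrt(B) * dnorm(2.5)/pnorm(2.5)`.
   Without this second pass, the flux of spots too faint to detect leaks
   into the background and flattens the high-resolution signal, biasing the
   fitted B factor upward by tens of percent.
2. **Ring and salt rejection.** The azimuthal mean of a protein frame varies
   smoothly with resolution; ice rings and salt diffraction are sharp. Three
   tests run against moving-median references: a spike in the clipped
   background, a spike in the *excess* mean (raw minus clipped — this is
   where narrow rings that sigma-clipping swallows reappear), and a
   fine-grained scan of per-bin pixel medians over 150 equal-`h` bins, which
   detects narrow annuli irrespective of the coarse shell layout. Flagged
   shells are excluded from the fit and the score. The excess test applies
   only at `h >= 0.2` (d < 5 Å): ice and salt powder rings live there, while
   at lower resolution the protein signal itself falls too steeply to pass a
   smoothness test.
3. **Spots.** Pixels above `B(h) + 4 sqrt(B(h))` (a Poisson noise model) are
   grouped into 8-connected components; components survive if they span 2 to
   100 pixels, have eccentricity at most 0.95 (rejecting streaks), and sit
   on an unflagged shell. These thresholds are configurable; the defaults
   were chosen once as typical for clean pixel-detector frames.
4. **Mean spot intensity.** For every unflagged shell containing at least
   one spot pixel, `Ibar(h)` is the background-subtracted sum over *all*
   shell pixels divided by the shell's pixel count `N(h)`. Summing the whole
   shell rather than only detected spot pixels makes `Ibar` an unbiased
   estimate of Bragg flux per unit detector area: shells where only the
   brightest spots clear the detection threshold are not biased toward those
   survivors. Shells without any detected spot pixel are treated as
   signal-free.
5. **Wilson fit.** `log Ibar(h) = log k − 2 B s^2 + log Sigma_p(h)` with
   `s = h/2` is fitted by least squares, where `Sigma_p` is the package's
   tabulated standard protein intensity curve (below). `CC_powder` is the
   Pearson correlation of observed and fitted `log Ibar` over the shells
   used. A negative fitted B is clamped to zero and the scale refitted:
   a crystal cannot be sharper than the standard curve, and without the
   clamp resolution-flat salt signal can masquerade as a well-fitting
   negative-B model.
6. **Score.** `score = max(CC_powder, 0) × Σ Ibar(h) V(h)` over spot-bearing
   shells, and exactly zero when no spots were found. Flagged or unusable
   shells inside the spot-bearing resolution range are imputed from the
   fitted Wilson model: the protein signal under an ice ring is real, and
   imputing it keeps the score stable under ring contamination instead of
   docking a frame for its flagged shells.

Three readings were fixed where the scoring algorithm is described only in
outline: `s = h/2`; the correlation computed on the log scale (the scale on
which the fit is linear); and the score summed over spot-bearing shells
only. All three are package conventions, stated here because alternatives
(linear-scale correlation, all-shell sums) would be defensible too.

## The standard protein intensity curve

No machine-readable tabulation of the average-protein Wilson curve was
available, so the package ships its own 21-knot tabulation, interpolated
piecewise-linearly in `h^2`, normalized to 1 at `h = 0`, with the canonical
qualitative features: a strong low-resolution maximum, the dip near d ≈ 5.5 Å
where solvent and macromolecular scattering cancel, the secondary maximum
near d ≈ 4.5 Å from backbone repeat distances, then smooth monotone decay.
Both the frame simulator and the Wilson fit use this same curve, so the
B-recovery tests close the loop on the fit machinery, not on the curve's
absolute accuracy. Conclusions about real data would inherit whatever
mismatch exists between this tabulation and the true average-protein curve.

## The frame simulator

`render_frame()` draws a Poisson background with smooth radial profile
`background_level · exp(−falloff · h^2)` and adds `n_spots` Gaussian spots
(σ = 1.2 px) at uniformly random pixels, each with integrated intensity
`spot_scale · Sigma_p(h) · exp(−2 B s^2)` times a unit-mean exponential
deviate — the acentric Wilson intensity statistics the scoring model
assumes. Optional ice rings enter the Poisson mean as narrow Gaussian
annuli in `h` (σ = 0.004 Å⁻¹, 60 counts/px at crest by default, at the
hexagonal-ice spacings 3.90, 3.67, 3.44, 2.67, 2.25 Å); salt spots are few,
intense and resolution-flat. Three simulator choices matter for
interpretation:

- **Spots are geometry-free**: random positions, not a consistent lattice.
  The scoring stage never indexes, so lattice consistency is unnecessary;
  tests of indexing-dependent behaviour are impossible with these frames
  and are carried by the reflection-level simulator instead.
- **Background is drawn by inversion** (`qpois(runif(n), mu)`), one uniform
  per pixel, so toggling one simulation component (say, an ice ring)
  perturbs only the pixels it touches. Spots and salt use independent
  derived sub-seeds for the same reason.
- **Spot profiles are added deterministically** on top of the Poisson
  background (no re-sampling), so with zero background the total flux is
  exactly linear in `spot_scale` — the anchor for the score-linearity test.

What passing tests show about real data is therefore limited: real frames
have detector gaps, point-spread tails, mosaic streaks, overlapping
lattices and radiation damage, none of which are simulated. The properties
verified here are internal consistency (recovery of planted parameters,
ranking, contamination robustness), not detector realism.

## Reflection-level simulation

`generate_ground_truth()` enumerates all Miller indices to `d_min` under a
general triclinic metric, reduces them to asymmetric-unit representatives
(lexicographically greatest image under the point group, with Friedel mates
folded in), and draws each true intensity from an exponential with mean
`Sigma_p(h) · exp(−2 B_true s^2)`. `simulate_partial_dataset()` then
emulates one wedge: an index-random sample of a fraction of the uniques
(there is no Ewald-sweep geometry — the clustering and merging mathematics
depend only on overlap structure), per-crystal linear scale and relative B,
Gaussian measurement noise proportional to the true intensity (σ floored at
1% of the median intensity to protect downstream divisions), an optional
per-class non-isomorphism perturbation `(1 + c·δ_hkl)` with `δ` a fixed
unit-variance Gaussian field shared within a class, and an optional
reindexing operator emulating a merohedral indexing choice. Negative
observed intensities are kept, as real integration programs keep them.

Symmetry support is deliberately minimal: explicit operator lists for P1,
monoclinic point group 2, tetragonal 4, hexagonal 6 and rhombohedral 3
(hexagonal setting), the last three with the `(k, h, −l)` two-fold
ambiguity operator. Full space-group machinery is out of scope.

The non-isomorphism magnitude is calibrated through the distances it
produces rather than chosen directly: `class_shift = 0.2` with 5%
measurement noise gives within-class distances ≈ 0.08 and between-class
distances ≈ 0.30, straddling the 0.15 selection cutoff — the regime the
clustering stage is supposed to resolve, with the cutoff roughly centred
between the two populations.

## Clustering and selection

`pairwise_cc()` merges each dataset's own symmetry-equivalent duplicates
(inverse-variance mean), then computes the Pearson correlation of
intensities over the uniques each pair has in common; pairs with fewer than
30 commons are missing and get the maximal distance 1 rather than an
imputed value — low-overlap pairs should separate, not blend. The distance
is `dist = sqrt(1 − CC²)`, under which a correlation of 0.989 sits just
inside the conventional 0.15 cutoff. Agglomeration uses average linkage by
default (single, complete and Ward are available); the dendrogram is cut at
0.15 into connected components of merges strictly below the cut, and the
largest cluster is selected, ties broken toward the lower mean
intra-cluster distance.

Merohedral indexing ambiguities are resolved before clustering, against the
first dataset as reference: each other set is passed through every
ambiguity operator (identity included) and keeps the one maximizing its
correlation with the reference. Sets with insufficient overlap under every
operator are left unchanged and flagged. Merging without this step
manufactures apparent twinning; the H-test on a deliberately half-flipped
fixture estimates a twin fraction around 0.4 before resolution and below
0.01 after. The unresolved value sits below the theoretical 0.5 of a
perfect twin because finite wedges mix the two indexing conventions in
binomially varying proportions per reflection.

## Scaling, merging and statistics

Relative scaling fits `log I_set = log k − 2 b_rel s² + log I_ref` per set
over commons with the reference, weighted by the set's `(I/σ)²`;
non-positive intensities are excluded from the log fit. This linear-scale +
isotropic-B model matches the simulator's generative model exactly; real
scaling programs model more (anisotropy, per-image scales, absorption), so
the round-trip accuracy seen here is an upper bound. The end-to-end
pipeline applies the fitted scales *before* computing pairwise correlations,
as the real workflow does.

Merging divides each observation by its set's `k·exp(−2 b s²)`, reduces to
the asymmetric unit and takes the inverse-variance weighted mean with
propagated sigma. Statistics follow the usual conventions: completeness
against the full unique count to `d_min`; multiplicity; `R_merge` and the
precision-indicating `R_pim = Σ_h sqrt(1/(n_h−1)) Σ_i |I_i − Ibar_h| / Σ I`
with both sums over uniques measured at least twice; `CC_1/2` as the mean
over 10 seeded random half-splits of the Pearson correlation between
half-averages (the number of splits is a stability convention, not a
standard); and mean merged `I/σ`. Negative merged intensities are retained
— truncation is a structure-solution concern.

The Yeates H-test computes `H = |I₁ − I₂|/(I₁ + I₂)` over twin-related
pairs with both intensities positive and estimates the twin fraction as
`α = clamp(1/2 − mean H, 0, 1/2)`; at least 50 pairs are required. The
anomalous-signal estimator is Crick–Magdoff-style:
`⟨ΔF/F⟩ = 100·√2·sqrt(Σ count·f''²) / (Z_eff · sqrt(N_atoms))` percent,
with `Z_eff = 6.7` effective electrons per light atom and 7.7 non-hydrogen
atoms per residue — for 316 residues with one Zn (f'' = 3.9 e) and three Ca
(f'' = 1.4 e) it returns 1.97 ≈ 2%.

## Numerical choices and degenerate inputs

- Pixel coordinates are 0-based `(fast, slow)` with centres at integers; the
  detector is flat and orthogonal, with no tilt, parallax, panel gaps or
  polarization/Lorentz corrections.
- Equal-volume shell binning is the default because it makes the `V(h)`
  weights uniform and the score sum well conditioned; equal-`h` binning is
  available. How the reference implementation bins shells is not public;
  this is a package choice.
- Shells with fewer than 50 usable pixels are unusable; Wilson fits need at
  least 4 shells, otherwise the fit is absent and `CC_powder = 0`; frames
  without spots score exactly 0; empty selections yield empty plans and a
  report without a merge stanza.
- ASU representatives are the lexicographically greatest orbit image
  (`h`, then `k`, then `l`); reduction is idempotent and orbit-invariant by
  property test.
- Ties in position ranking break by raster order; ties in main-cluster size
  break by mean intra-cluster distance.
- All randomness is seeded; mesh positions and wedge simulations derive
  per-item sub-seeds from the master seed, kept below 2³¹.

## Problem sizes

The shipped tests run on a 160 × 160 px detector (corner resolution
~1.6 Å), mesh grids up to 6 × 5, and reflection universes of four to ten
thousand uniques (P1 cell 30–50 Å to 2.5–3 Å; hexagonal and tetragonal
cells to 2.5–3 Å). These sizes were chosen so the full property suite
exercises every stage — including 20-seed recovery sweeps — in about two
minutes, while every statistical property tested (B recovery, cluster
recovery, trend monotonicity) is already stable at this scale.

## Known limitations

- The Wilson curve is a package tabulation, not a fitted empirical curve.
- Frames are geometrically unindexable by construction.
- Wedge sampling is index-random; completeness-vs-rotation-range behaviour
  of real wedges is not reproduced.
- The H-test assumes acentric intensity statistics; centric zones are not
  treated separately.
- A single ice ring obliterating an unusually strong resolution shell can
  still move an individual frame's score by more than the typical few
  percent, because the information under the ring is unrecoverable; the
  median behaviour over frames is what the imputation stabilizes.
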