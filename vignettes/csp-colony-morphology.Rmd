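---
title: "Quantifying colony morphology with clustered shape primitives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colony morphology with clustered shape primitives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspshapes)
```

## The problem

Dimorphic yeasts such as *Saccharomyces cerevisiae* switch under nutrient
stress from growth as unconnected cells to pseudohyphal growth: chains of
elongated cells that give colonies filamentous margins. Top-down binary
masks of such colonies carry strain- and nutrient-dependent shape
signatures, but hand-crafted feature lists risk missing the patterns that
actually discriminate. This package quantifies colony shape with
*clustered shape primitives* (CSPs): local chord-length descriptors that
are learned from the data by clustering, so no feature list has to be
specified in advance, together with three classical spatial point-pattern
indices used as comparator features.

## Shape primitives and the chord model

For a binary image, let Ω be the set of occupied pixels. Only boundary
pixels are analysed: a pixel is on ∂Ω when one of its 4-neighbours is
unoccupied or off the grid. At each boundary pixel p and each of D
equally spaced angles φ_d = (d − 1)π/D, the length of the longest line
segment through the centre of p at angle φ_d lying entirely inside Ω is
measured, giving the shape primitive v_p = (v_{p,1}, …, v_{p,D}).

The geometry model matters. Ω is taken to be the union of *closed* unit
pixel squares, and the chord is a continuous segment, not a pixel count:
for a 3 × 3 filled square the diagonals through the corner pixels measure
√2 and 3√2, and the boundary's eight pixels produce exactly three unique
primitives, (3, √2, 3, 3√2), (3, 2√2, 3, 2√2) and (3, 3√2, 3, √2). A
pixel-count model cannot produce these irrational values, which is why
the continuous closed-union model was adopted. Chords are computed by
exact ray–grid traversal (compiled code): the ray is marched from the
pixel centre across cell boundaries in both directions until it first
enters an unoccupied cell or leaves the raster (chords truncate at the
raster edge); a crossing through a lattice corner steps diagonally, so
points on shared edges and corners of occupied squares count as inside.
For concave shapes the chord line may re-enter Ω elsewhere; only the run
containing the pixel centre is measured. The test suite checks the
traversal against a dense-sampling oracle (0.01 px steps) to 0.05 px.

Pixel lengths convert to micrometres with the factor √resolution, since
the mask resolution is an *area* per pixel (μm²·px⁻¹) and the linear
pixel side is its square root. All clustering operates on physical
units so images at different resolutions are comparable.

## Learned vocabulary: CSPs, maps and histograms

The representation space F_g of a group of images is the multiset of all
its primitives. k-means (Euclidean distance) summarizes each group's
space into K cluster centres — the group's CSPs. With m groups there are
M = Km centres, labelled so that centre (g − 1)K + k is the k-th CSP of
group g. Each image is then described by its CSP map (each boundary
pixel labelled with the nearest of the M centres, ties to the smallest
index) and by the normalized histogram h = (h_1, …, h_M) of those
labels. The histogram is the image's shape feature vector; augmented
with the three spatial indices scaled by 1/M (so all coordinates share a
magnitude), it has length M + 3 — 23 for a two-group problem at K = 10,
33 for the three-group problem.

k-means details are deliberately pinned down for reproducibility:
k-means++ seeding, 10 restarts, Lloyd iterations (at most 300; Lloyd
stops at an assignment fixpoint, which implies centre movement below any
tolerance — the nominal tolerance is 10⁻⁶), the restart with the lowest
within-cluster sum of squares wins, and everything is deterministic
given the seed. A restart that aborts on an empty cluster (possible in
duplicate-heavy spaces) is discarded in favour of the remaining
restarts; this replaces re-seeding individual empty clusters, which the
underlying Lloyd implementation does not expose, and preserves the
determinism and fixpoint properties. Dimension reduction such as PCA is
deliberately not used: the clustering transforms primitives into CSP
features rather than projecting them, and directions of maximal variance
need not be directions of good discrimination.

CSPs are always fitted on training images only; test images are labelled
against the trained centres. Pooling train and test data before
clustering would leak information from the held-out images into the
features.

## Spatial indices

Three indices summarize deviation from complete spatial randomness
(CSR), each constructed to be ~0 under CSR. They are computed from *all*
occupied pixels (not only the boundary), about the colony centroid:

* **Radial index** I_r = 1 − R_CSR/R (clamped to [0, 1]), with R the
  maximum radius and R_CSR the outer edge of the outermost of 178 equal
  annuli whose occupancy probability (count / annulus pixel area) still
  meets the CSR reference N/(πR²). Colonies are dense centrally and
  rarefy outward, so the last crossing marks where the colony stops
  looking CSR-dense; long filaments push R beyond R_CSR. If no annulus
  falls below the reference, R_CSR = R and I_r = 0.
* **Angular index** I_θ: the population variance of the 200-bin angular
  occupancy counts, each divided by its CSR expectation N/200. Zero for
  angularly uniform colonies.
* **Pair-correlation index** I_Θ = F_Θ(1) − 1, the first-bin excess of
  the angular pair-correlation function: up to 1000 pixels are sampled
  without replacement (seeded; all pixels when fewer exist), all
  pairwise angular separations are folded onto [0, π] and binned into
  200 equal bins, and each bin is divided by its expectation under
  independent uniform angles (the folded separation of two independent
  uniform angles is itself uniform, so the expectation is n_pairs/200).

The bin counts 178/200/200 and the 1000-pixel sample are the defaults
throughout. These constructions are reconstructions of indices sketched
in the prior literature on yeast spatial patterns; the original
normalized-count and pair-correlation normalizations are not reproduced
verbatim, so absolute values may differ from earlier studies even where
the qualitative behaviour matches. "F_Θ(1)" is read as the first bin of
the binned function.

Two numerical caveats are worth knowing. First, both indices computed
from binned counts carry finite-size noise: a filled disc of radius 40
px has I_θ ≈ 0.04 purely from discretization (about 25 pixels per bin),
falling below 0.01 only for discs with ≳30000 pixels. Second, I_r
responds to filament length only up to moderate lengths: for very long
filaments R and R_CSR grow together (for boundary mass decaying like
1/r the crossing settles near R/2), so I_r saturates around 0.4–0.5
rather than approaching 1.

## Classification protocols

Classification uses linear discriminant analysis on **one feature at a
time** — with image counts of order ten per group, a single coordinate
of the augmented vector is all the data can support without
overfitting. On one coordinate with uniform priors and pooled
within-class variance, the Gaussian discriminant reduces to the nearest
class mean; zero pooled variance and all-identical class means
degenerate to the same rule, predicting the first class on exact ties.

Three evaluation protocols are provided:

* **Repeated train/test** (`repeated_evaluation()`): each group is split
  evenly at random (odd group sizes put the extra image in training, so
  a 9-image group trains on 5 and tests on 4); CSPs are fitted on the
  training images; the best single feature is selected; the held-out
  accuracy is recorded. This is repeated n = 30 times with fresh split
  and k-means seeds, reporting the mean, the sample standard deviation,
  and how often each spatial index was among the tied-best features.
* **Leave-one-out cross-validation** (`loocv_evaluate()`): each image in
  turn is held out; CSP fitting *and* feature selection are redone on
  the remaining S − 1 images (the held-out image must not influence the
  centres); the accuracy is the proportion of the S held-out images
  classified correctly.
* **Feature analysis** (`feature_analysis()`): a single split in which
  every coordinate is scored on the test set and all features achieving
  the maximal test score are reported, with the centre vectors of
  winning CSP features for plotting (`plot_csp_centre()` draws length
  against angle). Less robust than the other two, but it shows *which*
  shape patterns discriminate.

The selection criterion is training accuracy by default;
`selection = "test"` instead reports the best held-out score across
features (each trained and tested individually), an optimistic variant
that some published analyses appear to use. With training sets of ~10
images, many features routinely tie at a *perfect* training score, and
which of them is picked then determines the held-out accuracy. Breaking
such ties by feature position would make the result depend on the
arbitrary numbering of cluster centres, and in simulation it regularly
selects a tied feature that fails on the test set. Accuracy ties are
therefore broken by the Fisher separation ratio — the variance of the
class means over the pooled within-class variance, the natural
discriminant-analysis measure of how crisply a single feature separates
the classes — and only exact ratio ties fall back to the smallest
index. A spatial index is counted as "chosen" whenever it is among the
features tied for the best score in a selection event.

## The synthetic colony generator

Real colony masks are not bundled, so every pipeline stage is exercised
on synthetic colonies: a filled disc core with `n_filaments` thick
radial segments (truncated-normal lengths, evenly spaced directions
with a random global rotation, optional one-level branching). Filaments
are rasterized thick segments, not cell-level growth simulations — the
pipeline needs realistic shape *statistics*, not biophysics. Angular
anisotropy is controlled by `angular_jitter`, the dispersion of a
per-direction log-normal growth multiplier on filament length: 0
develops all directions equally; larger values concentrate boundary
mass in a few well-developed directions and provably increase I_θ.
(Two tempting alternatives fail: perturbing the direction angles merges
neighbouring filaments in the raster union, *losing* boundary mass and
lowering I_θ; concentrating directions into a sector shifts the
centroid toward the heavy side, and the off-centre core then fills in
the angular histogram, again lowering I_θ.)

Three presets mirror a reference experiment of two strains at two
nutrient levels (10, 9 and 10 images at resolutions 1.52, 1.55 and 1.53
μm²·px⁻¹ on 512 × 512 rasters, 40 px cores): `a7_50` with long sparse
filaments (125 ± 10 px), `ar_50` intermediate (60 ± 8 px) and `a7_500`
a short dense fringe (15 ± 3 px), the uniform-growth morphology of
ample nutrient. The length regimes are disjoint by more than 5 standard
deviations, and the filament counts are high enough (tens per colony,
as in real pseudohyphal colonies) that per-image histogram proportions
are stable; under these conditions the three classification problems
resolve at mean accuracies around 0.95–1.0, the regime reported for
real data of this design. What the generator does *not* emulate:
cell-scale boundary roughness, curved or tapering filaments, invasive
growth beneath the agar, and imaging artefacts. Passing tests therefore
demonstrate the pipeline's correctness and discriminative behaviour on
idealized morphologies, not segmentation robustness on real
photographs.

## Problem sizes and runtime choices

The test-suite experiments run at the preset scale (512² rasters, 29
images, n = 30 repetitions) for the acceptance properties, and at a
reduced scale (144² rasters, 4–6 images per group, n ≤ 10) for unit
tests of the protocols, where k-means runs in milliseconds. The
permutation controls use 100 label shuffles at the reduced scale. These
sizes were chosen so the full suite completes in a few minutes while
keeping every statistical check at its stated tolerance.

## Known limitations

* The chord model is exact for the closed-union geometry but pixel
  masks themselves discretize the underlying colony; descriptors below
  ~2 px scale are not meaningful.
* I_r saturates for very long filaments (above), and all indices carry
  finite-size noise on small colonies.
* With small image counts, many features tie at a perfect training
  score and the smallest-index tie-break is essentially arbitrary among
  them; the repeated protocol averages over this, but single runs can
  select a feature that generalizes poorly.
* Disconnected masks are accepted with a warning and analysed as-is;
  colonies touching the raster border have their chords truncated.
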