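---
title: "Models and methods behind scmsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmsi)
```

`scmsi` reconstructs the analysis chain of a microscopy-integrated
single-cell MSI experiment: in-source optics, multimodal
co-registration, mask-based spectrum compilation, accurate-mass
annotation and spatial statistics. This vignette documents the models
behind each stage, the parameters that matter, the numerical choices
we made where the design was genuinely open, and what the synthetic
phantoms do — and do not — establish about real data.

## Coordinate frames and transforms

Three frames are used throughout, all metric (micrometres, x right,
y down, pixel centres at `(index − 0.5) · pixel size`):
`external_fm` (the slide-scanner image), `insource_fm` (the microscope
inside the ion source) and `msi` (the MSI raster). The latter two
share one coordinate system — the instrument design couples laser
ablation and in-source imaging through the same objective and stage —
which is what reduces "register FM to MSI" to "register external FM
to in-source FM". Transforms are stored in pull-back (resampling)
convention: a registration result maps target-frame coordinates into
the moving frame. Composition and inversion are closed under this
convention and round-trip to identity below 1e-9 µm (tested).

## In-source optics

**Sharpness** is the variance of the response of the 3×3
four-neighbour Laplacian stencil, evaluated over the interior (valid)
region only, so image borders never contribute. The metric is
invariant to additive offsets and scales with the square of contrast;
the stencil choice is the standard discrete Laplacian (the method
description names only "a Laplacian filter").

**Autofocus** scans the configured z-range at 1 µm, moves to the
sharpest position, and rescans ±1 µm at 0.1 µm. Ties break toward the
lowest z, which makes the routine deterministic. On noise-free stacks
with blur monotone in defocus the recovered focus is within one fine
step of truth (50-stack battery in the acceptance suite).

**Focal surface.** Autofocus points are interpolated exactly by a
radial basis function: thin-plate spline (`r² log r` plus an affine
polynomial term) for ≥3 non-collinear points, a linear RBF for two
points, a constant for one. No smoothing term is used — the source
workflow says "interpolation", and autofocus points are treated as
exact. The surface is evaluated on a 10 × 10 µm mesh over the ROI and
each mosaic tile takes its z from the nearest mesh node.

**Mosaic and teaching points.** Camera tiles are cropped symmetrically
to the tile cell (≤100 × 100 µm) and placed by stage centre, so each
canvas pixel is written exactly once; no blending is needed because
the cells abut. Three tile centres (top-left, bottom-left,
bottom-right) are exported as (canvas pixel, stage µm) teaching
points; because the crop is exact, the affine fit through them
reproduces the canvas↔stage mapping to machine precision. The scale
factor (µm per camera pixel) is calibrated from a periodic bar target
by locating the dominant Fourier peak of the column-mean profile with
parabolic sub-bin refinement (within 1 % on noisy synthetic targets).

## Co-registration

The initialisation is deliberately translation-only — the mean
displacement over the landmark pairs — even when three or more
landmarks would support an affine fit; the full affine enters only
through the mutual-information refinement, mirroring the two-stage
structure of the original workflow.

The refinement maximises Mattes-style mutual information computed
from a joint histogram with 50 bins per image. Fixed-image samples
(a seeded random 1 % of pixels, drawn once per registration, which
makes the whole procedure deterministic) are binned hard; moving
intensities, sampled bilinearly, are spread over the two adjacent
bins with linear partial-volume weights, which keeps the metric
continuous in the transform parameters. Samples that map outside the
moving image contribute the background value 0 rather than being
dropped — discarding them makes the sample set, and hence the metric,
discontinuous in the parameters.

The optimiser is gradient ascent with finite-difference gradients,
heavy-ball momentum (0.7) and an adaptive step: a move along the
accumulated normalized-gradient direction is accepted if it improves
the metric, otherwise the step is halved and the momentum reset,
until the step undercuts the convergence minimum (1e-6) or the metric
stalls over the convergence window (20 iterations). Matrix parameters
are scaled by the image diagonal so learning rate 1 corresponds to
about 1 µm of point motion regardless of field size. Two optimisation
stages run at constant resolution but with both images Gaussian
smoothed at sigma 3 then sigma 1 pixels. We had initially assumed a
single unsmoothed level would suffice at this field size; empirically
the sampled-MI surface of sharp, nearly binary fluorescence images
has ridge structure that stalls plain ascent several micrometres from
the optimum, while the two-sigma smoothing schedule — which widens
the basin without moving the optimum of a symmetric blur — converges
to 0.01–0.2 µm mean TRE across 20-pair batteries. Resampling uses
bilinear interpolation (exact for affine intensity ramps); the
interpolator is our choice, as the source workflow does not state
one.

## Segmentation and morphometrics

Real experiments use a learned segmenter; `scmsi` ingests any integer
label mask. The built-in fallback thresholds the nuclear channel
(Otsu by default — production thresholds were manual, so the
parameter-free default is ours), labels connected nuclei as seeds,
and propagates labels into the supra-threshold membrane signal
(EBImage's seeded propagation, which draws watershed-like division
lines between touching cells). Our Otsu implementation returns the
midpoint of the between-class-variance plateau; the textbook argmax
convention returns the plateau's first bin, which for well-separated
modes sits at the edge of the lower mode and misclassifies its upper
tail. Morphometrics are the minimal subset that feeds downstream
analysis: area, 4-adjacency boundary length, second-moment
eccentricity, centroid and per-channel means. Masks live in the
external-FM frame and are only projected to the MSI frame inside the
compilation stage.

## Single-cell spectra

"Hit coverage" is interpreted geometrically: the fraction of an MSI
pixel's area covered by each cell mask, computed by supersampling the
pixel at the mask's resolution and mapping each subsample through the
registration transform. This is the only reading under which total
signal is conserved, and conservation is exact by construction:
`Σ_cells Σ_p f · I + unassigned = Σ_p I` (asserted to 1e-9 relative
in the acceptance suite). The uncovered share of a partially covered
pixel stays unassigned rather than being renormalised to cells —
renormalising would inflate edge-cell signal. Per-pixel peaks are
matched to species target m/z within the annotation ppm window before
summation. Per-cell profiles are normalized to the cell's summed
intensity; all-zero cells are flagged and left untouched, making
normalization idempotent.

Region comparisons (e.g. phagolysosome vs remaining cell) use
per-pixel means rather than region sums — the source figures do not
say which; the mean is free of region-area bias. The fold-change
pseudocount defaults to the smallest nonzero species mean, and the
marker threshold is log2 fold change 2.8.

## Annotation

Monoisotopic masses come from the most-abundant-isotope table
(C, H, N, O, P, S, Na, K, Fe); ion m/z include the electron mass
(0.000549 Da) explicitly — at a 3 ppm window on an m/z 700 lipid the
electron alone is 0.8 ppm. Supported adducts are [M+H]⁺, [M+Na]⁺,
[M+K]⁺, [M−H₂O+H]⁺, [M−H]⁻ and the radical molecular ion [M]⁺• (dyes,
heme). The shipped library stores explicit bulk formulas because
accurate mass cannot resolve isomers within a lipid class. Peak
extraction takes local maxima with S/N > 3 against a sliding-window
robust noise estimate (1.4826 × MAD); sparse centroid mean spectra
are first rasterized onto a dense axis by Gaussian deposition at the
stated resolving power, and apex m/z is refined by a parabola on log
intensity (exact for Gaussian peaks), preserving sub-ppm accuracy.
Isotopologues (+n · 1.00336 Da, n = 1, 2, less intense than their
parent) are removed before matching. Curation drops classes not
expected in the ion mode (glycerophosphoinositols and other acidic
classes in positive mode; triacylglycerols, sterols and dyes in
negative mode) and can flag or drop odd-chain compositions. Ties
within the window are all reported, ranked by |ppm| — mirroring a
manual curation step rather than guessing.

## Spatial statistics

Classification thresholds default to Otsu over the per-cell channel
means (the production analysis thresholded manually; "high intensity"
is not defined numerically there, so the parameter-free default is
our documented assumption). Classes nest — CD45⁺ requires high Cy5,
Ly6G⁺ adds TxRed, DcTRAIL-R1⁺ adds Cy7 — and each cell receives the
most specific matching class.

TME clustering is k-means on z-scored (population-sd) per-cell
species profiles of Ly6G⁻ cells, k defaulting to 8 as in the source
analysis (chosen there by visual inspection over 6–10); a silhouette
scan over 6–10 is provided as a report, never as a decision-maker.
Neutrophil subtyping embeds the standardized profiles with UMAP
(default parameters, seeded) and clusters the 2-D embedding with
DBSCAN (eps 0.7, min 7). Whether the original DBSCAN ran on two or
more UMAP dimensions is not stated; we use the 2-D embedding that is
also visualised. DBSCAN itself is implemented in the package (no
pre-installed R implementation exists in our dependency set) and is
tested against its textbook definition.

Both neighborhood radii are edge-to-edge: a neighbor counts when the
minimum boundary-to-boundary distance is within the radius (15 µm for
neighborhood counts, 40 µm for TME assignment — the source states
edge distance for the former and is silent for the latter; we use one
convention for internal consistency). Modal TME assignment breaks
ties by the nearest neighbor's label, which is deterministic and
local. Cluster-recovery tests compare partitions by adjusted Rand
index, never by label identity.

## The phantom generator

The generator is the package's study condition, fixed once: a
200 × 200 µm field, FM at 0.5 µm pixels, MSI at 1.0 µm pixels (the
tissue pixel size; 1.5 µm is the cultured-cell setting), 80 elliptical
cells (nucleus disc + cytoplasm annulus) of four types emulating the
tumor/CD45⁺/Ly6G⁺/DcTRAIL-R1⁺ marker logic with distinct bulk lipid
profiles, a true misalignment of 2° rotation, 1.01 scale and
(8, −5) µm shift about the field centre, a tilted focal plane, m/z
jitter of ≤1 ppm around theoretical (to exercise the 3 ppm window
realistically), scaled-Poisson MSI noise (counting-statistics
analogue of ion detection, one count = 0.25 intensity units) and
Gaussian FM noise (sigma 0.02 of the unit dynamic range). The
registration benchmark draws misalignments from the stated envelope
(≤3°, scale within [0.98, 1.02], ≤20 µm shift) and renders the
in-source view of each phantom through the true transform.

What passing on phantoms shows: the algebra and geometry are correct
(conservation, transform round-trips, oracle equivalence), the
registration machinery recovers known misalignments well below 1 µm,
and clustering recovers planted partitions. What it does not show:
performance under real tissue morphology (cells are smooth ellipses
with hard edges), matrix-crystal or ablation artefacts, optical PSF
structure beyond Gaussian blur, chimeric boundaries from imperfect
segmentation, or annotation specificity against a full lipidome —
the shipped library has tens, not thousands, of candidates.

## Problem sizes and determinism

Test and acceptance batteries run at desk scale, chosen as the
package's own benchmark sizes: 20 registration pairs at 150 × 150 µm
with 60 cells and eleven landmarks each, 50 autofocus stacks, 20-seed
cluster batteries of 75–120 cells sampled from planted profiles with
counting noise. Every stochastic stage (phantom rendering, MI pixel
sampling, k-means starts, UMAP) consumes an explicit seed and restores
the caller's RNG state, so identical inputs give bit-identical
rasters, peak lists and labels; this is asserted by tests rather than
assumed.
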