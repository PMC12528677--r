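# scmsi — microscopy-integrated single-cell MALDI mass spectrometry imaging

`scmsi` implements the computational pipeline behind single-cell
lipidomics by transmission-mode MALDI-2 mass spectrometry imaging
(t-MALDI-2-MSI) combined with fluorescence microscopy (FM). At ≤1.5 µm
MSI pixels, individual cells span only a handful of pixels, so every
downstream claim rests on three computational pillars that this package
provides:

1. **In-source microscopy math** — autofocus by variance of the
   Laplacian (coarse 1 µm scan, fine 0.1 µm scan over ±1 µm),
   radial-basis (thin-plate spline) interpolation of the focal surface
   on a 10 × 10 µm mesh, mosaic stitching of ≤100 × 100 µm camera
   tiles by stage coordinates, pixel↔stage scale calibration from a
   resolution test target, and teaching-point export that ties canvas
   pixels to stage micrometres exactly.
2. **Two-stage multimodal co-registration** — a translation-only
   landmark initialisation followed by affine refinement that
   maximises Mattes mutual information (50 bins, learning rate 1, 50
   iterations, convergence 1e-6/20, 1 % random pixel sampling) between
   the external FM image and the in-source FM image, whose coordinate
   system the MSI grid shares. Accuracy is quantified as target
   registration error (TRE) over landmark pairs,
   `TRE_i = ||T(x_i) − y_i||`.
3. **Mask-based single-cell spectra and spatial statistics** — cell
   masks are projected onto the MSI grid; each MSI pixel is
   apportioned by the *hit coverage* (the geometric area fraction a
   cell mask covers), so the intensity of species *s* in cell *k* is
   `I_ks = Σ_p f_kp · I_ps`, conserving total signal exactly. Spectra
   are annotated by accurate mass (< 3 ppm, S/N > 3, deisotoped,
   ion-mode curated; m/z from monoisotopic masses with explicit
   proton/electron corrections), normalized per cell, and analysed
   spatially: marker-threshold classification (CD45⁺ / Ly6G⁺ /
   DcTRAIL-R1⁺), k-means tissue microenvironments on Ly6G⁻ cells,
   UMAP + DBSCAN (eps 0.7, min 7) subtyping of Ly6G⁺ neutrophils,
   edge-distance neighborhood counts (15 µm), and modal TME
   assignment within 40 µm.

A synthetic phantom generator renders matched FM channels, label
masks, defocus stacks and MSI peak-list datacubes with known ground
truth (cell types, lipid profiles, misalignment, focal surface), so
the entire pipeline is testable end to end without instrument data.

## Worked example

Theoretical ion m/z from a molecular formula:

```r
library(scmsi)
adduct_mz(monoisotopic_mass("C46H80NO8P"), "[M+H]+")
#> [1] 806.5694        # [PC(38:6)+H]+, prints as 806.57
```

Annotating the mean spectrum of a phantom dataset:

```r
ph   <- generate_phantom(phantom_config(seed = 1))
ms   <- rasterize_spectrum(mean_spectrum(ph$msi))
pk   <- remove_isotopes(pick_peaks(ms))          # S/N > 3
hits <- match_library(pk, default_lipid_library(), "positive")
hits[, c("species", "adduct", "ppm_error")]
#>       species     adduct    ppm_error
#> 1 cholesterol [M-H2O+H]+ -0.000208231
#> 2  ACAR(18:0)     [M+H]+  0.001502662
#> 3   LPC(16:0)     [M+H]+  0.003644811
#> 4 SM(34:1;O2)     [M+H]+ -0.007344935
#> 5  PC(O-32:0)     [M+H]+ -0.038362293
#> 6    PC(34:1)     [M+H]+  0.003325842
#> 7    PC(38:6)     [M+H]+  0.004783791
```

All seven lipid species planted in the phantom are recovered within a
fraction of a ppm. The full workflow (simulate → focus → register →
segment → compile → annotate → classify → cluster → neighborhood →
summary matrix) runs as one call:

```r
run_pipeline(pipeline_config("artifacts/", seed = 3))
```

which writes per-stage CSV/TIFF/JSON artifacts plus a provenance log;
on the default phantom the registration stage reports a mean TRE of
about 0.01 µm over eleven landmark pairs. A thin command-line wrapper
for individual stages lives at `inst/cli/scmsi.R`.

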