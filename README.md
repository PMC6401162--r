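# holobright

Bright-field holography in R: reconstruct lensless in-line holograms and
give them the contrast, color and axial sectioning of an incoherent
bright-field microscope, by training a cross-modality image-to-image
network on paired data.

## The problem

An in-line holographic microscope records one intensity frame
`I = |U|²` — the interference of light scattered by a sparse sample with
the unscattered reference wave. Angular-spectrum backpropagation

```
U(z) = F⁻¹[ F[√I] · exp( i 2π z √(1/λ² − fx² − fy²) ) ]
```

refocuses that single snapshot to any height `z`, which is the appeal of
lensless holography: a whole volume from one exposure. But the sensor loses
the phase, so reconstructions carry twin-image ripples and out-of-focus
fringes, are monochrome, and stretch axially. A scanning bright-field
microscope has clean, colored, optically sectioned planes — at the cost of
a mechanical z-stack per field of view.

`holobright` implements the full computational bridge between the two
modalities for sparse micron-scale particle samples (beads, bioaerosols):

* **optics** — angular-spectrum propagation, in-line hologram simulation
  (thin-object multiplicative model), backpropagation with 3× spectral
  interpolation;
* **conditioning** — Bayer-channel extraction and wavelet shade correction;
* **autofocus** — Tamura-of-gradient edge-sparsity criterion,
  coarse-to-fine search;
* **baseline** — object-support iterative phase recovery;
* **registration** — phase-correlation rigid alignment and axial
  zero-registration of the two modalities;
* **paired data** — a seeded generator rendering the same 3-D phantom as
  coherent holograms and incoherent bright-field color z-stacks
  (defocus blur σ(Δz) = σ₀·√(1 + (Δz/z_R)²));
* **network** — a residual U-Net generator (complex field in, RGB out)
  with an optional least-squares adversarial term, trained with the
  6-generator/3-discriminator update schedule and lowest-validation-MAE
  model selection;
* **evaluation** — RMSE/SSIM/UIQI, contrast-to-noise ratio
  |μ_fg − μ_bg|/σ_bg, isolated-bead detection and 3-D PSF FWHM statistics.

## Worked example

Simulate a bead hologram, autofocus it, and compare phase recovery with
plain backpropagation:

```r
library(holobright)

ext <- 128 * 1.12                       # field of view, um
ph  <- generate_phantom(1, ext, z_range = c(498, 502),
                        radius_dist = c(4, 0), min_separation = 10,
                        seed = 7)
holo <- simulate_inline_hologram(ph, optical_geometry(), c(128, 128),
                                 noise_sd = 0.005, seed = 7)
af <- autofocus(holo, 400, 600, coarse_step = 10, tol = 0.1)
af$z_star
#> [1] 498.2587

bm <- benchmark_phase_recovery(seed = 1)
round(c(twin_reduction = bm$twin_reduction,
        cnr_backprop = bm$cnr_backprop, cnr_recovered = bm$cnr_recovered), 2)
#> twin_reduction   cnr_backprop  cnr_recovered 
#>           1.00          24.18         395.14 
```

The bead actually sits at z = 498.46 um (the seeded phantom's height), so
autofocus lands within 0.21 um. Phase recovery removes essentially all
twin-image energy outside the object support of this single-plane disk and
raises its in-focus contrast-to-noise ratio — but it cannot section away
fringes from *other* depths, which is what the learned translation does.

Train the desk-scale cross-modality model and measure the 3-D PSF medians
on held-out beads (about 9 minutes on one CPU):

```r
bm <- benchmark_cross_modality(seed = 11)
round(c(input = bm$median_axial_input, network = bm$median_axial_output,
        brightfield = bm$median_axial_gt), 2)
#>       input     network brightfield 
#>        5.27        2.48        2.44 
round(100 * bm$fringe_ratio, 2)
#> [1] 0.11
```

The network output's median axial FWHM drops from the coherent input's
value toward the bright-field ground truth, and out-of-focus fringe energy
falls to a fraction of a percent of the input's — the two signatures of
bright-field-like sectioning from a single hologram.

## Command line

A thin CLI wraps the same functions:

```sh
inst/cli/holobright simulate  --out runs/sim --seed 5 n_beads=2
inst/cli/holobright autofocus --out runs/af hologram=runs/sim/hologram.tif z_min=450 z_max=550
inst/cli/holobright make-dataset --config cfg.yaml --out runs/data
```

Each run writes its artifacts plus a `run_manifest.json` recording the
verbatim config, its hash and the master seed.
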