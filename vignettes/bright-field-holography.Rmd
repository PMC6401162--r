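---
title: "Bright-field holography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bright-field holography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A lensless in-line holographic microscope records a single intensity frame:
the interference between light scattered by a sparse sample and the
unscattered reference wave traveling the same axis. Numerical
backpropagation refocuses this frame to any height, which gives holography
its large depth of field from one snapshot — but the reconstruction carries
twin-image and self-interference ripples (the phase of the field is lost at
the sensor), is monochrome, and elongates axially. A scanning bright-field
microscope shows none of these artifacts but needs a mechanical z-scan per
field of view.

`holobright` implements the full computational chain that connects the two
modalities: a scalar-diffraction simulator for paired data, hologram
conditioning, edge-sparsity autofocusing, the classical object-support
phase-recovery baseline, rigid cross-modality registration, a trainable
image-to-image translation network that maps backpropagated complex fields
to bright-field-equivalent color planes, and the evaluation machinery
(RMSE/SSIM/UIQI, CNR, 3-D PSF FWHM statistics) used to quantify whether
the translation actually achieves bright-field-like axial sectioning.

## Optical model

Free-space propagation uses the angular spectrum method: the field's 2-D
spectrum is multiplied by

$$H(f_x, f_y; z) = \exp\!\left(i 2 \pi z \sqrt{\lambda^{-2} - f_x^2 - f_y^2}\right)$$

on propagating frequencies ($f_x^2 + f_y^2 \le \lambda^{-2}$); evanescent
components are set to zero, which is exact for the propagation distances
used here (hundreds of micrometres at $\lambda = 0.85\,\mu m$). The default
geometry matches a lensless near-infrared setup: $\lambda = 0.85\,\mu m$,
$1.12\,\mu m$ sensor pitch, sample about $500\,\mu m$ above the sensor in
air.

Holograms are formed by a thin-object forward model: unit-amplitude plane
wave, multiplicative complex transmittance per object plane (particles are
antialiased disks with amplitude absorption and phase delay), sequential
propagation between planes and to the sensor, intensity detection, optional
additive Gaussian sensor noise (default sd 0.01 on unit-mean intensity).
This first-Born-like model is valid for the uniform, relatively sparse
samples the method targets; dense occluding samples are out of scope.

Backpropagation initializes the sensor field as $\sqrt{I}$ with zero phase
(the standard lensless convention — the measurement has no phase) and
applies the exact inverse of the forward propagation. A `pad_factor` of 3
zero-pads the spectrum before inversion, interpolating the pixel pitch by
3x. Two numerical caveats that the tests encode explicitly:

* the discrete kernel is adequately sampled only for grids with
  $N \gtrsim z\lambda/p^2$; oracle comparisons against a brute-force
  Rayleigh–Sommerfeld summation are run on grids satisfying this bound;
* a single-pixel aperture at this pitch is not band-limited, so oracle
  checks use Nyquist-band-limited (Gaussian-apodized) apertures.

## Hologram conditioning

Raw frames from a color sensor are split into their four Bayer channels
(near-infrared illumination makes all four respond), each channel is
balanced to unit mean and divided by its low-frequency shade estimate, and
the channels are re-interleaved. The shade is the level-$L$ approximation of
a multilevel 2-D discrete wavelet transform (hard-coded sym4 filters,
periodized transform on a mirror-padded grid) with all detail coefficients
zeroed; division rather than subtraction because illumination shade is
multiplicative. $L = 6$ by default (shade scale $\gtrsim 64$ px); the
half-resolution Bayer channels use $L - 1$ so the physical scale matches.
"Balancing" is interpreted as per-channel mean equalization — the most
conservative reading consistent with re-interleaving into one monochrome
frame.

## Autofocusing

The focus criterion is the Tamura coefficient of the gradient magnitude,
$\sqrt{\operatorname{sd}(g)/\operatorname{mean}(g)}$ with $g$ the
central-difference gradient magnitude of the backpropagated amplitude
(amplitude, not intensity, by default; both are supported). The search is a
coarse grid (default 10 um) followed by golden-section refinement to 0.1 um.
Coherent single-particle focus curves carry genuine axial sidelobes of
roughly 10% prominence, so the implementation relies on the main lobe
dominating the curve rather than on global unimodality; the test suite
checks exactly that, plus recovery within 2 um on seeded multi-bead
holograms.

## Phase-recovery baseline

The classical comparison point alternates between the measured sensor
amplitude and an object-plane support constraint: outside the support
(pixels beyond $k$ standard deviations from the mean amplitude, dilated by
a disk) the field is replaced by the background estimate — mean amplitude
outside the support, zero phase. One hundred iterations by default, fixed
count, no convergence test, for reproducibility. This suppresses the twin
image of in-plane objects but, as the evaluation shows, does not remove
out-of-focus fringes from other depths — the gap the learned translation
closes.

## Synthetic paired data

The generator emulates the paired acquisition the method needs: the same
3-D particle phantom is rendered coherently (hologram + backpropagation)
and incoherently (bright-field color z-stack). Bright-field defocus is a
variance-growing Gaussian blur,
$\sigma(\Delta z) = \sigma_0\sqrt{1 + (\Delta z / z_R)^2}$, with
$\sigma_0 = 0.61\,\lambda/\mathrm{NA} \approx 0.45\,\mu m$ and
$z_R = \lambda/\mathrm{NA}^2 \approx 0.98\,\mu m$ for a 20x/0.75 NA
objective at 0.55 um — physically motivated defaults, not fitted to any
measured PSF; validation therefore uses parameter recovery and direction
tests, not absolute widths. Particles composite multiplicatively onto a
white background with per-channel transmittance
$(1 - a)\,c_{ch}$ inside the disk (absorption $a$, color $c$), so the
hologram is monochrome while the target is colored — the translation must
learn colorization from morphology. The renderer produces no fringes at any
defocus; the modality gap (coherent fringing and axial elongation vs
incoherent smooth blur) is asserted by tests.

What this generator does *not* emulate: realistic pollen morphology and
spectra, partial coherence of the ~1 nm source bandwidth, high-NA vectorial
effects, refractive-index structure of the mounting medium, dense samples.
Passing tests show the pipeline reproduces the method's behavior under its
stated assumptions, not that it matches any particular instrument.

## The cross-modality network

The generator is a U-Net variant with residual connections: conv stem,
`depth` encoder levels (residual blocks, 2x average pooling, channel
doubling), residual bottleneck, decoder with 2x2-stride-2 transposed
convolutions and skip concatenation, linear RGB head. Input is the
backpropagated complex field as two channels (Re, Im); output approximates
the bright-field RGB patch in [0, 1]. The discriminator
has six convolutional blocks and two fully connected layers; the
adversarial term is least-squares, weighted by `adversarial_weight`
(default 0.02, 0 disables it — all correctness properties hold at 0).

Two design choices matter on this data and are deliberate:

* **linear head, not a squashing nonlinearity.** Bright-field targets are
  almost entirely white; a sigmoid head saturates there and multiplies the
  L1 gradient of the rare dark-bead pixels by $\sigma'(x) \approx 0$, and
  the network collapses to "always white". A linear head keeps the
  regression gradient constant; outputs are clipped to [0, 1] at inference
  only.
* **head bias initialized at the white level**, so optimization starts at
  the target background rather than at black.
* **phase-aligned input normalization.** The backpropagated background
  carries an arbitrary global phasor exp(i 2 pi z / lambda); each patch is
  multiplied by the conjugate unit mean phasor, mean-centered per channel,
  and scaled by its mean amplitude (~1 for unit-mean holograms). A
  per-patch z-score instead couples the input scale to the local object
  density and the absolute height, and the model then fails to transfer
  from training patches to scenes with different bead density — observed
  directly on held-out phantoms.

The training schedule follows the reference recipe: per iteration six
generator updates (Adam, 1e-4) and three discriminator updates (Adam,
3e-5); validation MAE every 50 iterations; the selected model is the
validation-MAE argmin. Everything — initialization, data order,
augmentation — derives from one seed, and identical seeds give identical
selected checkpoints. Augmentation draws distinct transforms from the
eight axis-aligned rotations/flips, applied identically to input and
target.

Training batches are drawn from a **content-stratified** pool: every patch
whose target shows object contrast plus an equal number of background-only
patches. Micron-scale beads occupy a vanishing fraction of the field, so
unstratified sampling starves the loss of object signal; stratification is
the desk-scale stand-in for the dense pollen fields of a real acquisition.
The training z-list combines fine axial sampling through focus (0.5 um
within +/- 5 um) with coarse far-defocus coverage (2.5 um out to
+/- 20 um): the network must see the intermediate defocus appearances to
reproduce the bright-field contrast-vs-depth curve, and the far planes to
learn fringe suppression.

Inference tiles arbitrary planes with linear feathering in the overlaps,
normalizing each tile exactly as in training; plane-wise application to a
backpropagated stack yields the single-snapshot virtual z-stack.

## Evaluation protocols

* RMSE over channels; SSIM with the standard 11x11 Gaussian window
  (sigma 1.5, stabilizers $(0.01 L)^2$, $(0.03 L)^2$); UIQI as the global
  single-window index $4\sigma_{xy}\bar x\bar y / ((\sigma_x^2 +
  \sigma_y^2)(\bar x^2 + \bar y^2))$ (a sliding-window variant would need
  only a window argument; the global form is the default because no window
  is canonical).
* CNR $= |\mu_{fg} - \mu_{bg}| / \sigma_{bg}$.
* Bead detection: 3-D local maxima of $|I - \mathrm{median}|$ above an
  adaptive threshold; maxima of one bead (axial sidelobes, focal rings of
  coherent stacks) are merged by lateral clustering within half the
  isolation distance; then any pair of beads closer than the isolation
  distance in 3-D removes both; centroids by 5x5x5 center of mass.
* FWHM: half-maximum between the extremum and a baseline (median of the
  outer 20% of samples), crossings by linear interpolation. Lateral
  profiles are taken through the centroid at the nearest-to-focus plane
  (dark dips inverted first); axial profiles use the per-plane contrast
  extremum in a small window, which is robust to sub-pixel lateral drift
  across z. The same conventions are applied to input, output and ground
  truth, so comparisons remain meaningful even though absolute values
  depend on the conventions.

## Desk-scale study sizes

The package's own experiments (test suite and `scripts/acceptance.R`) run
at sizes chosen for a single CPU: 32 x 32-pixel training patches cut from
3x-interpolated reconstructions of 64 x 64-pixel sensor frames, 10 training
phantoms with 5 beads each, a depth-2, 8-channel generator trained for 3000
iterations, and held-out evaluation on 3 phantoms with 7 isolated 1 um
beads measured over 81 planes at 0.5 um steps. The full-scale configuration of the reference recipe (256 x 256
patches, depth-4/32-channel generator, tens of thousands of iterations)
remains reachable through `generator_config()` / `training_config()`.

## Known limitations

* The forward model is scalar, thin-object and sequential; it does not
  model multiple scattering or occlusion.
* The bright-field PSF is a parametric Gaussian-defocus model; axial
  asymmetries and spherical aberration of real objectives are absent.
* Rigid per-plane registration replaces multi-stage global-to-local
  registration; sufficient for synthetic data with known alignment, a
  fidelity reduction for real stage-scanned stacks.
* The desk-scale network narrows axial PSFs toward the bright-field
  reference and suppresses fringes, but its absolute image quality is far
  from a full-scale training run; no claim is made beyond the directional
  and ratio properties the tests assert.
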