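---
title: "Depth-resolved SAW-OCE phase velocity estimation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved SAW-OCE phase velocity estimation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surface acoustic wave optical coherence elastography (SAW-OCE) drives a
low-frequency mechanical wave along a sample surface — skin, an agar
phantom — and watches it propagate with phase-sensitive OCT. The wave's
phase velocity at a given depth reflects the stiffness of the material at
that depth: a stiff epidermis carries a faster surface wave than the softer
dermis below it. The quantity of interest is therefore the depth-resolved
phase velocity profile $v(z)$, and, in layered media, the depth at which it
jumps.

The raw observable is a complex-valued volume $c[z, x, t]$ (axial depth,
lateral position, time). `sawoce` implements the full chain from that
volume to a velocity profile and a detected interface, twice over:

* a physics-based estimator (**NSA**, numerical spectral analysis) that
  reads the velocity off the frequency–wavenumber spectrum of each depth
  layer, and
* a learned estimator (**PVNet**) that regresses the velocity directly
  from the lateral–temporal phase image of a depth layer.

Because no public SAW-OCE data exist for this problem, the package also
ships a synthetic volume generator with exact ground truth; all tests and
the desk-scale training study run against it.

## From the complex volume to phase images

Surface detection thresholds the time-averaged magnitude at
`noise_mean + k_sigma * noise_sd` (noise floor from the top 5 % of depth
rows, `k_sigma = 5`), then median-filters the per-column result (window
11). Columns with no super-threshold voxel raise an error — a volume of
pure noise has no surface. Flattening shifts each lateral column by an
integer number of pixels; we deliberately avoid sub-pixel interpolation
because integer shifts preserve the complex statistics the spectral
estimator consumes. An optional `margin` leaves air rows above the
flattened surface; it exists because the threshold detector needs a noise
floor above the surface to re-detect one.

Motion is extracted as lag-1 Kasai-style phase differences,
$\Delta\phi[z, x, t] = \arg(c[z,x,t+1]\,\overline{c[z,x,t]})$, wrapped to
$[-\pi, \pi)$. The conjugate product is wrap-safe, unlike subtracting
frame-wise phase angles. Default amplitudes keep $|\Delta\phi| < \pi$, so
no unwrapping is applied; a 1-D temporal unwrap flag exists for stress
tests. One hundred consecutive depth layers below the surface (spacing
`dz`) are retained by default, starting at the surface layer itself — the
first-layer offset is a convention, exposed as `depth_offset`.

## NSA: weighted spectral centroid in the (k, f) plane

For depth $z$, every phase-difference slice in $[z - r, z + r]$
(`depth_radius` $r = 2$; truncated, not padded, at the stack edges) is
mean-removed, apodized with a separable symmetric Hann window in $(x, t)$,
zero-padded (next power of two times `pad_factor = 2`), and 2-D Fourier
transformed. The magnitude spectra are averaged into a stabilized energy
map $S(k, f)$. Mean removal suppresses the DC bin, which would otherwise
bias the centroid toward $k = 0$; padding reduces centroid quantization.

Three further choices deserve explanation:

* **Quadrant selection.** The FFT of a real field is conjugate-symmetric;
  we keep the $f \ge 0$ half-plane and, within it, the wavenumber-sign
  half carrying more ROI energy. A wave travelling one way along $x$
  concentrates in one half, and energy voting makes the choice without
  assuming a propagation direction.
* **Region of interest.** `auto_roi()` brackets the excitation frequency,
  $f \in f_0 (1 \pm \mathrm{band})$ with band 0.5, and maps it through a
  velocity search band ($c \in [1, 20]$ m/s by default, generously
  bracketing agar and skin) to $k \in [f_{min}/c_{max},\,
  f_{max}/c_{min}]$.
* **Energy floor.** Only the central spectral energy — bins at or above
  `energy_floor = 0.5` of the map's peak — enters the centroid. Without
  it, the broadband noise floor integrated over the (large) ROI drags the
  centroid toward the ROI centre; with it, the centroid sees the Hann
  main lobe of the wave and little else.

The velocity is the ratio of the energy-weighted centroid coordinates,

$$ f_c = \frac{\sum f\, S(k,f)}{\sum S(k,f)}, \qquad
   k_c = \frac{\sum k\, S(k,f)}{\sum S(k,f)}, \qquad
   c = \frac{f_c}{k_c}, $$

with $k$ in cycles per metre so that no $2\pi$ appears. Depths whose ROI
holds no energy are recorded as missing; a profile with more than half its
depths missing errors out.

## Smoothing and interface detection

The raw profile is smoothed with robust LOESS (`stats::loess`, degree 1,
`family = "symmetric"`: tricube distance weights, bisquare re-weighting of
residuals), window 30 samples converted to a span fraction. Local linear
fits reproduce straight lines exactly and the bisquare iterations discount
isolated outliers — both properties are asserted in the tests.

Interface detection fits two independent least-squares lines separated by
a free breakpoint, allowing a discontinuity (the velocity jump) at the
interface. The breakpoint is found by exhaustive search over all splits
leaving at least `min_segment = 5` points per segment (5 keeps each
per-segment regression well-posed; the choice is ours). Ties break toward
the shallowest breakpoint. The fit is computed from prefix sums in one
vectorized pass; the tests verify exact agreement with a naive
`lm()`-per-split oracle. Because a single line is a feasible bilinear fit,
`sse <= sse_single` always.

Real profiles need a null verdict: a homogeneous medium should not report
an interface merely because some split minimizes SSE. We emit
`has_interface = FALSE` when the jump is below 0.3 m/s or the bilinear fit
improves on the single line by less than a factor 1.05. Both thresholds
are configurable; 0.3 m/s is far below any layer contrast of interest here
and 1.05 only filters fits indistinguishable from a straight line.

Whether the fit should consume the raw or the smoothed profile is left
open by the method's description; `fit_bilinear(channel =)` provides both,
defaulting to the smoothed channel when present.

## The synthetic volume generator

The generator emulates the acquisition geometry of the target instrument:
a $384 \times 600 \times 600$ (axial $\times$ lateral $\times$ time)
complex volume, `dz = 4.7` µm, `dx = 8.6` µm, a 4 kHz excitation, and a
frame interval chosen so the time axis spans 16 excitation cycles (at
least 8 are needed for a usable temporal spectrum). Below the local
surface the field is

$$ A(z, x)\, e^{i \phi(z, x, t)}, \quad
   \phi = a \sin\!\big(2\pi f_0 (t\,dt - x\,dx / c(z'))\big), $$

with $a$ the peak optical phase modulation (1 rad by default, typical of
nanometre-scale tissue displacement at 1300 nm), $z'$ the depth below the
surface, $c(\cdot)$ piecewise constant per layer, and amplitude decaying
exponentially with depth (e-folding 100 indices, i.e. optical attenuation
over ~0.5 mm) and laterally (e-folding 600 indices). Above the surface
there is only noise: i.i.d. circular complex Gaussian with total standard
deviation `noise_sigma` (0.05 by default) relative to the unit surface
amplitude. The excitation in the instrument is a square wave; the
simulator uses its sinusoidal fundamental because the spectral analysis
operates in a band around $f_0$ — this keeps the spectral ground truth
single-lobed and analytically checkable (harmonics would fall outside
every default ROI anyway).

A `small` preset ($64 \times 128 \times 128$) exists for fast tests and
desk-scale training. It keeps the instrument's ~5.1 mm lateral field of
view by sampling it with 128 pixels of 40 µm instead of 600 of 8.6 µm:
the field of view, not the pixel count, sets the wavenumber resolution,
and at soft-tissue speeds (wavelengths up to ~2 mm at 4 kHz) an aperture
much smaller than a wavelength would make any spectral estimate
meaningless.

What the generator does **not** model, deliberately: guided-wave mode
coupling in thin layers (the depth-dependent velocity enters only through
the local layer's $c$), Rayleigh/Lamb dispersion physics, viscoelastic
attenuation of the wave itself, OCT speckle statistics and decorrelation,
and conversion from velocity to Young's modulus. Tests passing on this
generator therefore demonstrate correctness of the estimation chain under
an idealized single-mode surface wave — not performance on real tissue.

## PVNet

PVNet regresses the phase velocity of one depth layer from its
lateral–temporal phase image. The architecture is a hybrid
convolution/attention pyramid:

* a patch-embedding stem of two 3×3 stride-2 convolutions (4× spatial
  reduction);
* four stages at widths $C_{1..4}$, each of ConvEncoder blocks capped by
  one SwiftFormer attention block, with a 3×3 stride-2 downsampling
  convolution between stages;
* global average pooling and a two-layer regression head emitting one
  scalar (m/s).

The **ConvEncoder** block is
$X + \mathrm{Conv}_{1\times1}(\mathrm{GELU}(\mathrm{Conv}_{1\times1}(\mathrm{BN}(\mathrm{DWConv}_{3\times3}(X)))))$ —
depthwise spatial filtering, cross-channel mixing with a 4× hidden
expansion, and a residual path. The **SwiftFormer** block applies local
mixing ($\mathrm{Conv}_{1\times1}(\mathrm{DWConv}_{3\times3})$), flattens
the grid into tokens, and runs **efficient additive attention** over
RoPE-rotated query/key projections: token scores
$\alpha = \mathrm{softmax}(Q w_a / \sqrt{D})$ pool the queries into one
global query $q = \sum_i \alpha_i Q_i$, which modulates the keys
element-wise; a linear projection of $K \odot q$ plus a query residual is
the output. The cost is linear in the token count — `eaa_ops()` gives the
exact multiply-accumulate count and the tests assert its linearity.
**RoPE** rotates adjacent coordinate pairs of $Q$ and $K$ by angles
$m\,\theta_i$, $\theta_i = 10000^{-2i/D}$, making token interactions
depend only on relative position; positions are the flattened scan-order
token indices (a 2-D axial variant would be possible but is not what the
attention design calls for). The $\sqrt{D}$ score scaling follows the
additive-attention design this block derives from.

Exact layer dimensions for the published variants are not available, so
the package defines its own presets: `tiny` (dims 16/32/48/64, one block
per stage, 64×64 input, ~92k parameters) sized so that a CPU forward pass
is sub-second and a full desk-scale training run takes minutes; `S`,
`base` and `L` scale dims and depths up at 320×320 input. Parameter
counts of these presets are package choices and not comparable to any
published model size.

Inputs are wrapped to $[-\pi, \pi)$ and scaled by $1/\pi$; resizing of
acquisition-sized phase images to the network input is an explicit
preprocessing step (`resize_phase_image()`, bilinear), never hidden inside
`forward`. Targets are standardized on the training split and predictions
are de-standardized, so the optimizer sees unit-scale residuals regardless
of the velocity range. Training labels are the simulator's true
velocities; the pipeline's optional DLI branch instead uses the smoothed
NSA profile as supervision, which is the protocol a real deployment
without ground truth would use.

The whole network — forward, backward, Adam — is implemented natively:
BLAS matrix multiplications for all pointwise/im2col convolutions and
dense layers, small C++ kernels for the depthwise convolutions, GELU
(tanh form) and RoPE rotation, and hand-derived gradients for every layer
including batch normalization and the additive attention. Every block's
backward pass is verified against central finite differences in the test
suite.

## Training protocol and the desk-scale study

Defaults follow the standard protocol for this task: MSE loss, Adam,
initial learning rate $10^{-4}$, batch 128, up to 200 epochs, early
stopping on validation loss with patience 15, best-validation checkpoint
returned. All randomness (split, initialization, shuffling) derives from
the configured seeds; `lr = 0` freezes the model entirely, including
batch-norm statistics, so degenerate runs are bit-reproducible.

The package's desk-scale benchmark trains `tiny` on 2,000 simulated phase
images — 40 homogeneous small-preset volumes with velocities uniform in
[2, 8] m/s, 50 depth layers each, noise 0.05 — for at most 30 epochs at a
learning rate of $10^{-3}$ (the scaled-down regime warrants a scaled-up
rate; $10^{-4}$ is tuned for ~60k-image corpora). Held-out evaluation
uses 200 images from four fresh volumes. The acceptance criterion is a
held-out MAE below 0.3 m/s — an order of magnitude looser than the
instrument-scale figures reported for this architecture class, because
2,000 clean synthetic images are not 60,000 real ones. The test suite
runs the benchmark at three seeds and requires two of three to pass.

## Numerical conventions and degenerate inputs

* Depth indices are 0-based in every profile; physical depth is
  `index * dz` µm (`index_to_depth()` reports mm). Display conventions
  that count layers from 1 are a presentation concern.
* Wavenumbers are cycles per metre everywhere, so $c = f/k$ without
  $2\pi$.
* Phase wrapping maps to $[-\pi, \pi)$ (half-open at $+\pi$).
* The bilinear search breaks SSE ties toward the shallowest breakpoint;
  `z_break` is the depth index of the first point of the lower segment.
* Zero-energy spectra, all-noise volumes, empty profiles, odd RoPE
  dimensions, and mismatched channel counts raise typed errors
  (`sawoce_*` condition classes) rather than producing numbers.
* HDF5 volumes store the complex field as paired float64 `/real`,
  `/imag` datasets with `dz_um`, `dx_um`, `dt_s` and a JSON-encoded
  metadata attribute; round-trips are bit-exact.

## Known limitations

The estimator chain is validated against an idealized forward model; in
particular the simulator cannot exhibit the guided-wave mode mixing that
makes thin-layer inversion hard in practice, so breakpoint accuracy on
real thin layers will be worse than on synthetic profiles. The NSA
centroid remains sensitive to the ROI definition when the spectral lobe
approaches the ROI edge (very fast or very slow media relative to the
search band); widening the velocity band trades robustness for noise
admission. PVNet presets are desk-scale reconstructions of the
architecture, not the published trained models, and their accuracy on
real OCE data is untested by construction.
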