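# sawoce

Depth-resolved surface acoustic wave phase velocity estimation for optical
coherence elastography (SAW-OCE), in R.

SAW-OCE drives a low-frequency surface wave along a sample (skin, an agar
phantom) and tracks it with phase-sensitive OCT. The wave's phase velocity
at each depth reflects the local stiffness, so the depth-resolved profile
`v(z)` — and the depth where it jumps — localizes mechanically distinct
layers such as the epidermal–dermal boundary or a stiff lesion. `sawoce`
is for researchers processing such acquisitions (or prototyping the
processing before hardware exists): it implements the complete chain from
a complex OCE volume `c[z, x, t]` to a velocity profile and a detected
interface.

Two estimators share that chain:

* **NSA (numerical spectral analysis).** For each depth layer, lag-1
  phase-difference images are Hann-apodized, 2-D Fourier transformed into
  the frequency–wavenumber plane, magnitude-averaged over ±2 neighbouring
  layers, and reduced to a velocity by the weighted spectral centroid

  ```
  f_c = Σ f·S(k,f) / Σ S(k,f)
  k_c = Σ k·S(k,f) / Σ S(k,f)
  c   = f_c / k_c          (k in cycles/m, so no 2π)
  ```

  The profile is smoothed with robust LOESS (window 30) and segmented by
  a bilinear fit — two independent OLS lines with a free breakpoint and a
  velocity jump, chosen by exhaustive minimum-SSE search:

  ```
  v(z) = a1·z + b1   (z ≤ z_break)
         a2·z + b2   (z > z_break)
  ```

* **PVNet**, a hybrid convolution/attention regression network (patch
  stem, four ConvEncoder + SwiftFormer stages, efficient additive
  attention with rotary positional embeddings, pooled regression head)
  that predicts the velocity of a depth layer directly from its
  lateral–temporal phase image. It is implemented natively (BLAS matmuls
  plus small C++ kernels, hand-derived gradients, Adam) and trained at
  desk scale on simulated data.

A synthetic SAW-OCE volume generator with exact layered ground truth
replaces the instrument for testing and training; `vignettes/` documents
the forward model, every default, and what the generator deliberately
does not emulate.

## Worked example

Simulate a two-layer phantom (stiff 5.5 m/s cap over a 3.1 m/s substrate,
interface 25 layers below the surface), run the NSA chain, and segment:

```r
library(sawoce)

cfg <- sim_preset("small", layers = list(c(25, 5.5), c(39, 3.1)),
                  noise_sigma = 0.05, seed = 1)
vol     <- simulate_volume(cfg)
surface <- detect_surface(vol)
stack   <- extract_phase_stack(flatten_volume(vol, surface), n_depths = 50)
profile <- nsa_profile(stack, nsa_config(smooth_window = 15), smooth = TRUE)
fit     <- fit_bilinear(profile)
fit
#> <bilinear_fit> break at depth index 25 (jump 1.84 m/s), SSE 2.587 vs single-line 13.18
#>   upper: v = 5.599 + -0.01664 z   lower: v = 3.754 + -0.01654 z   interface: yes
index_to_depth(fit$z_break, 4.7)
#> [1] 0.1175
```

The detected breakpoint sits exactly at the configured interface (depth
index 25, here 0.118 mm below the surface); the upper/lower intercepts
(5.60 and 3.75 m/s at the fitted lines' origins) track the configured
layer speeds, with the jump attenuated by the ±2-layer spectral averaging
across the boundary. `autoplot(profile, fit = fit)` draws the profile,
the smooth, the truth channel and the breakpoint; `tidy(fit)` /
`glance(fit)` give the segments and the fit summary as tibbles.

`run_pipeline()` wires the same stages behind one YAML-configurable call
and writes every artifact (HDF5 volume, surface CSV, profile CSV, fit
JSON, summary, manifest); `inst/scripts/oce_pipeline.R` exposes each stage
as a shell subcommand.

Training the network on simulated data:

```r
pairs <- make_training_set(
  lapply(1:40, function(i) sim_preset("small",
    layers = list(c(64, runif(1, 2, 8))), seed = i, noise_sigma = 0.05)),
  depths_per_volume = 50, image_size = c(64, 64))
fit <- train_pvnet(pairs, training_config(lr = 1e-3, max_epochs = 30),
                   pvnet_config("tiny"))
evaluate_mae(fit, pairs)   # in-sample sanity; use fresh volumes for held-out
```

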