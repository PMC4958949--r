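# dicrecon

Quantitative reconstruction of **optical path length (OPL)** maps from
**differential interference contrast (DIC)** micrographs.

DIC is the workhorse label-free modality of cell biology: cheap, gentle,
and ubiquitous — but qualitative. The image it produces is (to a good linear
approximation) the directional derivative of the specimen's optical path
length along the microscope's shear axis, rendered as bright/dark relief on
a mid-gray background. Segmentation, tracking and any quantitative
measurement work far better on the underlying OPL map than on the relief,
so the derivative must be inverted: a deconvolution problem with a
derivative-type, DC-free point spread function.

This package is for microscopists and image-analysis developers who want
that inversion as plain R functions (matrices in, matrices out) or as a
command-line tool. It provides:

* **The image-formation model.** `G(x,y) = Σ_W K(ξ,η) I(x+ξ, y+η)` with a
  derivative-type kernel `K` — the first derivative of a Gaussian along the
  shear `u` (`u² + v² = 1`), or the difference of two Dirac impulses —
  via `simulate_dic()`, plus phantom generators (`generate_shape_set()`,
  `bead_phantom()`) so everything is exercisable without any data download.
* **The variational reconstruction** `reconstruct_proposed()`: gradient
  descent on `E(I) = Σ(AI − G)² + λ Σ √(Iₓ² + I_y² + ε²)`, a data term
  plus edge-preserving total variation, with three discretizations of the
  Euler–Lagrange data term (moments of the kernel, shear-aligned moments,
  or derivatives moved onto the integral kernel K₀ — the default, exact for
  the full PSF).
* **Six reference algorithms**: Hilbert transform, Wiener filtering,
  regularized inverse filtering (Yin), sparseness-enhanced multiplicative
  update (SEMU), a TV + L1 cone program solved to global optimality by
  primal-dual splitting (SOCP), and the earlier variational scheme with a
  background tether (Feineigle).
* **Evaluation**: normalized MSE, threshold-sweep ROC/AUC (equal to the
  Mann–Whitney rank statistic), and a rotation-fair `benchmark()` driver.
* **Calibration**: bead profile extraction and least-squares scaling that
  converts reconstructed intensities to physical OPL
  (`extract_profiles()`, `fit_scale()`, `apply_calibration()`).

## Worked example

Simulate a 9 µm calibration bead (polystyrene, n = 1.595, in oil,
n = 1.515), reconstruct it, and calibrate intensity to path length:

```r
library(dicrecon)

k <- make_dirac_difference(shear_spec(45))      # DIC PSF, 45 deg shear
truth <- bead_phantom(radius_um = 4.5, delta_n = 0.08,
                      pixel_um = 0.15, size = 71)
g <- simulate_dic(truth, k)                     # the DIC contrast image

rec <- reconstruct_proposed(g, k, variational_params(lambda_tv = 0.1))
#> <dic_recon> proposed, 71x71, 3000 iterations, final energy 7.67635

np <- normalize_pair(rec, truth)
mse(np$recon, np$truth)                         # 0.0314
pearson(np$recon, np$truth)                     # 0.9104

prof <- extract_profiles(rec, center = c(36, 36), length = 33)
cal  <- fit_scale(prof, truth[36, 36 + (-33:33)])
#> <calibration_result> scale = 3.90744, offset = 0.00409113, r = 0.9886
max(apply_calibration(rec, cal))                # 0.694 um  (truth: 0.72)
```

Reading the numbers: the reconstruction correlates 0.91 pixelwise with the
phantom, and the four-direction averaged bead profile matches the
theoretical chord profile `2·Δn·√(r² − ρ²)` with correlation 0.9886. The
fitted scale (3.91 OPL units per intensity unit) converts any
reconstruction from the same imaging configuration into path length; the
calibrated bead peak comes back at 0.694 µm against the true
`Δn × diameter = 0.72` µm — a few percent low, the signature flat-top
flattening of the TV term, which keeps the sharp rim but irons the gentle
spherical cap.

`plot_energy_trace(rec)` shows the monotone energy decay;
`show_image(rec)` displays the map. The same pipeline is scriptable:

```sh
exec/dicr simulate --out set/ --size 64 --seed 1
exec/dicr reconstruct --algorithm proposed --psf set/psf.txt \
    set/dic_001.tif recon_001.tif
exec/dicr evaluate --pred . --truth set/ --metric mse --out results.csv
```

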