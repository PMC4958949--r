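---
title: "Reconstructing optical path length from DIC images: models, algorithms and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing optical path length from DIC images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dicrecon)
```

## The image-formation model

Differential interference contrast (DIC) microscopy shears two polarized
beams by a sub-resolution distance along a unit vector $\mathbf{u} = (u, v)$
and interferes them. Under positive bias the image shows a mid-gray
background with bright/dark relief where the specimen's optical path length
(OPL) changes along $\mathbf{u}$. The package models this linearly: the
contrast image $G$ is a windowed correlation of the OPL map $I$ with a
derivative-type kernel $K$ on $W = [-d, d]^2$,

$$G(x, y) = \sum_{(\xi, \eta) \in W} K(\xi, \eta)\, I(x + \xi,\, y + \eta),$$

with mirror (symmetric) boundary handling. `simulate_dic()` implements
exactly this sum; the test suite pins it to a naive per-pixel double-loop
oracle. Two PSFs are built in: the directional first derivative of an
isotropic Gaussian (`make_gaussian_derivative()`) and the difference of two
impulses at $\pm$`offset` along the shear (`make_dirac_difference()`), the
usual coarse stand-in for the $\sigma = 0.5$ Gaussian derivative. Both are
zero-sum, so constant backgrounds produce zero contrast — which is also why
every reconstruction is only defined up to the lost DC level (and, for a
strictly directional kernel, up to content constant along the shear).
Diffraction and partial coherence are deliberately outside the model, and no
flat-field or bias correction is attempted.

A note on orientation conventions: kernels are `(row, col) = (y, x)` arrays
with the origin at the center pixel, $x$ increasing rightward and $y$
downward, and both built-in PSFs are positive on the $+\mathbf{u}$ side, so
correlating an image with them approximates the image's directional
derivative along $+\mathbf{u}$. The shear defaults to 45° everywhere but is
never hard-coded: every constructor and CLI entry point accepts an explicit
angle.

## The variational reconstruction

`reconstruct_proposed()` minimizes

$$E(I) = \sum_\Omega \bigl(A I - G\bigr)^2
       + \lambda \sum_\Omega \sqrt{I_x^2 + I_y^2 + \varepsilon^2},$$

by explicit gradient descent from $I_0 = 0$, where $A$ is a discretization
of the forward correlation and the second term is a smoothed total
variation (TV). TV preserves discontinuities: its Euler–Lagrange (EL) term
is the curvature flow $\operatorname{div}(\nabla I / |\nabla I|_\varepsilon)$,
which is near zero on straight edges however large their amplitude (the
test suite verifies it responds at least 10× less than a Laplacian on a
large step).

Three discretizations of the data-term EL equation are provided
(`el_data_term()`):

* **`kernel_form`** (default): the derivative is moved from the image onto
  the kernel through the *integral kernel* $K_0$ of
  `make_integral_kernel()`. $K_0$ is the exclusive cumulative sum of the
  PSF along the lattice direction nearest the shear, embedded with two zero
  boundary rings, so its forward difference reproduces the PSF on the
  window interior and all its first differences vanish on the boundary.
  Summation by parts then makes
  $\mathrm{corr}(I, K) = -\mathrm{corr}(\Delta^-_{\mathbf{e}} I, K_0)$ an
  *exact algebraic identity* whenever each PSF line along the step sums to
  zero (true by symmetry for the built-in kernels on axis and diagonal
  shears). This scheme therefore supports the correct PSF exactly.
* **`bilinear`**: the forward operator is replaced by its kernel-moment
  (Taylor) approximation $m_{10} I_x + m_{01} I_y + m_{11} I_{xy}$.
* **`piecewise_constant`**: the shear-aligned variant
  $m_s I_s + \tfrac12 m_{ss} I_{ss} + \tfrac12 m_{tt} I_{tt}$, whose odd
  cross-moments vanish for kernels symmetric about the shear axis;
  asymmetric kernels are rejected with an error naming the violated
  symmetry. Its EL expression involves the gradient of $G$ and the Hessian
  of $I$, and it is the cheapest of the three.

A design decision worth stating explicitly: each scheme's returned descent
direction is the **exact discrete gradient of that scheme's own discrete
energy** (forward operator, mirror boundary, and adjoint all consistent,
with the adjoint of mirror padding implemented as fold-back accumulation).
The master correctness oracle of the test suite — central finite
differences of the energy on random 16×16 images at $10^{-4}$ relative
tolerance — holds for all three schemes and for the TV term with no
discretization slack. On smooth, low-frequency images the three gradient
fields agree (pairwise correlation > 0.95); they differ in how much
high-frequency content the approximation passes.

### Numerical choices

* $\varepsilon$ (`tv_eps`) defaults to $10^{-3}\times$ the dynamic range of
  $G$: a pure TV EL term divides by $|\nabla I|$ and needs the guard; the
  energy reports $\sqrt{\cdot} - \varepsilon$ so constants score exactly 0.
* $\lambda = 0.1$ by default, the value used throughout the bead
  calibration study.
* Step size: fixed user step (default 0.05) with automatic halving (up to
  20 times) whenever a step would increase the energy, and slow regrowth
  after successes. The logged trace is therefore monotone non-increasing
  *by construction*; if no decrease is possible and the gradient is not
  negligible the loop stops with an error advising a smaller step.
* Stopping: relative total-energy decrease below `rel_tol` ($10^{-6}$) over
  10 iterations, or `max_iter` (3000).
* Derivatives: central differences; Hessian entries by composed central
  differences; mirror boundary everywhere, matching the forward model so
  the true phantom is a stationary point of the noise-free energy.
* The final image is clipped to nonnegative OPL.

The earlier variational scheme (`reconstruct_feineigle()`) minimizes
$\sum (K * I - G)^2 + \lambda_1 \sum (\partial I/\partial \mathbf{n})^2 +
\lambda_2 \sum b\,(I - I_{db})^2$ with $\mathbf{n} \perp \mathbf{u}$: the
first penalty suppresses the bright streaks that grow along the shear, the
second tethers estimated background pixels ($b$, from
`estimate_background_mask()`: local variance → Gaussian smoothing → Otsu
threshold — a heuristic that does not guarantee a correct labelling) to a
desired level $I_{db}$. The method predates TV regularization and blurs
edges accordingly; it is here as a comparison baseline.

## The Fourier and algebraic baselines

`hilbert_reconstruct()` multiplies the spectrum by $-i\,\mathrm{sgn}(s)$,
$s$ being the projection of the frequency vector onto the shear. It is a
pure phase filter (an isometry on the zero-mean part) and the fastest
method, but inverts only the *sign* structure of the derivative, not its
magnitude. Frequencies exactly perpendicular to the shear ($s = 0$) and the
sign-ambiguous Nyquist lines of even-sized images are zeroed; both signs of
the filter are valid reconstructions with inverted contrast (`invert`).

`wiener_reconstruct()` and `yin_reconstruct()` divide by the kernel
spectrum with additive regularization (`ns_ratio`, and Laplacian
smoothness + constant sparsity respectively); with `smooth_weight = 0` Yin
reduces exactly to Wiener. The multi-shear origin of the Yin method is
reduced to its single-image form — shear direction cannot be changed
mid-experiment on a standard microscope. All three Fourier methods use the
plain periodic FFT: phase filters and regularized inverses need exact
operator identities (double-Hilbert, Parseval, noiseless inversion) that an
extend-and-crop pipeline would break; the cost is the usual periodic edge
wrap, negligible away from the border. Defaults `ns_ratio = 1e-3`,
`smooth_weight = 1e-3`, `sparse_weight = 1e-4` were fixed once on the
phantom fixtures.

The algebraic pair poses the model in matrix form $\mathbf{H}\mathbf{f} =
\mathbf{g}$ but never materializes $\mathbf{H}$ (for a 256×256 image it
would be $65536^2$); `system_operator()` exposes the forward correlation
and its exact adjoint, which pass a dot-product adjoint test at $10^{-10}$.

* `semu_reconstruct()` solves the nonnegative quadratic program with L2
  Laplacian smoothness and weighted L1 sparsity by a multiplicative
  update: the gradient is split into nonnegative parts using the sign
  split of the composite quadratic kernel and of the linear term, and the
  iterate is scaled by $(N/D)^\gamma$. Zeros are absorbing and every
  iterate is nonnegative exactly. Because the classical update ratio
  guarantees descent only for exact splits, the exponent $\gamma$ is
  halved until the objective decreases — the trace is monotone by
  construction. Optional log-sum reweighting
  $w_i \leftarrow 1/(f_i + \epsilon_w)$ sharpens sparsity.
* `socp_reconstruct()` solves the convex program with isotropic TV and
  plain L1 under $f \ge 0$ to global optimality with Chambolle–Pock
  primal-dual splitting, stopping on primal/dual residual norms. On 12×12
  instances its objective matches an independent box-constrained
  quasi-Newton solution (L-BFGS-B on a negligibly smoothed TV) to
  $10^{-4}$ relative. The quadratic cost of dense formulations is why the
  method is guarded by `max_pixels` (default 64×64) — consistent with its
  exclusion from larger benchmarks on runtime grounds.

## The synthetic phantom sets

`generate_shape_set()` emulates the public synthetic benchmark: 20
ground-truth images — 5 base shapes (ellipse, rectangle, pentagon,
triangle, cross) × 3 rotations as strictly two-valued images, plus the 5
base shapes with a radial intensity ramp as multi-level images — each paired
with its simulated DIC image, with optional additive white Gaussian noise.
The exact shape inventory and rotation count beyond "simple shapes and
rotated versions" is the package's own documented choice; no image-for-image
match with the deposited dataset is claimed. Two conventions are decisions,
not published facts: "20 dB noise" is referenced to the *variance* of the
contrast image (DIC images carry a large constant bias, so mean-square
referencing would understate the visible degradation), and the default
image size is 64×64, chosen so the full 20-image × 7-algorithm benchmark
and all iterative methods run in minutes on one core — the published work
does not state its synthetic image dimensions. Binary shapes are rasterized
by hard point-in-shape tests (no antialiasing) so the two-valued invariant
holds exactly under rotation.

What the generator does *not* emulate: diffraction rings, partial
coherence, camera noise statistics (Poisson), uneven illumination, or the
imperfect real PSF. Passing tests on these phantoms therefore validate the
algorithms and their contracts, not performance on real micrographs.

`bead_phantom()` provides the calibration target: a homogeneous sphere's
OPL is its chord length times the index difference,
$\mathrm{OPL}(\rho) = 2\,\Delta n \sqrt{r^2 - \rho^2}$ — defaults mirror a
9 µm polystyrene bead ($n = 1.595$) in immersion oil ($n = 1.515$), peak
OPL $0.08 \times 9 = 0.72$ µm.

## Evaluation and calibration

Reconstructions are compared after `normalize_pair()`: negative values are
clipped first (they are physically meaningless), then reconstruction and
truth are independently min-max scaled to $[0, 1]$ — the clip-then-scale
order follows the stated protocol literally. `mse()` ranks algorithms;
`roc_auc()` scores against binary masks by thresholding the normalized
reconstruction at every unique value it contains ("every possible value" on
finite data), counting pixels $\ge$ threshold as foreground. With that tie
convention the trapezoidal AUC equals the Mann–Whitney rank statistic with
half-weight ties, which the tests verify by brute force; AUC 1 means
threshold-equivalence to the ground truth. `benchmark()` averages rotated
variants of a base shape before averaging across shapes, so a shape's
weight does not depend on its rotation count.

`extract_profiles()` averages the horizontal, vertical and two diagonal
center-line profiles of a reconstructed bead (diagonal samples live
$\sqrt 2$ px apart and are linearly resampled to integer-pixel radii).
Near the bead rim the chord profile has infinite slope, so pointwise
agreement with the closed form degrades to a few percent at the one or two
rim samples at any realistic pixel size; strictly inside the rim
(|ρ| ≤ 0.98 r) the averaged profile matches the closed form to better than
1% of the peak. `fit_scale()` fits `theoretical ~ scale * measured +
offset` by least squares — an affine rather than scale-only fit, because
reconstructions are only defined up to the lost background level
(scale-only fitting remains available). The TV term's known flat-top
effect — large jumps kept, gentle interior gradients flattened — is visible
in the reconstructed bead profile and is asserted qualitatively in the
acceptance tests; `apply_calibration()` then converts any reconstruction
from the same calibrated system into OPL units.

## A worked run

```{r example, eval = FALSE}
k <- make_dirac_difference(shear_spec(45))
ps <- generate_shape_set(seed = 1)
bm <- benchmark(ps, c("proposed", "semu", "yin", "wiener",
                      "feineigle", "hilbert"))
bm$summary
```

The ranking this produces (proposed lowest mean normalized MSE, the
Fourier inverses mid-field, Hilbert last) is recomputed from scratch by
`scripts/acceptance.R`, together with the bead calibration correlation and
the dataset composition counts.

## Known limitations

* The linear model ignores diffraction; strongly scattering or thick
  samples violate it, and the bead reconstruction inherits a sphericity
  blur that no linear method removes.
* Strictly directional kernels annihilate image content constant along the
  shear; no single-image method can recover it. The inverse filters
  additionally lose DC by construction.
* `piecewise_constant` requires shear-axis-symmetric kernels, and the
  integral-kernel identity is exact only for shears along a lattice axis or
  diagonal; other angles use the nearest lattice direction for the
  cumulative sum.
* Background-mask estimation is a variance heuristic; supplying a curated
  mask to `reconstruct_feineigle()` is always preferable.
* The explicit descent loop is plain (no multigrid or preconditioning), by
  design; very large images are better served by the Fourier methods or by
  lowering `max_iter`.
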