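---
title: "Idealized receptive fields and their invariance mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Idealized receptive fields and their invariance mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visrf)
```

## The model

`visrf` realizes the idealized linear model of the earliest stages of
visual processing: a receptive field is a convolution kernel drawn from
the family of Gaussian derivatives. The scalar-scale spatial family is
generated by the rotationally symmetric Gaussian
$g(x, y; s) = e^{-(x^2+y^2)/2s}/(2\pi s)$ (with $s$ a *variance*, in
pixel$^2$, throughout the package) and its partial derivatives up to
order four; the affine family replaces $s$ by a full covariance
$\Sigma = R(\theta)\,\mathrm{diag}(\lambda_1, \lambda_2)\,R(\theta)^T$
and differentiates along an arbitrary axis $\varphi$ and its orthogonal
complement. Spatio-temporal receptive fields factor as a
velocity-translating spatial Gaussian times a temporal smoother,
$T(x, t) = g(x - v t;\,\Sigma)\, h(t - \delta)$, where $h$ is either a
temporal Gaussian of variance $\lambda_t$ (non-causal, for batch
analysis) or a time-causal cascade of first-order integrators with time
constants $\mu_1, \dots, \mu_K$ — the composed kernel has mean
$\sum_k \mu_k$ and variance $\sum_k \mu_k^2$, vanishes identically for
$t < 0$, and can be evaluated by streaming recursive updates. The
velocity-adapted temporal derivative
$\partial_{\bar t} = v_x \partial_x + v_y \partial_y + \partial_t$
annihilates the translating spatial factor, so $n$-th order
velocity-adapted temporal differentiation reduces analytically to
differentiating the temporal factor.

Phenomenological cell models are built from the same parts: LGN
centre-surround cells as $\pm \nabla^2 g$ composed with a temporal
smoother (space-time separable; on-centre is $-\nabla^2 g$, whose
response to a bright central blob is positive), and V1 simple cells as
oriented directional derivatives of affine Gaussians, optionally
velocity-adapted over space-time.

The structural properties that define this family — and that the test
suite checks as executable contracts — are:

* **Semigroup / cascade.** $g(\cdot; s_1) * g(\cdot; s_2) =
  g(\cdot; s_1 + s_2)$, so coarser scales can be reached by incremental
  smoothing.
* **Diffusion.** $\partial_s L = \tfrac12 \nabla^2 L$, which also makes
  the difference of Gaussians $g(s_2) - g(s_1)$ converge to
  $\tfrac{s_2 - s_1}{2}\nabla^2 g$ as $s_2/s_1 \to 1$.
* **Non-enhancement.** Values at interior spatial maxima never increase,
  and at minima never decrease, with increasing scale.
* **Covariance** under spatial rescaling, affine warps and Galilean
  (constant-velocity) transforms, which the three selection mechanisms
  below convert into invariance.

## Invariance mechanisms

**Scale selection.** Scale-normalized derivatives
$s^{\gamma m/2} L_{x^m}$ have extrema over scale that follow image
rescalings: if $f'(x) = f(x/c)$ then $\hat s' = c^2 \hat s$. The package
defaults to $\gamma = 1$, for which the closed-form calibration holds:
on a rendered blob $g(\cdot; t_0)$ the normalized Laplacian magnitude at
the centre is $s/\pi(s+t_0)^2$ and the normalized Hessian determinant
$s^2/4\pi^2(s+t_0)^4$, both maximal at exactly $\hat s = t_0$.
Signatures are sampled on a logarithmic scale grid (default 2 levels per
octave over $[1, 256]$; the calibration tests use 4 levels per octave)
and extrema are refined by three-point quadratic interpolation in
$\log s$; among several extrema the strongest normalized magnitude wins,
but all are reported. Patches are normalized by resampling with the zoom
factor $\sqrt{\hat s / s_{\mathrm{ref}}}$.

**Affine shape adaptation.** The second-moment (structure tensor) matrix
$\mu$ — Gaussian-windowed averages of
$(L_x^2, L_x L_y, L_y^2)$ — transforms under a warp $f'(x) = f(Ax)$ with
matched covariances as $\mu' = A^T \mu A$ (with unit-mass integration
windows there is no determinant factor; this was confirmed empirically
with the analytic warp oracle). The fixed point of shape adaptation is
$\Sigma \propto \mu^{-1}$, and the normalizing transform is the
principal square root $\mu^{1/2}$, normalized to unit determinant: the
fixed point determines only the foreshortening, with overall scale left
to the scale channel and a free residual rotation. Two design choices
matter in practice and were settled by experiment on warped fixtures:

* The *stable* iteration composes,
  $\Sigma \leftarrow W\,\hat\mu\, W$ with $W = \Sigma^{1/2}$ and
  $\hat\mu = W \mu W$ the tensor seen in the normalized frame (smooth
  *more* along the excess-energy direction). The superficially natural
  replacement $\Sigma \leftarrow \mu^{-1}$ has the same fixed point but
  is the unstable inversion of this map and diverges.
* Because the effective loop gain grows exponentially once the kernel
  attenuates the pattern, steps are accepted by a backtracking rule that
  makes the isotropy residual
  $Q = \lambda_{\max}(\hat\mu)/\lambda_{\min}(\hat\mu) - 1$ decrease
  monotonically across accepted iterations, with the per-iteration
  correction clipped to a factor-4 trust region. The covariance
  condition number is capped at 25 (a slant of roughly 79°): beyond
  that, annihilation of the compressed direction produces spurious
  "isotropy" from numerically dead measurements, not from pattern
  structure.

Defaults: integration covariance $\Sigma_{\mathrm{int}} = r^2 \Sigma$
with $r = 2$ (the coupling is a free choice; a fixed ratio is the
standard one), tolerance $Q < 0.05$, at most 20 iterations.

**Galilean diagonalization.** The spatio-temporal structure tensor over
$(x, y, t)$ satisfies, for a pattern translating at $v$, the advection
identity $L_t = -v \cdot \nabla L$; the velocity solving
$[\mu_{xx}\; \mu_{xy}; \mu_{xy}\; \mu_{yy}]\, v = -[\mu_{xt};
\mu_{yt}]$ zeroes the mixed space-time entries after the Galilean
transform, is exact for pure translation, and is additive under
superimposed Galilean warps. A rank-deficient spatial block (the
aperture problem: a grating determines only the normal flow) raises a
degeneracy error naming the deficient direction, with a condition cap of
$10^4$. Stabilization resamples frames by $x \mapsto x + v(t -
t_{\mathrm{ref}})$.

**Illumination invariance.** On the logarithmic luminosity scale a
multiplicative gain becomes an additive constant, which every
derivative kernel (zero tap sum, exact after mean correction)
annihilates to machine precision; a zero-order kernel is *not*
invariant and the check rejects it explicitly. For a scene
$f = a \cdot i$ (albedo times illumination), $\log f = \log a + \log i$,
so derivative responses equal the albedo responses wherever the
illumination field is constant over the kernel support, with a
Taylor-bounded discrepancy for slowly varying fields.

## Numerical choices

* **Discretization.** Kernels sample the continuous closed forms at
  pixel centres (origin at the central tap) via an exact
  polynomial-times-Gaussian representation of all derivatives, truncate
  at **5** marginal standard deviations per axis, renormalize zero-order
  kernels to unit sum, and mean-correct derivative kernels to an exact
  zero sum. The 5-sd radius (rather than the more common 4) is needed
  for the cascade identity to hold to $10^{-6}$ of dynamic range: at
  4 sd the truncated tail mass (~$3\times10^{-4}$) limits the cascade
  error to ~$10^{-5}$.
* **Convolution.** True convolution $(f * k)(x) = \sum_u f(x-u) k(u)$
  with mirror (reflect-101) boundary by default (preserves constants),
  FFT-backed; spatio-temporal kernels are applied as per-frame 2-D
  convolutions accumulated over temporal taps.
* **Temporal discretization.** The discrete cascade kernel is the
  impulse response of the exact-exponential-step integrators
  ($a_k = e^{-\Delta t/\mu_k}$, stage weights $(1-a_k)a_k^n$). This
  makes streaming and batch evaluation agree exactly, keeps DC gain
  exactly 1 and causality bitwise, and — since the stage weights equal
  the bin integrals of the continuous exponential, placing tap times at
  $(n + K/2)\Delta t$ for a $K$-stage cascade — matches the continuous
  mean and variance to $O((\Delta t/\mu)^2)$. Pure temporal analysis
  resolves the fastest stage with $\Delta t = \min(1, \min_k \mu_k/8)$
  (variance error then below 0.2%); spatio-temporal kernels use one tap
  per frame, as frame-rate data dictates. Temporal derivatives of causal
  kernels are mean-corrected backward differences (causality is
  preserved exactly); non-causal temporal Gaussians are differentiated
  analytically.
* **Interpolation.** All warps are pull-backs
  ($\mathrm{out}(x) = \mathrm{in}(W(x))$) with bicubic (Catmull-Rom)
  interpolation and mirror boundary. Coordinates follow the `(row,
  col)` storage / `(x = col, y = row)` maths convention with the origin
  at the top-left pixel centre for images and at the central tap for
  kernels.
* **TIFF storage.** 32-bit float TIFF samples are stored normalized to
  $[0, 1]$ (the underlying library clamps values outside that range)
  with the affine range in a companion `.range.json`; round-trips are
  exact to single precision. 16-bit PNG is encoded directly by the
  package (the png library only writes 8-bit) and round-trips exactly
  for quantized data.

## Synthetic fixtures: what they do and do not show

All tests run on fixtures rendered in closed form, so every oracle is
analytic and there is no dataset dependency:

* *Blobs* $g(x; t_0)$ rendered exactly, including sub-pixel centres —
  scale-selection calibration.
* *Gratings* with exact phase-shifted translation — aperture-problem
  and annihilation contracts.
* *Ring waves* $J_0(2\pi\|x\|/\lambda)$, whose structure tensor at the
  centre is exactly isotropic by symmetry, with affine warps rendered
  analytically through the quadratic form — affine adaptation. The
  adaptation scale (3 px$^2$) resolves the 12 px wavelength
  ($2\pi^2 s/\lambda^2 \approx 0.4$): in the opposite, strongly
  attenuated regime the measurements ride on the exponential tail of
  the kernel and are numerically meaningless. Interpolated warps of
  noise textures were found to corrupt the second-moment transformation
  law at the few-percent level and are deliberately not used as
  adaptation oracles.
* *Smoothed noise textures* (seeded) — non-enhancement and cascade
  checks; *translating blob sequences* rendered analytically per frame
  (25 frames of 56×56 px, long enough that the temporal kernels never
  fold at the sequence boundary, under which the estimator is exact for
  pure translation) — velocity recovery; *albedo × illumination scenes* with constant, ramp
  or softened sun/shade step layouts and an albedo contrast chosen at
  the natural-texture level (log-reflectance spread ≈ 0.3) —
  illumination invariance.

Passing these checks establishes that the implementation realizes the
idealized theory to the stated tolerances. It does *not* establish
performance on real images, which adds sensor noise, non-Gaussian
statistics, occlusion, multiple motions and non-Lambertian photometry:
the velocity fixtures contain one translating pattern (no transparency),
the affine fixtures are weakly isotropic by construction, and the
illumination model is multiplicative only.

## Known limitations

* Derivative orders are supported up to four (spatial) and two
  (temporal), matching the modelling range of the kernel family.
* The self-similar (scale-covariant) time-causal kernel is not
  implemented; the integrator cascade is the time-causal smoother, at
  the cost of exact covariance under temporal rescaling.
* Velocity estimation is regional (one estimate per window); per-pixel
  flow fields and joint velocity/scale selection are out of scope.
* Affine adaptation assumes the pattern is weakly isotropic in the
  tangent plane; on strongly oriented patterns the fixed point reflects
  the pattern anisotropy itself, not the viewing geometry.
* Scene photometry handles a multiplicative illumination field only;
  camera vignetting and exposure terms are not simulated (a global gain
  is exactly the multiplicative case).
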