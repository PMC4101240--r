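---
title: "Localized active contours with a vascular vector field: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized active contours with a vascular vector field: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselac)
```

## The segmentation problem

Vessels in angiographic and related modalities (DSA, MRA, CT, ultrasound)
are bright, thin, branching tubes on a darker background, frequently with
*intensity inhomogeneity*: the same vessel changes brightness along its
length, which defeats global two-region models of the Chan–Vese type.
`vesselac` segments such structures with a level-set active contour whose
data term is computed from *local* statistics around each contour point,
supplemented by a vesselness-derived directional force that carries the
front into thin and weak branches.

The contour is the zero set of a scalar field $\varphi$ on the pixel grid;
the interior (vessel) region is $\{\varphi < 0\}$. All coordinates in the
package are 1-based `(row, col)` with the row index increasing downward,
and intensities are linearly rescaled to $[0,1]$ at load time, so every
threshold below is expressed on that scale regardless of the input bit
depth.

## Localized region energy

Around a pixel $x$, local interior and exterior mean intensities are
defined through a Gaussian window $K_\sigma$ and a smoothed interior
membership $H_\varepsilon(-\varphi)$ (an arctan-regularized step of width
$\varepsilon$, saturating exactly beyond $\pm\varepsilon$):

$$
f_1(x) = \frac{\sum_y K_\sigma(x,y)\, H_\varepsilon(-\varphi(y))\, I(y)}
              {\sum_y K_\sigma(x,y)\, H_\varepsilon(-\varphi(y))},
\qquad
f_2(x) \text{ analogously with } 1 - H_\varepsilon(-\varphi).
$$

The energy sums, over contour pixels weighted by the regularized Dirac
$\delta_\varepsilon(\varphi)$, the kernel-weighted squared residuals of the
image against $f_1$ (inside) and $f_2$ (outside), plus a length penalty
$v \sum \delta_\varepsilon(\varphi)\,|\nabla\varphi|$ and the distance
regularization $\mu \sum (|\nabla\varphi| - 1)^2/2$ that keeps $\varphi$
close to a signed distance function without explicit reinitialization.

Minimizing the energy in $\varphi$ (fitting means held fixed) gives the
data force implemented in `lrf_force()`:

$$
\delta_\varepsilon(\varphi(z)) \sum_x K_\sigma(z,x)\,
\delta_\varepsilon(\varphi(x))
\left[\lambda_1 (I(z) - f_1(x))^2 - \lambda_2 (I(z) - f_2(x))^2\right],
$$

that is: the intensity at the *updated* pixel $z$ is compared against the
interior/exterior means carried by the contour points $x$ near it. A pixel
resembling the local interior mean is pulled inward ($\varphi$ decreases),
one resembling the exterior is expelled. We stress two discretization
facts that the test suite pins down with brute-force summation oracles:
the kernel stencil is clipped at the image border *without*
renormalization (numerator and denominator clip identically, so the means
stay exact), and a denominator below $10^{-10}$ — a pixel whose truncated
window contains no interior (or exterior) mass at all — marks the pixel
undefined and falls back to the plain kernel-weighted mean, which keeps
the force finite without biasing the residual.

The kernel scale follows the image-size rule
$\sigma = \mathrm{round}((\text{rows} + \text{cols})/16)$ pixels
(`default_sigma()`), the stencil is truncated at radius
$\lceil 2\sigma \rceil$ and renormalized, and $\varepsilon = 1$ px is the
sub-grid smoothing width for both the Heaviside and the Dirac (the same
$\varepsilon$; the vesselness speed threshold below is a distinct
parameter that merely shares the Greek letter in the field's notation).

## Vesselness and the vascular vector field

The directional force uses the standard multiscale Hessian analysis of
bright tubes: at each scale $\sigma_h$ the image is Gaussian-smoothed,
second derivatives are taken and normalized by $\sigma_h^2$, and the
eigenvalues $|\lambda_1| \le |\lambda_2|$ of the $2\times 2$ Hessian give
the vesselness

$$
R = \begin{cases}
0 & \lambda_2 > 0,\\[2pt]
e^{-R_B^2 / 2\alpha^2}\left(1 - e^{-S^2/2\beta^2}\right) & \text{otherwise,}
\end{cases}
\qquad R_B = |\lambda_1|/|\lambda_2|, \quad S = \sqrt{\lambda_1^2 + \lambda_2^2}.
$$

`multiscale_vesselness()` takes the pixelwise maximum over the scale sweep
(default $\{1, 1.5, 2, 3, 4, 5\}$ px, covering vessel diameters of roughly
2–10 px; ties resolved toward the smallest scale for determinism) and
records the maximizing scale and the unit eigenvector $v_1$ of the
smaller-magnitude eigenvalue — the local vessel direction. Defaults:
$\alpha = 0.5$; $\beta$ adapts per scale to half the maximum $S$ observed
in the image at that scale, the usual data-driven choice that keeps $R$
usable across modalities. Only the bright-on-dark polarity is detected
($\lambda_2 < 0$); dark vessels are handled by the `invert` configuration
flag.

The vascular vector field (VVF) is $v_1$ wherever $R > \tau$ (default
$\tau = 0.05$) and zero elsewhere, sign-aligned with $\nabla\varphi$ each
iteration so it points with the outward normal. Its magnitude is the
arctan sigmoid `vvf_speed()`,
$f(R) = \tfrac12[1 + \tfrac2\pi \arctan((R - \epsilon_v)/\epsilon_v)]$
with $\epsilon_v = 0.05$, and the force added to the flow is
$\lambda\, f(R)\, |V \cdot \nabla\varphi|$ with $\lambda = -0.1$ by
default: a negative weight inflates the contour *along* the vessel
direction, which is how tips advance into thin, weak branches; on straight
vessel walls $V \perp \nabla\varphi$ and the term vanishes, so it does not
fatten the segmentation sideways.

## Automatic initialization

The rough initial region is obtained by thresholding the already-computed
vesselness map at `init_threshold`, removing connected components smaller
than `min_object_px` (default 20 px) and filling equally small enclosed
holes. The level set is then initialized to the three-valued field
$-\rho$ / $0$ / $+\rho$ on interior / boundary / exterior, with boundary
pixels (mask pixels 4-adjacent to background, taken on the mask side)
belonging to the object and $\rho = 2 > 2\varepsilon$ so the initial
labels saturate the smoothed step.

Two points deserve emphasis. First, the enhancement step producing the
rough region is deliberately simple — a cut on the vesselness map — and
swappable; a user mask can replace it entirely (`init_mask`). Second, the
default cut is `init_threshold = 0.15`, *stricter* than the VVF gate
$\tau = 0.05$. The two thresholds serve different purposes: the VVF gate
is a recall-oriented cut (dropping a true vessel vector loses the force
that reaches thin branches), while the initialization cut estimates the
vessel *support*. The tube's multiscale response decays to roughly this
level near the tube boundary but stays above $0.05$ for another pixel or
two of scale-space halo; cutting at $0.05$ therefore over-segments by
about the smoothing scale. Because steady-point freezing (below) pins the
far field within a few iterations, the evolution refines the
initialization by only about a pixel, so the rough boundary has to start
near the true one. On the package's phantoms the $0.15$ cut places the
rough mask within a pixel of the truth at both 10% and 28% noise while
covering the full centerline.

## Evolution, narrowband, freezing, stopping

The flow $\partial\varphi/\partial t$ is the sum of the data force, the
length term $v\,\delta_\varepsilon(\varphi)\,\mathrm{div}(\nabla\varphi /
|\nabla\varphi|)$, the regularization $\mu(\nabla^2\varphi -
\mathrm{div}(\nabla\varphi/|\nabla\varphi|))$ and the VVF term, advanced
by explicit Euler with $\Delta t = 0.1$ and defaults $v = 0.2$,
$\mu = 1.0$, $\lambda = -0.1$. Spatial derivatives are central differences
(one-sided at borders); the curvature denominator is floored at $10^{-8}$.

Updates are restricted to a narrowband: all pixels within Chebyshev
distance `band_width` (default 4) of a 4-neighbor sign change of
$\varphi$. Because the force at a pixel depends only on the current
$\varphi$ field — not on which pixels are being updated — the banded step
equals the full-grid step at band pixels exactly (the suite checks
agreement to $10^{-12}$). The fitting means feeding the band update are
evaluated on the band dilated by the kernel radius, since the data force
at a band pixel reads $f_1/f_2$ across its whole window.

Steady-point freezing is the second acceleration: a band pixel whose sign
has not changed for `freeze_patience` (default 10) consecutive iterations
*and* whose $|\varphi| \ge \rho/2$ is frozen permanently — its label is
regarded as final and it is skipped thereafter. The $|\varphi|$ guard
keeps pixels sitting on the contour itself (stable sign, unstable
position) active. Freezing is aggressive by construction: it pins the
flanks of the front within roughly `freeze_patience` iterations, which is
also what stabilizes the computation — see the limitations below.

The run stops when the fraction of band pixels changing sign stays below
`stop_frac` ($10^{-3}$) for `stop_patience` (20) consecutive iterations,
when the band empties, or at `max_iters` (500). The total energy is
recorded per iteration (`energy_every`) as a diagnostic trace only; it is
not a stopping rule.

## The phantom generator

`default_y_phantom()` renders the verification target: a
$110 \times 110$ px branching tube — a vertical trunk (half-width 3 px,
intensity 1.0) splitting into two oblique branches (half-width 2 px,
intensities 0.8 and 0.6) on a black background — with additive zero-mean
Gaussian noise and hard clipping to $[0,1]$. Branch geometry is the
package's own design; the canvas size, the presence of per-branch
intensity differences, and the 28% default noise level are the study
conditions the phantom emulates. "28% noise" is read as a noise standard
deviation of 0.28 times the foreground–background intensity range; the
generator exposes `noise_fraction` explicitly, and its sampling is
seed-deterministic (`withr::with_seed`), so renders are bit-identical
given a seed. Ground truth (the noiseless tube support) and the
rasterized centerlines are returned alongside the image.

What the phantom does *not* emulate: intensity inhomogeneity along a
branch, curved or tapering vessels, structured (correlated or
multiplicative) noise, background texture, and partial-volume blur at the
tube boundary. Passing the phantom tests therefore demonstrates the
machinery — locality of the statistics, noise robustness at the stated
level, recovery of branches with differing intensities — not clinical
performance on any real modality.

## Evaluation metrics

`mrmse()` implements the contour-distance metric used for quantitative
comparison: each truth point is matched to the nearest evolved point
within its $(2r+1)\times(2r+1)$ window (default $r = 12$; many-to-one
matching allowed), and

$$
\mathrm{MRMSE} = \frac{\sum_{\text{matched}} d_i^2 + 2(k_2 + k_3)\,r^2}
                      {k_1 + k_2 + k_3},
$$

with $k_1$ matched truth points, $k_2$ unmatched truth points, and $k_3$
evolved points that were never selected *and* have no truth point within
their own window. Two reading choices are documented rather than implied:
the formula is a mean of *squared* distances — no square root is applied,
despite the metric's name — and the matching rule above (nearest within
window, many-to-one, symmetric-in-spirit $k_3$) is this package's
resolution of an underspecified matching; the test oracle implements the
same rule independently. Contours are compared as sub-pixel point sets
traced by the same marching-squares extraction for truth and prediction.
`dice()` is provided for mask-level overlap.

## Numerical choices and degenerate inputs

* Constant images normalize to all zeros; a constant image yields an
  identically zero data force (residuals cancel), and the vesselness of a
  flat image is identically zero, so the rough mask is empty and the run
  returns the (empty) initialization.
* Exact zeros of $\varphi$ are treated as contour points on the interior
  side when extracting the zero level set (the three-valued
  initialization produces exact zeros).
* The zero Hessian gets eigenvector $(1, 0)$ by convention; its
  vesselness is 0, so the convention never influences the VVF.
* Kernel truncation at $\lceil 2\sigma\rceil$ captures >95% of the
  Gaussian mass and bounds the per-pixel cost at the large $\sigma$
  implied by the size rule.
* Explicit Euler with $\mu\,\Delta t = 0.1$ sits inside the diffusion
  stability bound for the 5-point Laplacian ($\le 0.25$).

## Design decisions on genuinely open points

* **Interior membership.** The interior is $\{\varphi < 0\}$ (fixed by
  the three-valued initialization), so the smoothed membership entering
  $f_1$ is $H_\varepsilon(-\varphi)$. With the opposite reading the data
  force is anti-restoring — the contour expands without equilibrium — so
  consistency of the energy, the force, and the initialization forces
  this choice; the step-image behavior of $f_1/f_2$ (bright interior
  $\Rightarrow f_1 \approx 1$) confirms it.
* **Data-force form.** The force is the variational descent of the
  energy: residuals at the updated pixel, fitting means at the
  neighboring contour points. The variable-swapped alternative (residuals
  at the neighbors, means at the updated pixel) is measurably
  non-discriminating across a thin tube's cross-section — it produces a
  nearly position-independent pressure and a systematic sub-pixel drift —
  and is not a descent direction of the energy, which would also break
  the energy-decrease property the suite verifies.
* **Heaviside width** $\varepsilon = 1$ px: conventional sub-grid
  smoothing; keeps $\delta_\varepsilon$ supported near the contour and
  satisfies $\rho \ge 2\varepsilon$ with the default $\rho = 2$
  (non-strictly; both are configurable).
* **Stopping rule**: sign changes are the observable the freeze logic
  already tracks, so convergence is declared on them; energy is logged
  but deliberately not used (it keeps decreasing slowly during sub-pixel
  drift and has no natural threshold).
* **Freezing is permanent.** Provisional unfreezing was considered and
  rejected: permanence is what yields the speed-up on long contours, and
  the induced distortion is quantified below instead of hidden.

## Known limitations

* **The regularizer and the three-valued start.** The single-well
  distance penalty $(|\nabla\varphi|-1)^2/2$ anti-diffuses wherever
  $|\nabla\varphi| < 1$. The three-valued initialization is exactly such
  a field (plateaus at $\pm\rho$), so an *unfrozen* evolution has no
  discrete fixed point: the zero crossing wanders at a slow, steady rate
  (fractions of a pixel over tens of iterations) even after the data term
  has equilibrated. Steady-point freezing pins the flanks and is what
  makes the computation stationary in practice. Consequently, frozen and
  unfrozen runs agree to sub-pixel boundary distance (MRMSE a few tenths
  of a squared pixel) but not to arbitrarily high mask Dice: for a tube
  only 4–6 px wide, a half-pixel boundary wobble already costs several
  points of Dice. Users comparing accelerated and plain runs should
  compare boundary distances, not thin-structure Dice.
* **Initialization sensitivity.** Because the data force is
  Dirac-weighted twice (once at the updated pixel, once over the contour
  neighborhood), it is weak far from the front; combined with freezing,
  the final boundary is essentially the initialization polished by about
  one pixel. The automatic initialization is tuned to that reality (see
  above); grossly wrong user masks will not be rescued.
* **Problem sizes.** The phantom suite runs on the $110\times110$ canvas
  with the full default pipeline (roughly 40–80 iterations, seconds per
  run); the brute-force oracles run on $\le 20 \times 20$ instances.
  These sizes are the package's verification design; nothing in the
  implementation is specific to them.
* Only 2D single-channel images are supported; 3D volumes are out of
  scope.
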