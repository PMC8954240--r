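---
title: "Multimodal deformable registration with a joint co-sparse analysis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal deformable registration with a joint co-sparse analysis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intra-operative brain shift — the deformation of brain tissue after a
craniotomy — invalidates pre-operative MR images during neurosurgery.
Photoacoustic (PA) imaging is an attractive intra-operative modality because
haemoglobin gives vessels strong optical absorption, so the vessel meshwork
(the surgeon's main landmark) is rendered brightly in real time. Updating the
pre-operative MR image then reduces to a deformable multimodal registration
problem: find the smooth transform that maps the pre-operative MR frame onto
the intra-operative PA frame.

Intensity relationships between PA and MR are nonlinear and spatially
varying, so sum-of-squared-difference metrics fail and histogram metrics such
as normalized mutual information (NMI) are the usual baseline. `cosreg`
implements an alternative built on the co-sparse analysis model, together
with that NMI baseline, a phantom simulator that provides ground truth, and
the standard evaluation metrics.

## The co-sparse analysis model

A signal $x \in \mathbb{R}^n$ (here: a vectorized, zero-mean $7\times7$ image
patch, $n = 49$) satisfies the analysis model when an over-complete operator
$\Omega \in \mathbb{R}^{k \times n}$ ($k > n$) makes $\Omega x$ sparse. The
rows of $\Omega$ act as filters; the index set of (near-)zero responses — the
*co-support* — pins down the low-dimensional subspace containing $x$. The
package measures sparsity with the log-square surrogate

$$g(\alpha) = \sum_k \log(1 + \nu \alpha_k^2),$$

a smooth zero-norm approximation that tightens as $\nu$ grows (`sparsity_g`,
default $\nu = 10^3$). Degenerate operators are excluded by three
constraints: unit Euclidean row norms (the oblique manifold, enforced
exactly by retraction), full column rank, penalized by
$h(\Omega) = -\tfrac{1}{n\log n}\log\det(\tfrac{1}{m}\Omega^\top\Omega)$
(`rank_penalty_h`, $m$ fixed to the row count so the Gram matrix is
row-averaged), and non-redundant rows, penalized by
$r(\Omega) = -\sum_{k<l}\log(1 - (\Omega_k^\top \Omega_l)^2)$
(`coherence_penalty_r`). Both penalties diverge for degenerate operators, so
they enter the learning objective with *positive* weights $\kappa$ and
$\mu$ — minimization then steers away from rank deficiency and duplicated
rows.

### Joint learning

For a registered image pair, co-located patches from the two modalities form
an ensemble sharing a common sparse component. The package learns one
operator per modality by minimizing

$$\frac{1}{N}\sum_i \sum_k \log\!\big(1 + \nu (a_{ik}^2 + b_{ik}^2)\big)
  + \kappa\,[h(\Omega_a) + h(\Omega_b)]
  + \mu\,[r(\Omega_a) + r(\Omega_b)],$$

with $a_i = \Omega_a x_{a,i}$, $b_i = \Omega_b x_{b,i}$: the two responses
share one saturating term per row, which favours solutions in which the
modalities are sparse on a common co-support. Learning uses the *aligned*
(pre-deformation) pair; registration then treats the operators as fixed.
This split resolves an ambiguity in the joint formulation, which nominally
optimizes transform and operators in a single expression.

### ADMM solver

`learn_operators` splits the objective with the constraint
$Y = [\Omega_a X_a; \Omega_b X_b]$ and alternates:

* **Coefficient step** — the proximal operator of the joint surrogate,
  separable over (row, patch) response pairs. Each 2-D prox reduces to a 1-D
  radial problem whose stationary points solve a cubic; all real roots are
  found in closed form, the best is selected by objective value, and a
  guarded Newton polish refines it to $10^{-10}$.
* **Operator step** — a few projected-gradient iterations (default 5, with
  backtracking) on the penalized least-squares sub-problem, each followed by
  retraction of every row to unit norm, so the oblique-manifold constraint
  holds after every sweep, not only at exit.
* **Dual update** — the scaled multiplier absorbs the constraint residual.

Both operators start from one shared seeded random unit-row draw. A shared
start costs nothing (the data immediately differentiates the two operators)
and makes the degenerate single-modality call ($X_b = X_a$) exactly
symmetric, which is a useful invariant to test. Iterations stop at
`max_iter` (default 200) or when both scaled residual norms fall below
$10^{-6}$; a 10-fold growth of the primal residual over 20 sweeps aborts
with the trace attached.

Defaults: $\nu = 10^3$, $\kappa = 10$, $\mu = 0.01$, $\rho = 1$, $k = 2n$
(98 rows for $7\times7$ patches), 2,000 training patch pairs. Patch size 7
balances expressiveness against over-smoothing and cost; 20,000 pairs (and
any other setting) remain available through the configuration objects.

## The registration cost

The fixed/reference image is the pre-deformation MR; the float is the
deformed PA. The package uses backward warping throughout: a transform $T$
stores a displacement $u$ on the reference grid, the warped float is
`float(x + u(x))`, and the same $u$ maps reference-frame landmarks into the
float frame — one convention shared by `warp_image`, `transform_points`,
the cost, and the evaluation, so no silent sign errors are possible.

The registration similarity realizes the model's central claim — matched
patches have *intersecting co-supports* — directly. With the learned pair
stacked, $\Omega_s = [\Omega_{PA}; \Omega_{MR}]$, applied to both patches,
define soft co-support indicators $s = \log(1 + \nu(\Omega_s p)^2)$
(elementwise). The cost at sample centre $x_i$ is minus the Pearson
correlation of the two indicator vectors, averaged over centres
(`coupled_cost`):

$$C(u) = -\frac{1}{N}\sum_i
  \mathrm{corr}\!\big(s(\mathrm{ref}, x_i),\;
                      s(\mathrm{float}, x_i + u(x_i))\big).$$

Three properties motivated this form over a plain joint $g$-sum, which was
tried first and measurably fails:

* a $g$-sum over one warped side is reduced by moving sample windows onto
  structureless float regions, an incentive with no alignment meaning;
* its only alignment force relies on row-paired co-activation across two
  separately adapted operators, which is weak — accidental wrong-structure
  matches can then outscore true matches (on the phantom, descent reached
  costs well below the true deformation's while landmark error worsened);
* the correlation is scale-free and bounded: inflating or suppressing
  response magnitudes cannot improve it, matched geometry activating the
  same rows of the stacked operator maximizes it, and a mono-modal pair at
  perfect alignment is exactly stationary.

Stacking makes responses row-comparable by construction while still using
the learned, modality-adapted filters; the learning step itself keeps the
plain joint $g$ objective.

## The optimizer

Both registrars share one scaffold (`register_jacsm` swaps only the metric
relative to `register_nmi`):

* **Transform** — cubic B-spline free-form deformation, knots every 16 px on
  the full-resolution domain, identity-initialized.
* **Pyramid** — 2 levels (block-mean $\times2$, then full resolution). The
  simulated vessels are 2–3 px wide, so a $\times4$ level retains no vessel
  structure and is counter-productive.
* **Sampling** — patch windows on a regular grid with stride 5 px
  (overlapping windows constrain the metric: a false local match cannot
  satisfy many overlapping windows at once). Only centres whose *reference*
  patch standard deviation is in the upper quartile are kept: structureless
  reference windows carry no alignment information but let a sampled metric
  be gamed by sliding them onto arbitrary float content; because the mask is
  computed on the fixed reference, the optimizer cannot exploit it. Both
  levels prefilter the images with a 1 px Gaussian so that the pixel noise
  floor, whose effective smoothing would otherwise depend on the fractional
  part of a displacement, does not bias the metric toward off-grid
  solutions. Window sampling is bilinear by default; a fixed-width Gaussian
  kernel sampler (`sampling = "kernel"`) is available for magnitude-based
  metrics, whose interpolation bias does not cancel.
* **NMI baseline** — same windows; the histogram (32 equal-width bins per
  axis) is built from all sampled pixel pairs, updated incrementally per
  window for the local gradients.
* **Gradients** — central finite differences on the control displacements
  (step 0.5 px), computed per knot over the affected windows only, then
  smoothed over the knot grid (1 knot Gaussian) so updates live in
  deformation modes no rougher than the knot spacing.
* **Regularization** — a small bending-energy penalty (mean squared second
  differences of the control grid, weight $2\times10^{-4}$) and a box bound
  of 12 px on control displacements, reflecting that brain shift is a
  bounded, smooth phenomenon.
* **Line search** — backtracking on the full cost with strict decrease, so
  every cost trace is non-increasing by construction; a level stops when the
  relative decrease falls below $10^{-4}$.

With the trivial (constant) metric the optimizer returns its initialization
unchanged, and registering an image to itself with a consistent operator
pair returns the exact identity — both are asserted in the tests.

## The phantom simulator

No public data accompany the physical experiments this package emulates, so
`generate_phantom` provides the study conditions: a 150 × 40 mm tissue slab
with a half-elliptic (head-like) top surface on a 256 × 256 canvas at 0.6 mm
spacing, with two gently curved near-horizontal tubes of 1.2 and 1.4 mm
inside diameter. Renderings are analytic contrast models, not physics
simulations — the claim under test is registration behaviour:

* **MR** — homogeneous gel body (0.6 with a mild smooth texture of
  amplitude 0.05) with strongly enhancing contrast-filled tubes (1.0), a
  0.8 px point-spread blur and additive Gaussian noise ($\sigma = 0.02$);
* **PA** — dark tissue (0.05), bright vessels (1.0), both multiplied by the
  optical depth attenuation $e^{-0.1\,\mathrm{depth\,[mm]}}$ measured from
  the top surface — so vessels outshine tissue at every depth — plus blur
  and noise;
* **US** — speckled tissue (multiplicative gamma noise of strength 0.4)
  with weak vessel contrast.

Landmarks (default 5, minimum 3) sit on vessel centrelines. The simulated
brain shift is Gaussian noise per displacement channel smoothed with a 32 px
($\approx$ 19 mm) correlation length and rescaled so the maximum magnitude
is exactly 8 px (4.8 mm): brain shift is a bulk, gravity-driven sag, so a
long correlation length is the realistic emulation. The deformation is
applied to the float (PA) image only, and the generator retains the field so
evaluation can compute displacement-error metrics.

What the simulation does *not* emulate: acoustic propagation, laser fluence,
spectral unmixing, transducer geometry, real MR texture and artifacts, 3-D
effects, or deformations with folding. Passing tests therefore show that the
method recovers smooth bounded deformations from vessel-and-surface contrast
under modality-specific renderings — not that it meets any clinical
accuracy requirement.

## Evaluation

`evaluate_run` computes, against the simulator's ground truth:

* **TRE** — Euclidean mm distance at the vessel landmarks between the
  transform-mapped position and the true corresponding position in the
  float image (the ground-truth correspondence field is the fixed-point
  inverse of the applied deformation, `invert_field`);
* **RMSE** — root-mean-square residual displacement-vector error in mm over
  the whole field (an intensity-difference reading of "RMSE" would be
  incomparable across modality pairs; the displacement reading matches the
  mm scale of the other metrics);
* **HD95** — 95th-percentile Hausdorff distance between vessel-mask
  boundary points of the reference and of the registration-compensated
  float mask; percentiles interpolate linearly between order statistics
  (type 7) and are applied to each directed nearest-neighbour distance
  distribution before the outer maximum. The classical maximum HD is
  attached as an attribute and always bounds HD95 from above.

An `unregistered` baseline row (identity transform) is always reported, so
improvement percentages are computed rather than assumed.

## Numerical conventions

* 0-based pixel indices, (row = y, col = x), pixel centres at integer
  coordinates, physical position = index × spacing + origin.
* Row-major patch vectorization (row offset slowest).
* Natural logarithms throughout; co-support indices are 1-based (R
  convention).
* Out-of-domain samples clamp to the edge during registration (dropping
  windows instead makes the sampled mean discontinuous and penalizes the
  true deformation when informative border windows leave the domain);
  zero-padding is available for visualization.
* All randomness is seeded; `run_experiment` derives per-stage, per-repeat
  seeds from the master seed through a fixed counter scheme, so adding a
  repeat never perturbs earlier repeats and identical configurations
  reproduce byte-identical reports.

## Problem sizes used by the test suite

The packaged tests run the full study at its native 256 × 256 / 0.6 mm
conditions with five repeats for the registration and method-comparison
checks, 2,000 training and 1,000 held-out patch pairs over five seeds for
the learning check, and a 128 × 128 / 1.25 mm configuration (same geometry,
coarser grid) for the fast unit tests.

## Known limitations

* The multimodal similarity (either method) has a sub-pixel bias floor: its
  optimum sits ~0.2–0.7 px off the geometric truth because the modalities
  render the same structure differently. Zero-deformation runs therefore
  report sub-pixel, not zero, errors.
* The phantom's structure is effectively one-dimensional (tubes and a
  surface); displacement components along structures are only weakly
  observable and are recovered mainly through the smoothness of the
  transform model.
* Finite-difference gradients keep the implementation simple and
  verifiable; an analytic chain rule would be the natural speed-up.
* 2-D only; no rigid/affine pre-alignment; no diffeomorphic guarantee
  beyond the bending penalty and displacement bound.
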