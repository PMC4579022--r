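---
title: "Displacement-field morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Displacement-field morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models each
stage implements, the tunable parameters and why their defaults are what
they are, what the synthetic phantom does and does not emulate, and the
design decisions taken where the method left room.

## 1. The pipeline and its assumptions

`dfmorph` classifies subjects by how their brain anatomy deviates from a
normal template, measured as a dense displacement field on a handful of
informative coronal slices. The pipeline assumes its inputs are already
motion-corrected and rigidly normalised to a common space; only an
in-plane rigid refinement (rotation + translation, mean-squared-error
objective, Nelder-Mead with BFGS polish from the identity) is applied
before non-rigid registration. Gray levels are compared directly — no
intensity normalisation — so cohorts must be acquired or harmonised
consistently.

## 2. Key-slice selection

The inter-class variance of coronal slice $k$,
$v(k) = \lVert \mu_A(k) - \mu_N(k) \rVert^2$, scores how much the AD and
NC group mean images differ there. A slice is kept when $v(k)$ strictly
exceeds half the maximum of the curve *and* its coronal index is
divisible by the undersampling step (default 10, anchor configurable).
The two conditions are applied as a conjunction; whether a failing
multiple-of-step slice should recruit a neighbour instead is left
unspecified by the selection rule as stated, and the conjunction is the
simplest reading. Because the threshold is relative, rescaling all
intensities by $c$ multiplies every $v(k)$ by $c^2$ and leaves the
selection unchanged.

## 3. Level-set displacement-field estimation

The moving image $I_1$ evolves along its own gradient direction until it
matches the reference $I_2$:
$$\frac{dV}{dt} = \bigl(I_2 - I_1(V)\bigr)
  \frac{\nabla I_1(V)}{\lvert \nabla I_1(V) \rvert},$$
where $I_1(V)$ is $I_1$ backward-warped by $V$ (bilinear interpolation,
boundary values clamped; $u$ = horizontal component, $w$ = vertical,
0-based pixel coordinates). The scheme itself leaves the discretisation
open; this package fixes:

* **Explicit Euler steps**, $\Delta t = 0.4$ by default, with a
  step-acceptance rule: a step is kept only if the residual
  $\lVert I_2 - I_1(V) \rVert$ does not increase, otherwise the local
  step size is halved and the update retried. The logged residual
  sequence is therefore non-increasing by construction, and divergence is
  impossible rather than detected.
* **Gradient stabilisation**: the normalising $\lvert \nabla I_1(V)
  \rvert$ receives an additive floor of $10^{-3}$ times the intensity
  range, so gradient-free regions produce zero update instead of noise
  amplification.
* **Regularisation**: the update force is Gaussian-smoothed with
  $\sigma = 1.5$ px before integration (fluid-like), and the accumulated
  field with $\sigma = 0.5$ px after each step (diffusion-like). An
  earlier variant that smoothed only the accumulated field with
  $\sigma = 1.5$ stalled near 60 % residual reduction on phantom pairs;
  splitting the regularisation this way reaches >90 % reduction with
  sub-pixel endpoint error while keeping the field smooth. Both sigmas
  are exposed in `levelset_params()`.
* **Stopping**: 200 iterations or relative residual change below
  $10^{-4}$, whichever first.

Two regimes deserve different schedules. Matching *appearance* (for
features) converges quickly; recovering the *magnitude* of displacement
inside texture-free regions (for region detection) relies on the slow
diffusion of boundary information, so `run_region_detection` examples and
tests run the solver to 1200 iterations. Registration of two images can
only estimate displacement where intensity varies; inside perfectly
homogeneous regions the reported magnitude is an interpolation, not a
measurement.

## 4. Features and PCA

Per subject and key slice, the template (the per-slice mean NC image by
default; a fixed single NC subject is an option) is registered to the
subject — template as moving, subject as reference, so the field describes
how the normal anatomy must deform to become the subject. The field's
polar form supplies two channels: magnitude, and direction mapped to
$[0, 2\pi)$ with the convention that zero-magnitude pixels get direction
0. Direction values are treated as plain features (no circular
statistics); both channels are concatenated by default and either can be
selected alone. PCA retains the components explaining 95 % of variance
(configurable); inside cross-validation it is fitted on training rows
only and applied to validation rows.

The template is computed from the whole cohort's NC group once, before
cross-validation. Strictly, validation subjects therefore contribute to
the template if they are NC; the alternative (per-fold templates) changes
the feature space across folds and prevents out-of-fold assembly. The
per-fold PCA + classifier, which actually see the labels, are leakage-free.

## 5. GEPSVM

With class sample matrices $X_1$, $X_2$ and $U = (w, b)$, the first plane
minimises the Rayleigh quotient $U^T P U / U^T Q U$ with
$P = [X_1\; {-o}]^T [X_1\; {-o}] + tI$ and
$Q = [X_2\; {-o}]^T [X_2\; {-o}]$, solved as the generalized eigenvalue
problem $PU = \lambda QU$; the second plane swaps the classes. The
implementation reduces the pencil to an ordinary symmetric eigenproblem
through a Cholesky factor of $Q$; when $Q$ is singular it factors $P$
instead and uses $\lambda_{\min}(P, Q) = 1/\mu_{\max}(Q, P)$, which the
Tikhonov term ($t = 10^{-4}$ by default) guarantees to exist. Only when
both matrices are singular at $t = 0$ does fitting fail, with the advice
to set $t > 0$. Every fit records the relative eigen-residual
$\lVert PU - \lambda QU \rVert / \lVert U \rVert$; tests require it below
$10^{-6}$. Note the Tikhonov term breaks exact feature-scale invariance;
at $t = 0$ predictions are provably unchanged under rescaling.

## 6. TSVM

The twin SVM fits plane 1 by
$$\min_{w_1, b_1, q} \tfrac12 \lVert X_1 w_1 + o b_1 \rVert^2
  + c_1 o^T q \quad \text{s.t.} \quad -(X_2 w_1 + o b_1) + q \ge o,\;
  q \ge 0,$$
and plane 2 by the role-swapped program. Both duals are box-constrained
QPs in one multiplier per opposite-class sample,
$\max_\alpha\, o^T\alpha - \tfrac12 \alpha^T G (H^TH)^{-1} G^T \alpha$,
$0 \le \alpha \le c$, with $H = [X_P\; o]$, $G = [X_D\; o]$. The package
solves them with its own projected-gradient solver (Barzilai–Borwein
steps, monotone Armijo safeguard, periodic active-set Newton polish,
KKT tolerance $10^{-10}$); an independent interior-point solver
(`kernlab::ipop`) serves as the oracle in tests, with objectives agreeing
to $10^{-6}$. A ridge of $10^{-8} \cdot \mathrm{tr}(H^TH)$ regularises
the inversion. Primal feasibility, complementary slackness and the
duality gap are recorded per fit.

One property matters for experiment design: the one-sided margin
constraints admit a degenerate optimum. If a data set places the distant
class on *both* sides of the proximal class's natural plane (the
symmetric X-shaped crossing-lines configuration), the constant solution
$w = 0$, $b = -1$ — "a plane at infinity" — has objective $m_1/2$ and
beats every informative plane for any penalty $c \ge$ about $0.5$, while
small penalties drive $w \to 0$ with $b \to 0$. The bundled
`crossplanes_data()` benchmark therefore places the crossing point
off-centre with asymmetric arms (so each class lies on one side of the
other's plane) and excludes a small zone around the intersection, where
any nearest-plane rule is undefined; the twin QPs are fitted with
$c_1 = c_2 = 0.1$ there. On that geometry both non-parallel-plane
classifiers reach 100 % training accuracy while no single hyperplane
exceeds ~75 %.

## 7. Prediction rule and baseline

Neither non-parallel-plane formulation fixes a decision function; the
standard nearest-plane rule with norm-normalised distance is used for
both, with ties assigned to class 1 (AD), biasing ties toward
sensitivity. The baseline is a soft-margin linear SVM ($C = 1$); its dual
(box bounds plus one equality constraint) is formulated in-package and
solved by `kernlab::ipop`, with an escalating ridge for the rank-deficient
case $p \ll n$ and a majority-class constant fallback for fully
degenerate inputs. Optimality is certified by the primal-dual duality
gap ($<10^{-6}$ on well-conditioned problems).

## 8. Region detection

$R = \{(x, y) : \lvert V(x, y)\rvert > T\}$ with strict inequality;
$T = 5$ px by default, a value that separates deformation treated as real
shape change from estimation noise. Detection is exact by construction
and tested against per-pixel brute force. An optional brain-mask
intersection can suppress background detections (off by default, matching
the plain rule). Dice overlap is evaluated against the zone where the
*ground-truth* magnitude exceeds $T$: the full support of the nonzero
deformation is several times larger than its supra-threshold core, so
even a perfect estimator could not reach Dice 0.5 against the full
support, and that comparison is not used.

## 9. Evaluation protocol

Stratified K-fold splitting deals the shuffled classes round-robin with a
single rotating fold pointer, which guarantees per-class counts *and*
total fold sizes within one of each other (126 subjects at $K = 10$ give
six folds of 13 and four of 12). Stratification is the default because at
a 28/98-style imbalance unstratified folds frequently lose the AD class;
`stratify = FALSE` restores plain random splits. Each repetition draws a
fresh split from `seed + repetition`; per fold, PCA and the classifier
are fitted on training rows only; the out-of-fold predictions are
assembled into one confusion table per repetition (not averaged per
fold), and metrics are summarised as mean ± SD over repetitions.
Undefined ratios (empty denominator) propagate as `NaN` with a warning
rather than a silent zero. Hyperparameters default to $t = 10^{-4}$,
$c_1 = c_2 = 1$, $C = 1$; they are deliberately not tuned inside the
reference protocol, and any tuning must be nested in the training folds.

## 10. The phantom: what it emulates, and what it does not

`make_phantom_slice()` draws the three tissue classes whose shape change
is diagnostic: a bright cortical ring, a dark central ventricle (two
mirrored ellipses) and two hippocampus-like blobs, on a mid-gray brain
disc, lightly smoothed, with additive Gaussian noise (default
$\sigma = 0.01$ in [0,1] intensity units — realistic for averaged
structural MR, and chosen so that the $2\sigma^2$ noise floor on the
registration residual leaves the solver's $\ge 80\,\%$ MSE-reduction
property attainable at all). The AD deformation is parametric and known:
a radial homothety of factor `ventricle_scale` around the ventricle
centre (exact out to a radius covering the enlarged ventricle, then
cosine-tapered, so the dark area scales by the factor squared), plus a
radial compression of the cortical ring toward its fixed outer edge
implementing `cortex_scale`, the whole field Gaussian-smoothed
($\sigma = 2$). Across the simulated coronal axis the brain cross-section
waxes and wanes and the deformation amplitude is windowed to the central
slices, so key-slice selection has a ground truth to find. Default effect
sizes (`ventricle_scale = 1.5`, `cortex_scale = 0.85`) are in the range
of gross ventricular enlargement reported for clinically evident AD; no
public cohort quantifies the exact morphometry the phantom should match,
so these are stated conditions, not calibrated estimates. Default cohort
composition keeps roughly 1 AD : 3 NC, mirroring the imbalance regime of
clinical samples, which is what makes precision behave differently from
specificity.

What the phantom does **not** emulate: 3-D anatomy and partial-volume
effects, intensity inhomogeneity, multi-site contrast differences,
anatomical variability beyond smooth geometric jitter, and any
deformation outside the two modelled effects. Passing on phantoms
therefore validates the *machinery* — registration accuracy, feature
propriety, leakage-free evaluation, classifier correctness — not clinical
performance.

## 11. Problem sizes used in the reference experiments

Displacement-field recovery uses ten 96 px phantom pairs with
`ventricle_scale = 1.3` and noise $\sigma = 0.005$, keeping the
ground-truth magnitude under 5 px — a controlled registration benchmark
near the noiseless regime. Cohort experiments use 16 subjects
(4 AD / 12 NC) at 128 px with 10 slices and a 5-repeat 10-fold protocol;
a full 50-repeat protocol is a flag away but adds nothing statistically
on a cohort this small. The zero-effect (null) cohort is evaluated with
the SVM baseline, whose degenerate-margin behaviour is a constant
majority-class vote, making "accuracy equals the majority fraction" the
correct null expectation; the nearest-plane rules of GEPSVM/TSVM have no
majority prior, so their null accuracy is not a calibrated quantity.

## 12. Known limitations

* Magnitude estimates inside homogeneous tissue are diffusion
  interpolations (section 3); thresholded regions are reliable near
  edges, conservative in flat interiors.
* The mean-NC template couples NC validation subjects into the feature
  definition (section 4).
* Linear kernels only, matching the formulations implemented.
* The TSVM degenerate optimum (section 6) means its penalties need care
  on geometries where classes straddle each other's planes.
* `NaN` metrics can occur in tiny cohorts when a repetition predicts no
  positives; they are excluded from precision summaries and flagged.
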