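---
title: "Simulating surgical brain retraction: model, discretisation and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating surgical brain retraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retractsim)
```

## The problem

Inserting retractor blades to open a path to a deep surgical target
displaces brain tissue by several millimetres and — unlike craniotomy-induced
brain shift — creates a genuine discontinuity: the tissue is split along the
retraction path. Navigation systems that keep displaying the preoperative
image therefore mislead exactly where precision matters. `retractsim`
simulates this process: given a segmented brain volume, the geometry of the
retraction path, and tracked displacements of the retractor surfaces, it
computes the discontinuous volumetric deformation field and resamples the
preoperative image into a predicted post-retraction image.

## Constitutive model

Brain parenchyma in compression and extension is described by a one-term
Ogden hyperelastic energy of the principal stretches
$\bar\lambda_i$ (isochoric part),

$$W_\mathrm{iso} = \frac{2\mu_0}{\alpha^2}\left(\bar\lambda_1^\alpha +
  \bar\lambda_2^\alpha + \bar\lambda_3^\alpha - 3\right),$$

combined with Prony-series stress relaxation

$$\mu(t) = \mu_0\Big(1 - \sum_k g_k\big(1 - e^{-t/\tau_k}\big)\Big).$$

The package defaults are the porcine-brain parameters
$\mu_0 = 842$ Pa, $\alpha = -4.7$, $(\tau_1, g_1) = (0.5\,\mathrm{s}, 0.450)$
and $(\tau_2, g_2) = (50\,\mathrm{s}, 0.365)$, giving an instantaneous shear
modulus of 842 Pa and a long-term modulus of
$842\,(1 - 0.450 - 0.365) = 155.77$ Pa. The negative exponent makes the
tissue markedly stiffer in compression than in extension, which is what
uniaxial tests on brain samples show.

```{r}
m <- ogden_material()
relaxation_modulus(m, c(0, 0.5, 50, Inf))
```

Only shear parameters are published for this tissue, so compressibility is a
modelling decision: we use an isochoric/volumetric split with a quadratic
volumetric penalty $U = K/2\,(J-1)^2$ and derive $K$ from an equivalent
Poisson ratio (default 0.49, near-incompressible but numerically benign;
configurable through `material: poisson`). Tests that compare against the
closed-form *incompressible* uniaxial solution use 0.4995, where the two
models agree to well under 1 %.

Viscoelasticity acts on the isochoric stress only. The internal variables
$Q_k$ (one stress-like tensor per Prony term) follow the recursion

$$Q_k^{n+1} = e^{-\Delta t/\tau_k} Q_k^n +
 g_k\,\frac{\tau_k}{\Delta t}\big(1 - e^{-\Delta t/\tau_k}\big)
 \big(S_\mathrm{iso}^{n+1} - S_\mathrm{iso}^n\big),$$

which is the exact convolution when $S_\mathrm{iso}$ varies linearly within
a step; the test suite checks it against brute-force trapezoid convolution
quadrature on random strain histories. Internally all stresses are second
Piola–Kirchhoff tensors; Cauchy stresses are obtained by push-forward for
reporting, so the stress convention in every test is unambiguous.

The material interface is pluggable: `linear_material()` provides a St
Venant–Kirchhoff model with the same API for the linear-elastic comparison
mode.

## Discretisation: octree hexahedra and XFEM enrichment

The segmented brain is meshed with a uniform axis-aligned hexahedral grid:
the mask's bounding box is divided into the coarsest grid with edge length
below `max_edge` (default 5 mm — one uniform octree level; the meshes of
interest run to a few thousand nodes), and every cell containing at least
one masked voxel centre becomes an element. The inclusion threshold is
configurable; one voxel centre reproduces the generous coverage behaviour
expected when a mesh is generated directly from a segmentation.

The crack (the retraction path) never conforms to this mesh. It is
represented by two level sets — $\varphi$, the signed normal distance to the
crack surface, and $\psi$, the signed distance past the crack front — with
the crack being $\{\varphi = 0,\ \psi \le 0\}$. The displacement field is
enriched:

$$u(x) = \sum_{i \in I} N_i(x)\,u_i
 + \sum_{j \in J} N_j(x)\big(H(x) - H_j\big)\,a_j
 + \sum_{m \in M} N_m(x) \sum_{l=1}^4 \big(F_l(x) - F_l(x_m)\big)\,b_m^l,$$

with $H = \operatorname{sign}\varphi$ on nodes of cut elements ($J$) and the
four $\sqrt{r}$-type branch functions on nodes of elements containing the
crack front ($M$). We use the *shifted* form (subtracting the nodal value of
each enrichment function), for two reasons: standard degrees of freedom keep
their nodal-interpolation meaning, and prescribed crack-face displacements
become expressible exactly — for a Heaviside node the face on the node's own
side takes the value $u_j$ and the jump is $2a_j$, so prescribing both faces
$(u^+, u^-)$ is the exact linear map $u_j = u^{s_j}$,
$a_j = (u^+ - u^-)/2$. A welcome side effect of shifting is that Heaviside
enrichment vanishes identically on uncut elements, so no blending treatment
is needed for $J$; tip functions do blend into neighbouring elements and are
integrated there.

Nodal level-set values within $10^{-6}$ of an element edge of zero are
snapped to the positive side, so a crack coincident with a mesh plane can
never produce a degenerate cut.

Cut, tip and tip-blending elements are integrated with a regular
$4^3$ sub-cell midpoint rule, classifying each sample point by its side of
the crack; uncut elements use the standard $2^3$ Gauss rule. A
crack-conforming tetrahedral subdivision would integrate the cut volume
fractions exactly, but the regular sub-cell rule is robust for arbitrary
plane poses, and all kinematic identities (patch test, rigid face opening,
jump reproduction) hold exactly or to quadrature accuracy; the residual
volume-fraction error only perturbs the equilibrium solution at a level far
below the mesh discretisation error.

## Boundary conditions from tracked retractor surfaces

Two displacement BC families close the problem: a zero-displacement set (the
brain-stem region, where the organ is anchored — for enriched nodes both
crack faces are pinned) and prescribed crack-face displacements in the
retraction region. The latter are recovered from point clouds of the
retractor surfaces: the scanned inner surface is extruded by the blade
thickness (2.9 mm) along its normals, the pre- and post-retraction clouds
are registered with coherent point drift (CPD — an EM algorithm with a
uniform outlier component, default weight 0.1; rigid and affine modes), and
the per-point displacements are transferred to the Heaviside-enriched nodes
of elements touched by the cloud by inverse-distance weighting within one
element size. Affine mode is the pipeline default because a V-shaped opening
whose magnitude tapers linearly with depth *is* an affine field on the blade
surface, so the registration can represent it exactly; rigid mode is
appropriate when blade bending is negligible and is what the parameter
recovery tests exercise.

## Solving the nonlinear system

The discrete equilibrium equations are solved by damped Newton iteration in
a total-Lagrangian setting, with the prescribed DOFs eliminated (satisfied
exactly) and the loading ramped over `increments` pseudo-time steps spanning
`duration` seconds (defaults 10 and 30 s; `duration = 0` gives the
instantaneous hyperelastic response). Three numerical choices matter:

* **Analytic consistent tangent.** $dS/dE$ is assembled from the spectral
  decomposition of $C$: the $2\,\partial s_i/\partial c_j$ normal block plus
  principal-shear moduli $(s_i - s_j)/(c_i - c_j)$ with the l'Hôpital limit
  at (near-)equal stretches. A central-difference tangent is retained as an
  independent cross-check in the tests.
* **Factorisation at the last converged state.** The consistent tangent of
  a stable equilibrium is positive definite in practice, while the tangent
  evaluated right after a boundary-condition bump often is not. Each
  increment therefore factorises (sparse supernodal Cholesky) *before*
  applying the bump and reuses the factor quasi-Newton style, refreshing
  only when the residual stalls; a remembered diagonal-shift ladder covers
  genuinely indefinite refreshes, and a backtracking line search guards
  every step. This keeps wall time and memory bounded: a ~2,000-node
  retraction solve completes in tens of seconds on one CPU core (the
  acceptance script reports the measured time as `solve_time_s`), and the
  2.5 mm reference solve in a few minutes.
* **Convergence control.** Residual tolerance is $10^{-6}$ relative to the
  increment's initial residual (absolute floor $10^{-10}$), at most 60
  iterations per increment.

## Image update

The solved field is evaluated at every voxel centre (each voxel on its own
side of the crack) to produce a dense displacement field, and the predicted
post-retraction image is formed by backward warping: for each output voxel
$y$ the preimage $x$ with $x + u(x) = y$ is found by five fixed-point
iterations on the forward field, and the source image is sampled at $x$ with
trilinear weights restricted to voxels on the same side of the crack as $x$.
Output voxels whose preimage is inconsistent (forward-mapping mismatch above
1 mm) lie in the opened gap and receive a configurable background intensity
(default: the image minimum). These gap/masking rules are our own design;
the back-interpolation literature does not pin them down.

## The synthetic phantom

No imaging data ship with the package, so a deterministic phantom generator
produces every input: an ellipsoidal brain-like mask (default semi-axes
40/32/28 mm — porcine scale — at 1.5 mm voxels), a planar through-going
crack placed slightly off the mesh lattice, two retractor-blade point clouds
(14 mm wide, inserted 20 mm, with a 1 mm parabolic bow and 0.4 mm in-plane
sample jitter, since scanned surfaces are neither flat nor lattice-sampled),
post clouds displaced by the V-shaped opening (defaults 5.4 mm and 2.8 mm on
the two faces, tapering linearly to zero at the blade tip — the magnitudes
of a representative retraction), and 11–20 bead landmarks (default 14)
placed in three lobe-like clusters on both sides of the crack, in the region
where retraction-induced motion is appreciable. All randomness flows from
one seed; the same seed reproduces the phantom bitwise.

With 5 mm meshing the default phantom yields ≈2,100 nodes / 1,600
elements — the scale of the porcine retraction meshes the evaluation
metrics were originally reported for.

What the phantom does *not* emulate: real CT noise and partial-volume
effects, heterogeneous tissue (ventricles, falx, CSF), contact between the
crack faces, and tracking errors beyond isotropic jitter. Tests passing on
the phantom therefore demonstrate the correctness and internal consistency
of the mechanics, tracking and warping chain — not clinical accuracy.

## Evaluation metrics and the self-consistency experiment

For landmarks with pre-retraction, model-predicted and measured
post-retraction coordinates, the package computes the forecast error
(Euclidean distance between predicted and measured positions), the
prediction accuracy $100\,(1 - \mathrm{FE}/\|\mathrm{measured} -
\mathrm{pre}\|)$ (an alternative denominator, the predicted displacement, is
available behind the `denominator` switch because the published per-landmark
tables are consistent with either form only to within their own rounding),
the Dice overlap of segmentation masks, and target registration errors
before and after the model update. Summaries use the sample
(n−1) standard deviation, configurable, and round half-up to one
decimal only at report time.

Because no post-retraction images ship with the package, end-to-end
behaviour is scored by a *self-consistency* experiment: the same tracked
boundary conditions are solved on the default 5 mm mesh and on a 2.5 mm
reference mesh; beads advected by the reference field play the role of
measured landmarks for the coarse prediction, and the two warped masks are
compared by Dice. With default settings this yields mean accuracy ≈84 %,
mean forecast error ≈0.1 mm and Dice ≈99 %; the published per-subject floors
(71.5 % accuracy, 82.8 % Dice) serve as plausibility bands, not as ground
truth. Pointwise coarse-vs-fine displacement differences at probe points are
2–27 % of the local displacement (largest where the field is small), i.e.
refinement consistency holds at the ~10 %-of-peak level — the expected
behaviour of trilinear elements with sub-cell crack quadrature, not a 1–2 %
pointwise match.

## Known limitations

* Planar cracks only (plane plus optional straight front); curved
  retraction paths would need a triangulated crack surface and per-element
  level-set interpolation.
* No crack-face contact: the model happily interpenetrates faces if the
  prescribed displacements close the gap.
* Uniform (ungraded) octree meshing; no mesh-quality optimisation.
* The default crack is through-going, so tip enrichment — implemented and
  unit-tested — is exercised by the test suite rather than by the default
  pipeline.
* Axis-aligned image grids only.
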