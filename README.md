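# retractsim

Hyper-viscoelastic XFEM simulation of surgical brain retraction.

Inserting retractor blades to reach a deep surgical target displaces brain
tissue by several millimetres and splits it along the retraction path — a
genuine discontinuity that makes preoperative images, and the navigation
systems built on them, unreliable exactly where precision matters.
`retractsim` is for researchers in image-guided neurosurgery and
computational biomechanics who want to simulate that process end to end:
from a segmented brain volume and tracked retractor-surface point clouds to
a predicted post-retraction image, with the standard registration-accuracy
metrics.

## The model

Brain parenchyma is modelled as an Ogden hyper-viscoelastic solid. The
isochoric strain energy in the principal stretches,

    W = (2 mu0 / alpha^2) (lbar1^alpha + lbar2^alpha + lbar3^alpha - 3),

relaxes in time with a Prony series,

    mu(t) = mu0 (1 - sum_k g_k (1 - exp(-t / tau_k))),

with porcine-brain defaults mu0 = 842 Pa, alpha = -4.7,
(tau1, g1) = (0.5 s, 0.450), (tau2, g2) = (50 s, 0.365), plus a quadratic
volumetric penalty for near-incompressibility (Poisson ratio 0.49). The
tissue discontinuity is handled by the extended finite element method
(XFEM) on an octree hexahedral mesh: a two-level-set crack representation
(phi, psi) and Heaviside / crack-tip nodal enrichment,

    u(x) = sum_I N_i u_i + sum_J N_j (H(x) - H_j) a_j
         + sum_M N_m sum_l (F_l(x) - F_l(x_m)) b_m^l,

so the mesh never needs to conform to the retraction path. Boundary
conditions come from coherent-point-drift registration of pre/post
retractor-surface clouds (zero displacement at the brain stem anchors the
organ); the solved field drives a crack-aware backward warp of the
pre-retraction image. Accuracy is quantified by forecast error, prediction
accuracy, Dice overlap and target registration error.

## Worked example

The package ships a deterministic phantom (ellipsoidal brain-like mask,
planar crack, V-shaped retractor opening of 5.4 / 2.8 mm, 14 bead
landmarks) that stands in for CT/LRS data:

```r
library(retractsim)

ph   <- generate_phantom(phantom_config(seed = 1))
mesh <- build_octree_hex_mesh(ph$mask, max_edge = 5)
enr  <- classify_and_enrich(mesh, ph$crack)
enr
#> <hex_mesh> 2136 nodes, 1613 hexahedral elements, edge 4.969x4.846x4.625 mm
#>   crack: planar | elements: 1478 standard, 135 cut, 0 tip
#>   enriched nodes: |J| = 322 (Heaviside), |M| = 0 (tip); 7374 DOFs

bcs   <- phantom_bcs(ph, enr)           # CPD tracking -> crack-face BCs
field <- solve_retraction(integration_data(enr, ogden_material()), bcs)
field
#> <displacement_field> 7374 DOFs, 10 increments over 30 s; max |u| at nodes = 5.171 mm; ...

predicted <- warp_image_backward(ph$intensity, field)
```

The mesh lands at the scale reported for porcine retraction experiments
(roughly 2,000–4,600 nodes), the maximum displacement (5.17 mm) sits on the
crack-face nodes next to the retractor, and `predicted` is the
pre-retraction image resampled through the discontinuous deformation —
tissue on either side moves apart and the opened gap takes the background
intensity.

Scoring the coarse prediction against a 2.5 mm reference solve of the same
boundary conditions:

```r
cfg <- list(evaluate = list(fine_ground_truth = TRUE))
res <- run_pipeline(cfg)
res$metrics
#> <metrics_report>
#>   forecast error: 0.1 +/- 0.1 mm (max 0.4)
#>   prediction accuracy: 84.2 +/- 14.5 % (min 50.0)
#>   TRE initial 0.8 mm -> model-updated 0.1 mm
#>   DSC 99.4 %
```

A thin command-line wrapper with subcommands
(`phantom | mesh | bcs | solve | warp | evaluate | run`) is installed at
`inst/cli/retractsim`.

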