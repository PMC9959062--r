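---
title: "Holistic 3D assessment of the temporomandibular joint: methods and design"
author: "tmjmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holistic 3D assessment of the temporomandibular joint: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmjmorph)
```

## The problem

After orthognathic (jaw) surgery the temporomandibular joint adapts through
three processes that together determine the final position of the mandible:
remodeling of the condylar head, remodeling of the glenoid fossa of the
temporal bone, and displacement of the condyle within the fossa (a change of
the osseous joint space). Quantifying all three from a pair of pre- and
post-operative CBCT scans requires two different rigid alignment frames,
anatomically meaningful sub-regions, and measurements whose inter-observer
reliability can be demonstrated. `tmjmorph` implements that workflow
end-to-end on triangle meshes (mm units throughout) and voxel volumes, plus a
synthetic phantom generator that provides analytic ground truth for every
stage.

## The dual-frame design

A single registration cannot serve all three measurements:

* **Ramus frame (SBR).** Condylar remodeling must be measured relative to the
  mandibular ramus, because the mandible itself moves at surgery. The post
  ramus is aligned to the pre ramus by trimmed point-to-plane iterative
  closest point (ICP) registration: a coarse whole-ramus pass, then a
  refinement restricted to the stable reference region below the C-plane so
  that the remodeling condyle cannot bias the alignment.
* **Cranial frame (VBR).** Fossa remodeling and joint-space change must be
  measured relative to the skull. The post volume is aligned to the pre
  volume by masked rigid intensity registration over the stable cranial
  structures (anterior cranial base, forehead); the mask is an input, as in
  the clinical protocol.

Every mesh carries a frame tag (`"ramus"` or `"cranial"`), and every distance
or joint-space computation refuses mixed frames. This makes the most likely
category of pipeline error — comparing structures aligned in different frames
— impossible by construction rather than merely discouraged.

## Anatomy from landmarks, never from world axes

All directions are derived from a landmark set: the Frankfurt horizontal
plane through both porions and orbitale; the C-plane parallel to it through
the C-point (deepest point of the mandibular notch), which isolates the
condyle from the ramus; a pole plane through the lateral and medial condylar
poles perpendicular to Frankfurt (its positive side fixed by an anterior
reference landmark); and an orthogonal mid-plane through the pole midpoint
(positive side toward the lateral pole). The two latter planes partition both
the condylar head and the fossa patch into four named sub-regions —
anterior-lateral, anterior-medial, posterior-lateral, posterior-medial — with
identical sign conventions, so regions correspond across structures and
across left/right joints without any dependence on the scanner frame.

Vertices lying exactly on a cutting plane (within 1e-9 mm) are assigned to
the anterior / lateral side. The rule is arbitrary but deterministic; a
data-dependent tie-break would make labelings differ between observers and
between runs.

Two conventions are genuinely open in the source protocol and are therefore
explicit package choices:

* **Head/neck divider.** The condylar head and neck are reported separately,
  but no published plane separates them. The default divider is parallel to
  Frankfurt, midway between the C-point and the superior-most condylar
  vertex. It is deterministic and monotone under landmark jitter, and can be
  overridden with an explicit plane.
* **Orbitale laterality.** The Frankfurt plane takes a single `orbitale`
  point; users who prefer the average of left and right orbitale simply pass
  the average.

## Measurements

* **Volumetric change (%)**: `100 (V_post - V_pre) / V_pre` from
  divergence-theorem volumes of capped, closed clips (condyle, head, neck and
  the four head quadrants). Open meshes are a hard error, not a best-effort
  estimate — volume is a headline metric and silent repair would hide
  segmentation faults.
* **Surface distance maps (mm)**: for each vertex of the pre (reference)
  structure, the exact nearest-point distance to the post surface, signed by
  the outward reference normal: positive = apposition, negative = resorption.
  Headline tables report the mean *absolute* distance (sign cancellation
  would understate remodeling); the signed mean is reported alongside, and
  the fossa uses the RMS distance.
* **Joint space (mm)**: minimum condyle-to-fossa distance per sub-region, in
  the cranial frame; change = post − pre (positive = widening). The fossa
  target is region-restricted by default (`pairing = "region"`), which keeps
  the regional attribution meaningful; `pairing = "whole"` is available since
  the clinical definition does not state the restriction.

## Reliability statistics

Inter-observer agreement uses the one-way random-effects single-measure
intraclass correlation,

ICC(1,1) = (MSB − MSW) / (MSB + (k − 1) MSW),

with the exact F-quantile 95% confidence interval on (n − 1) and n(k − 1)
degrees of freedom. Negative estimates are reported as computed. "MAD (SD)"
is the mean absolute inter-observer difference with the sample SD of the
absolute differences (configurable to the SD of signed differences).
Bland-Altman bias and 1.96·SD limits of agreement complete the picture, and
ICC values are interpreted on the Cicchetti bands (poor < 0.40 ≤ fair < 0.60
≤ good < 0.75 ≤ excellent), with "reliable" meaning good or excellent
(ICC > 0.60). The study-design sample size comes from the Fisher-z one-sample
correlation formula, `n = ceil(((z_{1-α/2} + z_power) / atanh(ρ_a))² + 3)`;
at ρ_a = 0.6, α = 0.05, power 0.8 it gives n = 20 joints — this formula is
pinned because it is the one consistent with that printed requirement.

```{r sample-size}
sample_size_one_correlation(rho_alt = 0.6, alpha = 0.05, power = 0.8)
```

## The phantom generator

`make_tmj_phantom()` builds an idealized joint: a **spherical** condylar head
on a tapered, elliptic ramus shaft; a cranial plate carrying a concentric
spherical fossa socket at a known gap; and a separate forehead block that
gives the cranial volume three-dimensional structure for voxel registration.
The sphere is a deliberate simplification (the field's phantoms often use
superellipsoids): with a spherical head, cap volumes, the concentric joint
gap, and the effect of a vertical condylar displacement are all analytic, so
every acceptance check compares against a closed form rather than another
numerical method. The elliptic shaft cross-section matters: a surface of
revolution would leave axial rotation unobservable to ICP.

Remodeling is imposed as Gaussian indentations (depth d, width σ) along the
local surface normal at region-specific sites; the generator records the
carved volume as the surface integral Σ depth·dA on the pre mesh, an
independent first-order oracle for the volume difference measured later by
the divergence theorem. Rigid scan-pose perturbations and a condylar
displacement within the fossa complete the ground truth. Pseudo-CT volumes
rasterize the cranial meshes (bone 1200, soft-tissue background 80, Gaussian
smoothing, seeded additive noise).

What the phantom does *not* emulate: real condylar shape variation, CBCT
physics (beam hardening, scatter, metal artifacts), segmentation errors
beyond global thresholding, and the thin, sometimes discontinuous fossa roof
of real scans. Passing phantom tests therefore demonstrates the correctness
of the geometry, registration and statistics — not clinical robustness to
image quality.

```{r phantom, eval = FALSE}
spec <- tmj_phantom_spec(
  sites = list(list(structure = "head", region = "anterior-lateral",
                    depth = 0.5, sigma = 2)),
  skull_rotation_deg = 2, skull_translation = c(1.5, -1, 2),
  condylar_displacement = c(0, 0, 0.4))
ph <- make_tmj_phantom(spec)
a <- assess_tmj(ph$pre$ramus, ph$post$ramus, ph$pre$skull, ph$post$skull,
                ph$pre$landmarks, ph$pre$curve, ph$pre$seed_point,
                pre_volume = ph$volumes$pre, post_volume = ph$volumes$post,
                mask = ph$volumes$mask)
subset(a$report, metric == "joint_space_change_mm" & region == "whole")
```

## Numerical choices

* **Nearest-surface queries** use the exact point-to-triangle minimum over
  all faces, accelerated by a uniform grid with a conservative ring-expansion
  bound, so results are identical to the brute-force scan (this equivalence
  is property-tested on random queries).
* **Plane clipping** re-triangulates crossing faces with intersection points
  computed once per mesh edge (bit-identical across adjacent faces, so
  welding is exact), and caps each boundary loop by a centroid fan. For a
  planar loop the fan yields the exact enclosed volume even when the
  cross-section is non-convex. Sliver faces produced by near-tangent cuts are
  kept: removing them by an area threshold would open watertight solids.
* **Isosurfacing** uses marching tetrahedra (six tetrahedra per grid cube):
  a much smaller case table than full marching cubes, watertight by
  construction, with per-triangle orientation fixed against the
  above-threshold side. Volume recovery of a rasterized sphere at 0.3 mm
  spacing is within a few percent, which is the accuracy the segmentation
  stand-in needs.
* **ICP** defaults: point-to-plane correspondences, 10% trimming, 10 mm
  cutoff, tolerance 1e-5 mm on the RMS change, at most 200 iterations,
  deterministic stride subsampling to 3000 moving points. A step that would
  increase the trimmed RMS falls back to a point-to-point (Kabsch) step and,
  failing that, terminates — making the residual trace provably
  non-increasing.
* **VBR** optimizes six rigid parameters (degrees / mm, about the mask
  centroid) by Nelder-Mead over a 3-level mean-pooled pyramid, using every
  mask voxel (no stochastic sampling; the procedure is deterministic). The
  default similarity is masked normalized cross-correlation. Normalized
  mutual information is also implemented (with partial-volume linear binning
  and histogram size scaled to the pyramid level), but on pseudo-CT phantoms
  NCC recovered translations an order of magnitude more accurately and NMI's
  plateau-prone landscape repeatedly stalled the simplex optimizer, so NCC
  is the default and NMI an option for genuinely multi-modal inputs.
* **Curve attachment** snaps traced points to nearest mesh vertices and
  joins them by Dijkstra shortest paths along mesh edges — discrete rather
  than exact geodesics, which is deterministic and sufficient at the ~0.3 mm
  edge lengths of CBCT-resolution meshes; revisited vertices are pruned so
  the loop is simple.

## Problem sizes and what the tests show

The validation suite runs entirely on generated phantoms: ramus meshes of
~6000 vertices, cranial plates of ~8000, volumes at 0.6–1.2 mm spacing (the
finer 0.3 mm setting is exercised in the rasterization convergence test).
The end-to-end reliability study uses 20 joints with per-region remodeling
depths drawn from 0.15–1.0 mm, joint gaps 2.5–3.5 mm, vertical condylar
displacements −0.5–0.3 mm, and two simulated observers whose landmark and
curve points are jittered with σ = 0.3 mm — the manual steps of the
protocol; registration, which takes no manual input, is shared. These sizes
were chosen so the full suite completes comfortably on a laptop while
keeping every geometric tolerance meaningful; they are stated here so that
reported tolerances can be read against the resolution that produced them.

## Known limitations

* Segmentation is a global threshold plus largest-component filter — a
  stand-in for interactive clinical segmentation, adequate for phantoms only.
* Registration capture range is limited (centroid initialization for ICP,
  ±few degrees/mm for VBR at the default pyramid depth); grossly
  misoriented inputs need a manual pre-alignment.
* The head/neck divider and the joint-space pairing are package conventions
  (documented above), not clinically standardized definitions.
* Only rigid alignment is supported; deformable registration and soft-tissue
  (disc) assessment are out of scope.
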