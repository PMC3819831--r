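---
title: "Multigrid B-spline revision of deformable registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigrid B-spline revision of deformable registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrefine)
```

## The problem and the model

Automatic deformable registration leaves local errors; this package
implements the interactive stage that repairs them. The inputs are a
reference image and an image that has already been coarsely registered to
it ("transformed image"); the output is a revised transformed image plus
the revision deformation that produced it. The package never composes its
revision with the upstream method's transform — it operates on the
resampled image, exactly as an operator at a workstation would.

The revision transform is a hierarchy of uniform cubic B-spline lattices.
One level stores a displacement vector (in voxels) at every control
point; the blended displacement at image coordinate $x$ is the
tensor-product sum of the 16 (2-D) or 64 (3-D) neighboring control
displacements weighted by the cubic basis $B_0..B_3$ evaluated at the
intra-cell fraction. Three properties carry all the guarantees the
package tests:

* **Partition of unity** — the four basis weights sum to one, so a
  uniform lattice translates the image exactly and displacement bounds on
  control points transfer to the dense field.
* **Nonnegativity** — together with the above, the dense field is a
  convex combination of control displacements.
* **Local support** — a control point influences only its 4-cell
  neighborhood, which is what makes *local* manual revision meaningful
  and what lets the SSD probe restrict itself to a support region.

Refinement appends a finer lattice with the spacing exactly halved and
all displacements zero, so refinement alone never changes the current
field; the per-level fields sum to the total. Coarse levels stay
editable after refinement but the package warns, since the intended
workflow is to fix large errors on coarse grids and residuals on fine
ones.

## Conventions that had to be fixed

The formulation leaves several conventions open; the package fixes them
as follows and tests each one.

* **Displacements, not absolute coordinates.** Lattice values are
  displacement vectors added to the identity. An all-zero hierarchy is
  the identity transform; summing levels is then well defined.
* **Coordinates.** Image coordinates are 0-based and voxel-centered; an
  axis with $X$ voxels spans $[0, X)$. Lattice units are image
  coordinates divided by the level's spacing. Control point $(0,0)$ sits
  at image coordinate $(0,0)$; the printed index range $-1..N+1$ with
  $N = \lceil X/s \rceil$ gives a one-point margin so border evaluation
  never leaves storage.
* **$u = 1$.** The basis accepts the closed upper boundary
  ($B_3(1) = 1/6$); interior decomposition always yields fractions in
  $[0, 1)$, so the closed case only arises when a caller evaluates the
  basis directly.
* **Anisotropic spacing** is allowed per axis (clinical voxels are
  anisotropic); uniform spacing is the special case. Displacements are
  stored in voxels; `field_voxels_to_mm()` converts using the voxel
  spacing.
* **Backward warping.** Output voxel $x$ pulls its intensity from the
  input at $x + T(x)$ — no holes, one interpolation. The consequence is
  that *adding* $+d$ at a control point moves image *content* by roughly
  $-d$. Drag events therefore record the desired content motion and the
  engine stores the negated vector, keeping "drag content right, content
  moves right" true; a dedicated test pins this down with an
  integer-shift oracle.
* **Overlap mask.** Samples outside the input grid get fill value 0 and
  an explicit invalid flag. The SSD divides by the number of summed
  voxels, and the summed set defaults to the warp validity mask — the
  machine form of "all voxels within the overlap" — optionally
  intersected with a region of interest. For ROI-restricted use, $n$ is
  the number of masked voxels.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `spacing` | caller-supplied; `simulate` uses 16 | voxels | level-1 control spacing; halved per refine. A sensible starting point for fresh data is a quarter of the short image extent. |
| `interpolation` | `"linear"` | — | resampler for warps and probes. Linear is exact at integer offsets and range-preserving; Keys cubic (a = −1/2) is sharper but can overshoot; nearest is for label masks. |
| `threshold` | 10 | display units (0–255) | misregistration display mask: joint min–max rescale of both images, then \|difference\| > threshold. |
| `probe_step` | 1 | voxels | SSD probe magnitude in `suggest_direction()`. |
| `sweeps`, `initial_step` | 3, 2 | —, voxels | greedy reviser: passes over the lattice and first-sweep step, halved per sweep. |
| `max_magnitude` | 4 (`make_case`) | voxels | ground-truth control displacement bound; must stay below `spacing`/2 to avoid folding. |

The stopping rule is deliberately left to the caller: the interactive
procedure it models stops on visual satisfaction, and the quantitative
stand-ins exposed here are the SSD trace and the misregistration-mask
area.

## The synthetic module

Clinical pairs are replaced by phantoms with known ground truth. A
phantom is a smooth oblique ramp (intensities 20–80) carrying `n_blobs`
ellipsoids with distinct intensities (140–255) and ideal sharp
boundaries — the distinctive edges visual revision relies on. The truth
deformation draws control displacements uniformly in
$[-m, +m]$ per axis, with every control point within one cell of the
boundary pinned to zero so the border stays put (to within the $10^{-4}$
tail of an interior basis function) and the overlap stays essentially
full; for a two-level truth each level draws from $[-m/2, +m/2]$ so the
summed field keeps the bound. All generators take explicit seeds,
restore the caller's RNG state, and regenerate bit-identically.

What the phantoms deliberately do **not** emulate: anatomy, intensity
inhomogeneity between the pair, partial-volume texture, occlusion or
differing fields of view. Passing tests therefore demonstrate the
*mechanics* — field algebra, locality, replay determinism, SSD-guided
recovery — not clinical accuracy.

## Numerical behavior of the recovery experiment

The standard study (`scripts/acceptance.R`) builds a 128×128 case with
spacing 16 and magnitude 4, replays the session built from the truth
lattice (content motions equal to the stored truth displacements, so the
revision lattice holds their negation), and runs the greedy reviser.
Two numerical effects dominate the residual, and both are worth knowing
about before reading the numbers:

* **The negated lattice is not the exact inverse.** Backward-warping the
  transformed image with $-\phi$ composes to
  $\mathrm{ref}(x - \phi(x) + \phi(x - \phi(x)))$; the leftover is second
  order ($\sim \nabla\phi \cdot \phi$). Integer-displacement cases, where
  no interpolation happens, recover to machine zero — the test suite
  checks this — and the exact numerical inverse changes the residual SSD
  only a little.
* **Double resampling at ideal step edges.** The transformed image is
  interpolated once when the case is built and once per replay event; at
  a hard intensity step each pass widens the transition, while the
  reference keeps its ideal edge. This blur, not misalignment, is the
  bulk of the recovered-case SSD: it is why the recovered SSD settles
  near 13–15% of baseline rather than a few percent, and why the
  *low-threshold* misregistration area can grow after a successful
  revision (faint halos along every edge) even as strong misregistration
  — differences near the full edge contrast — collapses by an order of
  magnitude. The greedy reviser, which optimizes SSD directly rather
  than replaying the truth, reaches an SSD reduction of about 80% under
  the same conditions.

Problem sizes throughout the test suite (96²–128² images, lattices up to
a few hundred control points, 3-D spot checks at $\le 16^3$) were chosen
so the whole suite exercises every code path in seconds while staying
large enough for the asymptotic properties (partition of unity, locality,
additivity) to be meaningful.

## Other numerical choices

* Dense rendering is separable — per-axis basis-weight matrices
  contracted against the control grid — and is tested to agree with
  naive per-point evaluation to $10^{-12}$ and with a brute-force
  all-control-points oracle to $10^{-10}$.
* Linear interpolation clamps the cell anchor so integer coordinates
  (including the last voxel) reproduce stored values exactly; a zero
  deformation returns the input bit-identically.
* Joint min–max rescaling to $[0, 255]$ underlies both the overlay and
  the display threshold, so "gray" genuinely means equal raw intensity;
  a degenerate (constant, equal) pair maps to 0.
* Session JSON is written with 17 significant digits so a written
  session replays bit-identically to the in-memory one.
* Ties in `suggest_direction()` (neither probe strictly improves) return
  0 — no move — so supervision can never push SSD uphill at probe
  resolution.

## Known limitations

* No smoothness penalty: SSD is the only metric, so an aggressive manual
  session can produce an accurate but rough field. This mirrors the
  interactive setting it models; a regularized metric is out of scope.
* Monomodality only: SSD presumes comparable intensities. Multimodal
  metrics (NMI) are not implemented.
* Equal shapes required: pre-pad images upstream if fields of view
  differ.
* 2-D and 3-D only; color inputs rejected; forward/splatting warps and
  diffeomorphism guarantees are out of scope.
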