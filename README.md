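# regrefine

Interactive multigrid refinement of deformable image registration, as an R
package.

Automatic deformable registration (free-form deformation, Demons,
feature-based matching) is a core step in adaptive radiotherapy — contour
propagation and dose accumulation both ride on the deformation field — but
no automatic method gets every region right. `regrefine` implements the
*manual second stage*: starting from a reference image and an
already-transformed image, a clinician (or a script standing in for one)
revises the residual misregistration by dragging control points of a
hierarchy of cubic B-spline lattices, watching a fused RGB overlay and the
SSD metric.

## The model

The revision transform is a multilevel free-form deformation. On level
`i` a uniform lattice of control-point displacement vectors
Φ<sub>i,j(,k)</sub> (lattice indices −1 … N+1 per axis, spacing `s`
voxels) defines a displacement at image coordinate `(x, y)`:

    T(x, y) = Σ_{l=0..3} Σ_{m=0..3} B_l(u) B_m(v) Φ_{i+l, j+m}

with `i = ⌊x/s⌋ − 1`, `u = x/s − ⌊x/s⌋`, and the uniform cubic B-spline
basis

    B0(u) = (1−u)³/6
    B1(u) = (3u³ − 6u² + 4)/6
    B2(u) = (−3u³ + 3u² + 3u + 1)/6
    B3(u) = u³/6

The basis is a nonnegative partition of unity, so each control point
influences only its local 4×4-cell neighborhood. Refinement appends a new
zero lattice with the spacing halved; the per-level transforms sum:

    T_local = Σ_{i=1..L} T_local^i

Warping is backward (pull-back) resampling; supervision is the mean
squared intensity difference over the overlap of both images,

    SSD = (1/n) Σ (I_ref − T(I_trans))²,

and the visualization is an RGB fusion: reference in the green band,
transformed image in red and blue, so aligned structures appear gray and
misaligned ones green or purple. The mouse-driven GUI is replaced by a
replayable JSON *session* of drag/refine events, an SSD-probe helper that
suggests the drag direction, and a greedy auto-reviser for scripted use.

## Worked example

Build a synthetic case with a known deformation, replay the session that
undoes it, and watch the SSD trace:

```r
library(regrefine)

cs <- make_case(c(128, 128), spacing = 16, max_magnitude = 4, seed = 1)
cs
#> <synthetic_case> seed 1 | domain 128 x 128 | baseline SSD 398.355

sess <- session_from_truth(cs)
sess
#> <revision_session> spacing (16, 16) | 25 events (25 drag, 0 refine)

res <- replay(cs$reference, cs$transformed, sess, roi = cs$valid)
res
#> <replay_result> 25 events | SSD 366.608 -> 53.3551
```

The trace starts at the pre-revision SSD over the overlap (366.6 squared
intensity units) and drops event by event to 53.4 — each drag moves one
control point, the image is always re-warped from the original input, and
the SSD after each event is recorded. `rgb_overlay(cs$reference,
res$image)` fuses the pair for display; `write_image()` exports images,
overlays and dense displacement fields (PNG/TIFF/NIfTI/MetaImage).

The same operations are scriptable from a shell via the installed
`exec/regrefine` command (`simulate`, `overlay`, `ssd`, `warp`, `refine`,
`replay`, `field`).

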