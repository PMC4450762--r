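# phasesnake

Active contour (snake) segmentation and tracking of a **single cell in
phase-contrast microscopy image sequences**, for quantifying cell
morphology and motility over time. The target user has a video of one
lymphocyte-like cell — dark body, bright phase halo, uneven interior,
stretches of nearly invisible boundary — draws one rectangular ROI around
it, and wants an accurate closed boundary in every frame plus per-frame
area/perimeter/centroid tables.

## Method

The boundary is a closed parametric snake evolved by the explicit scheme

    x_i <- x_i + γ ( α Δ²x_i − β Δ⁴x_i + u(x_i, y_i) )

with elasticity α, rigidity β, and an external force field **V** = (u, v)
obtained by **vector field convolution**: the feature map convolved with
the radially attracting kernel k(x, y) = (x² + y² + ε)^(−r) · n(x, y),
where n points to the kernel origin.

The feature map is not a gradient edge map. The ROI first undergoes
**morphological gray-scale reconstruction** (border-seeded hole filling),
which erases interior intensity "holes" and flattens the cell body into an
exact plateau; a **Laplacian-of-Gaussian** filter (σ = 2, 13×13) applied
to the filled image yields **zero crossings** that are amplitude-gated and
cleaned by **small-component removal**. The resulting binary map is
sparse — force vectors appear only at significant edges — which makes the
snake both accurate at low-contrast boundaries and fast. The same plateau
drives initialization: its histogram mode, a narrow threshold band, disk
opening/closing and boundary tracing start the contour next to the phase
halo. Tracking is segmentation propagated frame to frame, the previous
final contour seeding the next frame. A classical GVF (gradient vector
flow) snake is included as the comparison baseline, and a seeded synthetic
phase-contrast scene generator provides ground-truth benchmarks.

## Worked example

```r
library(phasesnake)

sc  <- make_cell_image(scene_spec(seed = 1))   # synthetic cell + ground truth
roi <- scene_roi(sc$scene)                     # canonical tight ROI

res <- segment(sc$image, roi, preset_config("vfc_mgrl"))
res
#> segment_result: vfc_mgrl snake, 143 points, 100 iterations, not converged
#>   area 6401.7 px^2, perimeter 285.2 px, centroid (96.6, 96.4)
jaccard(res$mask, sc$mask)
#> [1] 0.986

seqq <- make_cell_sequence(sequence_spec(scene = scene_spec(seed = 1)))
tr   <- track(seqq$frames, seqq$roi, preset_config("vfc_mgrl"))
head(summarize_track(tr), 3)
#>   frame time_s area perimeter centroid_x centroid_y iterations converged reinitialized
#> 1     1     NA 6398     285.3      86.60      90.49        100     FALSE         FALSE
#> 2     2     NA 6379     285.0      87.35      90.94        100     FALSE         FALSE
#> 3     3     NA 6376     285.1      87.98      91.39        100     FALSE         FALSE
evaluate_run(tr, seqq$masks)$mean
#> [1] 0.9839
```

The Jaccard coefficient (JC = |A∩B| / |A∪B|) of 0.986 means the snake's
mask overlaps the generator's ground-truth mask almost completely; the
tracking table shows the cell drifting (centroid moving ~0.8 px/frame)
with stable area near 6 400 px², and a 30-frame mean JC of 0.984.
"Not converged" reports that the contour was still moving more than the
0.05 px tolerance at the fixed 100-iteration budget — the budget, not a
tolerance, ends each frame, mirroring the reference configuration.

A thin command-line wrapper ships in `inst/cli/phasesnake.R` with
`segment`, `track`, `simulate` and `evaluate` subcommands.

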