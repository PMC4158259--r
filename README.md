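# gastrograph

Noninvasive multitarget lesion tracking for gastroscopic image sequences.

During a gastroscopy an endoscopist marks suspicious lesions on screen with
virtual circles instead of tattooing them with ink or argon plasma
coagulation. The problem is then to *retarget* those circles in later
frames — or a later pass over the same anatomy — although the stomach wall
deforms and the endoscope moves freely. `gastrograph` implements a
graph-based solution for R users working on endoscopic image analysis:
registration between two arbitrary frames is solved as a shortest-path
search over a graph of pre-observed frames, composing local affine
transforms along the path.

## Method

**Image graph.** Every pre-observed frame is a node. Two frames *i*, *j*
are directly connected when their feature similarity

&nbsp;&nbsp;&nbsp;&nbsp;S<sub>ij</sub> = M<sub>p</sub> / max(Fp<sub>i</sub>, Fp<sub>j</sub>)

exceeds a connection threshold *h*, where Fp are keypoint counts from a
scale-restricted SIFT-style detector (detection scales σ ∈ [1, 3],
simplified 32-dimensional descriptors whose elements above 0.4 are clamped
to 1 to suppress illumination effects) and M<sub>p</sub> is the number of
mutual-nearest-neighbour descriptor matches. Each edge stores the affine
transform H<sub>ij</sub> estimated by RANSAC, with
H<sub>ji</sub> = H<sub>ij</sub><sup>−1</sup>.

**Threshold search.** *h* is found iteratively: sample pair similarities to
bracket [B<sub>low</sub>, B<sub>high</sub>], set
h = B<sub>high</sub> − λ(B<sub>high</sub> − B<sub>low</sub>) with λ = 0.1,
validate every pair above *h* by warping one frame onto the other and
scoring zero-normalized cross-correlation (Dif<sub>H</sub>); if any pair
scores Dif<sub>H</sub> ≤ 0.8 raise B<sub>low</sub> to *h* and repeat.

**Query matching.** A reference or moving frame is matched to its node by
registering it against a random node of a random anatomic subgraph
(angularis, antrum, body, ...). A subgraph is abandoned when
Dif<sub>H</sub> < 0.2; otherwise the walk follows the neighbour whose
stored edge transform is most consistent with the query's estimated pose.

**Pathway registration.** Edge weights are mean squared differences (SSD)
between candidate-node and moving-image warps in the reference frame;
Dijkstra's algorithm finds the minimum-weight pathway, and the deformation
is the ordered composition of the edge transforms along it
(H<sub>ij</sub> = H<sub>n_i n_1</sub> ∘ H<sub>n_1 n_2</sub> ∘ …).
Marked circles are mapped through the composed transform; centers falling
off-frame are reported as not visible.

**Evaluation.** A forward–backward framework tracks markers to the end of
a sequence and back; a trajectory is accepted when both directed
Kullback–Leibler divergences between the forward and backward position
distributions are below 0.1, and errors are converted to millimetres using
the 8 mm biopsy forceps visible in-frame as the scale standard.

Because no gastroscopic recordings ship with the package, a seeded
synthetic module (`make_sequence()`, `make_texture()`,
`make_phantom_markers()`) renders a ridged, vessel-like texture through a
chain of smooth affine motions with known ground-truth transforms and
landmarks; the whole test suite runs against it.

## Worked example

```r
library(gastrograph)

sq <- make_sequence(n_frames = 6, seed = 7)      # synthetic acquisition
g  <- build_graph(sq$frames, h = 0.3, seed = 1)  # image graph
g
#> <image_graph> 6 nodes, 15 edges, h = 0.3000, sites: site1
validate_connectivity(g)[c("n_components", "n_edges")]
#> $n_components
#> [1] 1
#> $n_edges
#> [1] 15

mk  <- make_phantom_markers(sq, n_markers = 4, radius = 6, seed = 2)
rec <- track_sequence(g, sq$frames[[1]], mk, sq$frames[-1],
                      stride = 1, seed = 3)
head(rec[, c("frame_id", "label", "x", "y", "radius", "visible")], 4)
#>   frame_id label     x      y radius visible
#> 1 frame001     1 211.6 171.80  5.957    TRUE
#> 2 frame001     2 179.8  78.73  5.957    TRUE
#> 3 frame001     3 131.6 176.68  5.957    TRUE
#> 4 frame001     4 191.2  74.37  5.957    TRUE
```

Each row is one marker retargeted onto one moving frame: `x`, `y` is the
predicted lesion center in that frame (pixels), `radius` the rescaled
circle and `visible` whether the center is still in-frame. Against the
generator's ground truth, the final frame's retargeting errors here are
0.06, 0.03, 0.03 and 0.03 px.

A command-line wrapper with `simulate`, `build-graph`, `match`, `track`
and `evaluate` subcommands lives at `inst/cli/gastrograph.R`:

```sh
Rscript inst/cli/gastrograph.R simulate --out frames/ --seed 1
Rscript inst/cli/gastrograph.R build-graph --frames frames/ \
    --out graph.json --h 0.3 --seed 1
```

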