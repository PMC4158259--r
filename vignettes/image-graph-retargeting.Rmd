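---
title: "Image-graph registration for endoscopic lesion retargeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-graph registration for endoscopic lesion retargeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gastrograph)
```

## The model

`gastrograph` treats deformation registration between two gastroscopic
frames as a path problem. The central assumption is that *between very
similar frames the stomach wall's apparent motion is well approximated by a
single planar affine transform*: the endoscope's focal length is fixed, its
motion range is bounded by the gastric cavity, and over a short visual
distance the wall deforms smoothly. Registration between *dissimilar*
frames — where that assumption fails — is recovered by chaining affine
transforms along a pathway of mutually similar intermediate frames.

Concretely, pre-observed frames become nodes of an undirected graph. Two
frames are connected when their feature similarity
$S_{ij} = M_p / \max(Fp_i, Fp_j)$ exceeds a threshold $h$, where $Fp$
counts detected keypoints and $M_p$ counts descriptor matches. Each edge
stores the RANSAC-estimated affine transform $H_{ij}$, with
$H_{ji} = H_{ij}^{-1}$ and $S_{ij} = S_{ji}$; unconnected entries hold a
$(0, 0)$ sentinel. A query (the marked reference frame, or a later moving
frame) is matched to a node, a minimum-cost pathway between the two nodes
is found with Dijkstra's algorithm, and the composed transform maps the
marked circles into the moving frame.

### Transform conventions

All transforms are $3 \times 3$ matrices with last row $(0,0,1)$ acting on
column vectors $(x, y, 1)^T$; $x$ is the 0-based column, $y$ the 0-based
row, pixel-center convention. $H_{ij}$ maps points of frame $i$ into frame
$j$; the same matrix serves as the inverse map when warping image $j$ onto
frame $i$'s canvas. `affine_compose()` applies transforms *in the listed
order*, so a pathway $n_1, \dots, n_m$ composes as
`affine_compose(list(H_{n1 n2}, H_{n2 n3}, ...))`; because points are
column vectors the matrix product accumulates on the left. The tracking
deformation for a query additionally includes the two query-side
registrations: (reference $\to$ its node) $\circ$ (pathway) $\circ$ (node
$\to$ moving frame).

## The feature detector

The detector is a deliberately simplified SIFT variant:

* **Scale restriction.** Gaussian levels follow a geometric ladder
  $\sigma_k = 2^{k/3}$ (the input image is assumed to carry
  $\sigma = 0.5$ acquisition blur), and difference-of-Gaussian extrema are
  searched only at levels whose assigned $\sigma$ lies in $[1, 3]$. In the
  fixed-focal-length endoscopic setting the image scale barely changes, so
  scales outside this band contribute little but cost much. We read the
  restriction as a bound on absolute Gaussian scale; octave indices would
  give a different (coarser) meaning.
* **32-D descriptors.** A $2 \times 2$ spatial grid of 8-bin gradient
  orientation histograms over a rotated $8 \times 8$ sample grid
  (spacing $1.5\sigma$), Gaussian-weighted, L2-normalized, then
  *clamp-normalized*: every element above 0.4 is set to 1 with **no**
  re-normalization afterwards. The clamp suppresses — rather than
  removes — illumination effects, and the similarity statistic downstream
  consumes the clamped values as-is.
* **Noise stabilization.** Two implementation choices harden the detector
  against sensor noise without moving the scale band: DoG response maps
  are lightly smoothed ($\sigma = 0.8$) before extremum detection, which
  stabilizes both which extrema exist and their response ranking; and
  orientation/descriptor gradients are sampled from the level two ladder
  steps coarser than the detection level ($\sigma \times 2$), while all
  window sizes still scale with the detection $\sigma$. Both choices also
  improved matching on clean sequences.
* **Matching.** Mutual nearest neighbours in Euclidean descriptor space
  with Lowe's ratio test (0.8, strict inequality) applied on *both* sides.
  The two-sided test keeps the match set — and hence $S_{ij}$ — exactly
  symmetric, which the graph invariants require. The matching rule is a
  design choice: the method itself only consumes match counts and
  correspondences.

Color frames are converted with ITU-R BT.601 luma weights everywhere
(descriptors, NCC, SSD), so all photometric statistics see the same
grayscale image.

## Validation statistic

Pair validation and node matching use zero-normalized cross-correlation
(ZNCC) over the warp's valid-overlap pixels, reported as `dif_h`
$\in [-1, 1]$. The decision levels are: a connected pair is acceptable
when `dif_h` $> 0.8$; a query abandons a subgraph when `dif_h` $< 0.2$.
ZNCC is offset- and gain-invariant, which matches the interpretation of
"closeness to 1 means the affine assumption holds"; a raw product-moment
without mean subtraction would be neither bounded nor
illumination-invariant. Warps whose valid overlap is below
`min_overlap = 0.25` of the canvas are rejected outright: below that the
statistic is dominated by interpolation boundary effects.

SSD edge weights are *mean* squared differences over the intersection of
validity masks, not raw sums; pathway candidates with different overlap
areas would otherwise be incomparable.

## Threshold search

`find_threshold()` brackets the sampled similarity range
$[B_{low}, B_{high}]$ and iterates
$h = B_{high} - \lambda (B_{high} - B_{low})$ with $\lambda = 0.1$,
raising $B_{low}$ to $h$ while any pair above $h$ fails ZNCC validation.
Three notes:

* Only pairs satisfying the *current* $S_{ij} > h$ are re-validated each
  round; pairs already below threshold are excluded, since the exit
  condition quantifies over connected pairs.
* Pairs whose RANSAC fails (too few matches, degenerate geometry) count as
  failed validation, so the search raises $h$ past their similarity — the
  same convention the graph builder uses (failures are unconnected).
* The first candidate $h$ already sits at the 90th percentile of the
  similarity range. On desk-scale inputs (tens of frames) this yields a
  deliberately sparse graph; production-scale graphs (tens of thousands of
  frames) contain many near-duplicate pairs whose similarity crowds the
  top of the range, which is what keeps such graphs connected. This is a
  scale property of the algorithm, not a bug; the package's end-to-end
  examples therefore build desk-scale graphs at a fixed $h = 0.3$.

## Query matching and pathway search

Node matching starts at a seeded random node of a seeded random anatomic
subgraph (the top-level partition by `site_label`; no deeper hierarchy is
used). If the node scores `dif_h` below 0.2 the whole subgraph is
abandoned and the next subgraph is tried in deterministic round-robin
order. Otherwise the walk inspects neighbours in order of *pose
consistency* — the Frobenius distance between the query's estimated
transform into the current node and each neighbour's stored edge
transform — moving to the first neighbour that improves `dif_h`, and stops
when none improves, when `dif_h` reaches 0.8, or after `max_visits = 50`
registrations. Frobenius distance is the simplest metric consistent with
"most consistent movement"; its translation entries (pixels) dominate,
which is appropriate since translation dominates endoscope motion.

Edge weights for the pathway search are query-dependent, so they are
computed lazily and memoized per query. For edges leaving the reference's
node the weight is the SSD between the candidate node's image and the
moving image, both warped onto the reference canvas (the candidate through
the graph transforms, the moving image through the direct
reference-to-moving RANSAC estimate). For edges deeper in the graph no
direct transform to the reference exists; there the weight falls back to
the edge's own registration residual — the SSD between the neighbour
warped across the edge and the tail node's image — i.e. how well the
stored affine actually connects the pair. Dijkstra runs with deterministic
tie-breaks: total weight, then fewer hops, then the lexicographically
smaller node-id sequence.

Retargeted circle radii are scaled by $\sqrt{|\det|}$ of the transform's
linear block, keeping circles circles for display; anisotropy is
deliberately ignored. Markers whose mapped center leaves the frame are
flagged not visible and re-appear when a later deformation brings them
back.

## Evaluation framework

`forward_backward()` tracks seed points to the end of a sequence and back;
the distance between origin and return position is the FB error, and
points lost in either direction are excluded from statistics but counted.
Trajectory acceptance bins forward and backward marker positions into
8-px square cells, smooths both histograms additively
($\varepsilon = 10^{-6}$, then renormalizes) and accepts a marker only
when both directed KL divergences (natural log) are below 0.1. Pixel
distances convert to millimetres through the apparent diameter of the
8 mm biopsy forceps.

A known sensitivity: on *short* trajectories (a dozen positions) a single
sample falling on the far side of a cell boundary between the forward and
backward pass shifts $1/n$ of the histogram mass onto a cell whose
smoothed counterpart is $\approx \varepsilon$, contributing
$\tfrac{1}{n}\ln\!\big(\tfrac{1}{n\varepsilon}\big) \gg 0.1$ and rejecting
the marker even when the geometric FB error is far below a pixel. The
acceptance rate reported on desk-scale sequences therefore understates
geometric accuracy; the mean FB error in px/mm is the more informative
number at this scale.

## The synthetic generator

`make_texture()` renders multi-octave *ridged* value noise (folded
$|2u - 1|$ layers with per-octave amplitude decay 0.7): the ridges give
the line-like, high-gradient structure that vessels and mucosal folds
provide in real imagery, and which any gradient-based detector needs.
`make_sequence()` draws a smooth random walk in affine-parameter space
(defaults: per-step rotation $\le 0.05$ rad, translation $\le 4$ px, scale
$\in [0.99, 1.01]$ — gentle motion at 25 f/s), renders each frame by
warping an enlarged base texture so content remains available at the
borders, optionally adds seeded Gaussian noise with clipping, and stores
ground-truth transforms and landmark tracks. Default frames are
$240 \times 280$, half the clinical $480 \times 560$ resolution, keeping
the full test suite within desk-scale budgets while preserving aspect
ratio. Site labels are assigned in contiguous blocks to emulate anatomic
subgraphs.

What the generator does *not* emulate: specular highlights, fold
self-occlusion beyond out-of-frame clipping, non-affine (projective or
elastic) deformation within a frame pair, lighting drift, and motion blur.
Passing tests on these fixtures therefore demonstrate the algorithmic
contracts — graph construction, search, composition, evaluation — under
the method's own modeling assumptions, not clinical performance.

For noise-robustness runs, noise is added to the *query* side (reference
and moving frames) while the graph is built from clean pre-observed
frames. That mirrors the intended deployment: graph construction is an
offline step over curated acquisitions, while tracking must survive live
sensor noise. Building a desk-scale graph from frames with independent
per-frame noise instead collapses every pair similarity (half of each
200-keypoint budget lands on unrepeatable noise extrema on both sides of
every pair), leaving no usable connection threshold — at production scale
the redundancy of tens of thousands of frames absorbs this.

## Defaults and tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `lam` | 0.1 | — | threshold-search bracket shrink |
| `dif_accept` | 0.8 | ZNCC | pair validation / walk early-accept |
| `dif_reject` | 0.2 | ZNCC | subgraph rejection |
| `kl_threshold` | 0.1 | nats | trajectory acceptance |
| `max_features` | 200 | keypoints | detector budget per frame |
| `ratio` | 0.8 | — | two-sided descriptor ratio test |
| `ransac_tol` | 3 | px | inlier residual tolerance |
| RANSAC iterations | 2000 | samples | exhaustive when fewer triples exist |
| `min_overlap` | 0.25 | fraction | minimum valid warp overlap |
| `stride` | 3 | frames | tracking decimation (real-time rate) |

Every seeded operation takes an explicit `seed` and restores the caller's
RNG state; identical seeds give bitwise-identical results, including CLI
outputs (no timestamps are written).

## Numerical choices and degenerate inputs

* RANSAC enumerates all 3-point samples exhaustively when
  $\binom{n}{3} \le$ `max_iter`, otherwise draws seeded samples; the
  consensus is re-fit by least squares; near-collinear samples
  ($|\det| \le 10^{-6}$) are discarded and fully collinear inputs raise a
  typed degenerate-geometry error.
* Constant or sub-$16\times16$ images yield an empty feature set rather
  than an error; empty feature sets propagate as similarity 0 /
  unregisterable.
* Keypoints are ranked by absolute DoG response with ties broken by
  ascending $(y, x)$; extraction is bitwise deterministic.
* Transform inverses re-fix the last row to $(0,0,1)$; the algebra holds
  to $10^{-9}$ over well-conditioned transforms.
* Graph files persist similarities to 12 significant digits and
  transforms as row-major 9-float arrays (round-trip within $10^{-12}$);
  sub-threshold similarities are not persisted, matching the $(0,0)$
  sentinel semantics.

## Problem sizes used by the tests

The suite exercises: 12-frame $240\times280$ sequences for end-to-end
tracking (clean: $\ge 90\%$ of retargeted centers within 3 px of ground
truth; query noise $\sigma = 0.05$: within 5 px), 5-frame
$120\times140$ graphs for matching and serialization, 100 random
$\le 8$-node graphs against a brute-force path-enumeration oracle, 1000
random transforms for the algebra identities, and 200 seeded RANSAC
recovery trials (10 exact inliers, 5 outliers, tolerance 3 px, corner
error < 1 px). These sizes were chosen so the whole suite completes on a
single CPU in a few minutes while each property is still tested in the
regime it describes.

## Known limitations

* Pairs are affine-only by design; within-pair elastic deformation is out
  of scope (the graph's premise is that *similar* frames are affinely
  related).
* The threshold search's first candidate already sits near $B_{high}$;
  desk-scale graphs built at the searched $h$ are sparse (see above).
* The KL trajectory criterion is conservative on short trajectories.
* The graph is static: frames that cannot be grouped to any subgraph
  raise a no-match error rather than extending the graph; incremental
  graph updates are future work.
* Matching cost grows linearly in visited nodes; no approximate-NN index
  is built over node descriptors.
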