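---
title: "Tracking and classifying multi-mouse social behaviour in thermal video"
author: "thermotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and classifying multi-mouse social behaviour in thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Quantifying the social behaviour of group-housed mice requires two things
that are hard to do by eye and tedious to do by hand: following the
position, body axis and identity of every animal through a long recording,
and assigning each animal a behavioural class in every frame. `thermotrack`
implements an integrated pipeline for top-view thermal video of untagged
mice: the warm bodies contrast strongly with the cooler arena under any
lighting, which makes thermal imaging attractive for recordings in the
dark, but it removes the fur-colour and texture cues that visible-light
trackers rely on, so identity must be carried by geometry and by each
animal's temperature distribution.

The pipeline has five stages, each exposed as ordinary package functions:
blob detection, temporal-watershed segmentation, identity matching, pair
feature extraction, and Temporal Random Forest classification, plus a
synthetic-scenario generator that renders thermal videos with full ground
truth so that every stage can be exercised and measured without any real
recording.

## Blob detection

Foreground extraction is a single global temperature threshold. The
threshold is estimated once, at the start of a video, from the empirical
temperature distribution of a window of `init_window` consecutive frames
(default 90, about three seconds at 30 fps): candidate thresholds are
scanned in ascending order and the smallest candidate is kept for which
*every* frame in the window shows exactly `n_mice` 8-connected components
with a total foreground area between `n_mice * min_mouse_area` and
`n_mice * area_upper_factor * min_mouse_area` (defaults 120 px² and 4). If
no candidate works the window slides forward one frame and the scan
repeats; if the video ends first, initialisation fails with a named error.
Once found, the threshold is used unchanged for the rest of the video.

Two numerical choices matter here. First, the candidate grid is at most
512 values spaced evenly over the window's temperature *range*, not over
its quantiles: almost all pixels are background, so a rank-based grid puts
essentially no candidates in the sparsely populated band between the
hottest background pixel and the coolest body pixel — which is exactly
where every feasible threshold lives. Second, feasibility is tested
cheaply: the area condition is evaluated first against per-frame sorted
values, and connected components are only counted when the area passes.

Mouse tails are thin, hairless and cold; in thermal video they flicker in
and out of the foreground and would corrupt the body-shape moments. They
are removed by a morphological opening: a pixel stays foreground iff it
survives the opening with at least one 5-px linear structuring element at
0°, 45° or 90°. Because opening is monotone in set inclusion, foreground
area remains monotone in the threshold after this step. Connected
components are 8-connected; components below a quarter of
`min_mouse_area` are discarded as unfeasible structures (residual tail
stubs, reflections). If more blobs than mice remain, the mask is dilated
with a 3×3 element up to `max_dilations` (default 5) times; if that fails
the frame is flagged `reinit` and the system re-initialises on the
following frames, emitting the skipped frames with empty keypoints rather
than dropping them. Fewer blobs than mice means animals in contact; those
masks are passed on to the temporal watershed.

## Temporal watershed

When mice touch, one blob covers several bodies. The temporal watershed
splits it by propagating each animal's pose from the previous frame as a
*seed* for a marker-controlled watershed, and iterating an EM loop:

* **Initialisation** — each mouse's seed is three collinear points (nose,
  centroid, genitals) along its previous axis, with the seed span shrunk
  to the mean major-axis length over the last `history_window` frames
  (default 10) minus a `slack` constant (default 6 px). The slack is what
  buys robustness to inter-frame displacement and to the non-rigid length
  changes of a stretching or hunched mouse: a seed shorter than the body
  stays inside it even when the body has moved a few pixels. The
  background seed is the 3×3-eroded complement of the foreground.
* **E step** — a seeded watershed on the negated temperature relief (warm
  body interiors are the deepest basins) assigns every foreground pixel to
  a mouse. The flood is implemented as a Meyer-style priority queue in
  compiled code, with FIFO tie-breaking for determinism, and is restricted
  to the foreground: the background seed never claims foreground pixels,
  so the per-mouse shapes always form an exact partition of the foreground
  mask. Foreground components that no flood reached are assigned to the
  mouse with the nearest centroid. If all of a mouse's seed points fall
  outside the foreground (a large jump), the seed snaps to the nearest
  foreground pixel within twice the slack; failing that the mouse is
  flagged mistracked for the frame.
* **M step** — per shape, the centroid comes from first-order moments and
  the axis from the eigen-decomposition of the second-order central
  moment matrix (with the 1/12 px pixel-variance term for stability on
  tiny shapes); the major-axis length is `4 * sqrt(lambda_max)`, exact for
  a filled ellipse. Nose and genitals sit at the axis endpoints, oriented
  to minimise the summed distance to the previous frame's keypoints. An
  eigenvalue tie (circular posture) falls back to the previous axis, or
  +x with no history.

The loop stops when fewer than `convergence_tol` (default 1%) of the
foreground pixels change owner, or after `max_em_iters` (default 10)
iterations. When the animals are disjoint the blobs themselves are the
converged shapes and the EM is skipped.

For the watershed to be meaningful the relief needs a ridge where two
bodies meet. Real thermal mice provide one: fur insulates, so the body is
warmest along the spine and visibly cooler at the contour. The synthetic
renderer reproduces this with a radial profile (100% of the temperature
offset at the core falling to 70% at the contour); without it, two
touching flat-temperature ellipses give the flood fronts nothing to stop
at and the hotter animal's basin swallows its neighbour — an artefact of
over-simplified test data, not of the method.

The very first tracked frame requires all mice disjoint; poses are then
bootstrapped directly from the blob moments, with the nose provisionally
at the +x axis extreme. Orientation is subsequently policed by a movement
vote: each frame contributes the sign of the inner product between the
frame-to-frame movement vector and the body direction (nose minus
genitals); displacement below `min_move` (0.5 px — centroid jitter of a
stationary animal carries no directional information) contributes zero.
When the sum over the last `vote_window` frames (default 10) turns
negative, nose and genitals are swapped and the sign buffer is cleared.
Clearing is what guarantees at most one swap per inversion event: the
buffered signs were computed against the pre-correction orientation and
would otherwise immediately vote the swap back.

## Identity matching

Frame-to-frame identity is a greedy assignment on the 6-D Euclidean
distances between pose vectors (nose, genitals, centroid): repeatedly take
the globally smallest remaining cost, fix that identity–shape pair, and
delete its row and column, with row-major tie-breaking for determinism.
On tracking-like cost matrices this agrees with the optimal assignment
essentially always; it can differ when two animals are nearly equidistant
mid-occlusion, which is exactly when geometry alone is unreliable.

A shape sanity check watches for that situation. Every accepted shape's
first Hu moment (η20 + η02, a similarity-invariant scalar) is recorded;
a Student-t location-scale model is fitted to the record by maximum
likelihood (refit every 100 accepted frames, moment fallback if the
optimiser fails) once at least 100 shapes have accumulated. A mouse is
flagged when the two-sided tail probability of its current hu1 falls below
`alpha` (default 0.01); a *global* misdetection state is raised only when
two or more mice are flagged in the same frame — one odd posture is
normal, two simultaneously deformed shapes usually mean the watershed has
let one seed overflow its neighbour.

While the global state is active, identity comes from heat instead of
geometry: each mouse's *heat signature* is the pool of temperature samples
inside its segmented shape over the last `buffer_frames` frames (default
9 ≈ 0.3 s), and the current shapes are assigned to signatures by the same
greedy search on two-sample Kolmogorov–Smirnov statistics. The KS
statistic is used directly as a cost — it is distribution-free, bounded in
[0, 1], and needs no assumption about what a mouse's temperature
distribution looks like. Signatures are updated only from unflagged
frames, so a corrupted segmentation never pollutes the reference
distributions. When tracking is lost entirely (a `reinit`), identities are
re-attached after re-bootstrap by heat if signatures exist, else by
distance to the last accepted poses.

The t model is fitted jointly over all mice (one baseline shape
distribution) rather than per mouse; the animals are conspecifics of
similar size and a joint fit reaches the required history four times as
fast. `matchingConfig(joint_fit = FALSE)` switches to per-mouse fitting.

## Pair features

Social behaviour is decomposed into ordered (reference, target) pairs, so
the classifier scales to any group size: a mouse's feature vector against
one conspecific never changes when a third animal enters the arena. Each
pair at each frame yields 13 measurements:

* **Relative position (5)** — head2head, head2body, head2genitals,
  genitals2genitals between reference and target, plus body2body, the
  centroid distance from the reference to its *nearest* conspecific
  (deliberately not the pair target: it separates "alone" from "near
  someone" regardless of which pair is being scored).
* **Shape (2)** — hu1 and pixel area of the reference, a proxy for
  posture (stretched, hunched, rearing).
* **Movement (6)** — distances between the reference centroid at frame t
  and at t + δ for δ ∈ {−15, −5, −1, +1, +5, +15}, a multi-scale sample
  of speed and acceleration over past and future. Offsets beyond the
  track are clamped to the first/last valid frame, so every frame stays
  classifiable; offsets landing on excluded (flagged) frames step through
  the sequence of valid frames instead.

Distances are in pixels: the classifier is trained by example on the same
geometry it later classifies, so no physical calibration enters. All
13 features are invariant to rigid motions of the camera frame.

## Temporal Random Forest

A per-frame classifier on these features already works, but behaviour is
temporally coherent and single-frame decisions flicker. The Temporal
Random Forest encodes time in the *ensemble* instead of in the features:
for every offset δ in −w..w it grows N unpruned CART trees (information-
gain splits, bootstrap resampling, each tree restricted to a random
d-feature subspace) on the pairs ⟨features at frame t + δ, label at
frame t⟩. At prediction time all (2w+1)·N trees vote — the offset-δ trees
reading the feature vector δ frames away — and the label is the mode,
with ties broken by the behaviour priority table and then alphabetically.
Defaults are N = 5, w = 15, d = 4 (≈ √13), i.e. 155 votes per frame. The
windowed vote acts as a regulariser: an isolated noisy frame inside a
stable context is outvoted by 150 trees that never see it. The offset
ensembles are genuinely different classifiers (a tree trained at δ = −15
learns what a behaviour looks like 15 frames before it is labelled),
which is why the construction beats simply smoothing per-frame outputs.

Class imbalance is left alone by default: rare behaviours are rare in the
training pool and degrade accordingly, which is the honest behaviour of a
learning-by-example system; `forestConfig(balanced_bootstrap = TRUE)`
equalises class frequencies per bootstrap if desired. Subspaces are drawn
once per tree (`per_split = TRUE` redraws per split). Training and
prediction are deterministic given the configuration seed.

Each mouse finally gets one label per frame by collapsing its M−1
pairwise labels through a priority table (1 = highest): Above,
Nose2Genitals, Nose2Nose, Nose2Body, Following, StandTogether, WalkAlone,
StandAlone. Contact behaviours dominate locomotion and rest — a mouse
sniffing one cage-mate while far from another is sniffing, not standing
alone. The numeric order of the contact behaviours among themselves is a
documented package choice (anchored by the rule that pairwise contact
beats StandAlone) and is serialized with every result; it can be
overridden wholesale. Durations are reported per class in frames and
seconds, with unlabelled frames in a separate `unknown` bucket so that
per-mouse frame counts conserve the video length exactly.

## Evaluation tools

`frameAgreement` scores a predicted label track against a reference on a
frame-by-frame basis: full eight-class accuracy, accuracy after grouping
into social (Nose2Body, Nose2Nose, Nose2Genitals, Above, Following) vs
non-social (WalkAlone, StandAlone) meta-classes, and per-group precision.
StandTogether's social status is genuinely arguable; it defaults to
non-social for agreement metrics and can be sent to its own bucket for
aggregate summaries. `durationDifference` reports absolute per-class and
per-group duration differences in seconds and as a percentage of video
length. `contiguousKFold` splits frames into k consecutive blocks without
shuffling — with temporally autocorrelated data, shuffled folds would
leak test frames into training windows. `trackingAgreement` matches
tracked to ground-truth centroids per frame and reports identity
agreement and switch counts.

## The synthetic scenario generator

The generator is first-class, tested code, not a fixture: it renders what
an overhead thermal camera sees of a 40 × 40 cm arena at 4 px/cm
(160 × 160 px) and 30 fps. Mice are warm ellipses (half-axes 14 × 5 px ≈
a 7 × 2.5 cm adult) over a Gaussian background (mean 20, sd 0.5 units);
each mouse carries a temperature offset above background (defaults 5,
6.5, 8, … units — well above noise, 1.5 units apart so heat signatures
are discriminable), the warm-core/cool-rim radial profile described
above, and a 1-px curled tail whose base is warm and whose distal half is
near ambient. Tails curl (radius 6 px, 0.8 rad off-axis) because real
tails do — and because a perfectly straight rendered tail is an artefact
that happens to align with one of the tracker's three linear structuring
elements, defeating the opening for the wrong reason. The distal
temperature falls in a step rather than a gradient: a gradual fade
necessarily crosses any threshold somewhere along the tail, leaving a
flickering segment that fragments the connected components on every
frame.

Scenarios are scripted: motion primitives (stand, line, arc) per mouse
per segment, with the ground-truth behaviour label of every ordered pair
declared per segment; the geometry of the presets respects the behaviour
definitions at the package's pixel scale (noses < 2 px ≈ 0.5 cm for
sniffing, < 40 px ≈ 10 cm for Following/StandAlone, 12 px ≈ 3 cm for
StandTogether). Generation is a pure function of spec + seed — frames are
rendered lazily from per-frame derived seeds, so a 5,400-frame video
never materialises in memory and any frame can be re-rendered
bit-identically. Infeasible scripts (a body leaving the arena) are
rejected at build time.

What the generator deliberately does *not* emulate: limb and whisker
detail, non-elliptical postures (rearing, grooming curl), reflections and
bedding clutter, camera vignetting, or genuinely deformable contact (two
rendered bodies overlap by max-temperature compositing). Passing the
synthetic suite therefore demonstrates that the algorithms are correctly
implemented and behave as designed under controlled conditions — clean
separation, known contact episodes, scripted labels — not that the
end-to-end accuracy figures transfer to real recordings, where posture
variation and annotation noise dominate.

## Study problem sizes and verification

The package's test-suite and the acceptance script (`scripts/acceptance.R`)
measure the pipeline at these scales, chosen as the smallest sizes at
which each property is meaningfully exercised: threshold initialisation
on a 300-frame three-mouse video; watershed pose recovery on a 200-frame
side-by-side contact episode; 1,000 random assignment matrices against a
brute-force oracle; 50 forced-inversion orientation trials; 100 injected
identity-swap heat-recovery trials; crossing-path fixtures of 300 (M = 2)
and 400 (M = 3) frames under combined vs distance-only matching; 20
replicates of noisy 360-frame feature sequences for the w = 15 vs w = 0
regularisation comparison; and a full 5,400-frame (3-minute) four-class
end-to-end run — simulate, track, extract features, train on the first
two contiguous folds, classify the third — for parameter recovery.

## Known limitations

* The foreground threshold is global and fixed after initialisation;
  slow thermal drift of the arena over long sessions would require
  re-initialisation (the machinery exists but is only triggered by blob
  failures).
* The watershed relief is temperature only; two animals at identical
  temperature in prolonged full-body contact are separated purely by seed
  geometry, and a long enough occlusion can still swap identities — this
  is what the heat-signature channel exists for, and it in turn needs the
  animals' temperature distributions to differ detectably.
* Poses are 3 keypoints on an ellipse model; postures that break the
  ellipse (tight grooming curls, rearing against walls) inflate hu1 and
  are handled statistically (sanity flag) rather than geometrically.
* The classifier is learning-by-example: it reproduces its training
  labels' biases, and rare classes degrade without reweighting.
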