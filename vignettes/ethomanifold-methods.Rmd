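---
title: "Methods: behavior post-processing and neuronal-manifold analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior post-processing and neuronal-manifold analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethomanifold)
```

`ethomanifold` analyses miniscope calcium-imaging sessions of freely behaving
mice together with video-derived behavior. It covers the post-processing side
of such an experiment — everything downstream of pose-estimation networks and
calcium source extraction: composite-frame construction for behavior scoring,
arena zone segmentation, key-point evaluation, behavior label denoising,
kinematics, population-activity manifolds, their compactness and geometry,
and shuffle-controlled group classification. Because public recordings for
this assay are not available, the package ships a first-class synthetic
cohort generator so that every stage is testable end to end.

## Composite frames for behavior scoring

Behavior is a property of a frame *sequence*, not a single image. The
composite-frame encoding compresses 21 consecutive video frames into one RGB
image scored at the 11th frame: the green channel holds the mean of the 10
preceding frames' green channels, the red channel the centre frame's red
channel, and the blue channel the mean of the 10 following frames' blue
channels. Motion then shows up as colour fringing around the animal.
`build_composite()` computes the channel means in floating point and
quantizes the stored image to 8-bit depth by rounding half-up; the
un-quantized array is kept alongside so that numerical properties can be
verified exactly. `composite_stream()` slides this construction along a
video: composites exist only for centre frames 11 through T − 10 — edge
frames are skipped, never padded — and a `stride` parameter is exposed
because nothing forces training composites to be built at every frame.

## Arena segmentation and zones

The circular arena is segmented analytically from a single grayscale frame:
the image is binarized at mid-contrast, dark connected components are
labelled (`EBImage::bwlabel`), each component is fit by a least-squares
(Kasa) circle, the largest-radius fit is taken as the arena boundary, and
the remaining component whose centroid lies closest to the detected centre
(within a central region of interest) is the central-zone marker. The
annulus between the central radius and the boundary is divided into three
equal-width zones, giving four radii `(central, inner, middle, outer)`.
`classify_zone()` bins points by radial distance with half-open intervals
(lower edge inclusive of the *next* zone, boundary radius inclusive of
`outer`), so every point of the closed disc receives exactly one label.

## Key-point evaluation (PCK)

`pck()` scores predicted key points with the percentage-of-correct-keypoints
metric at a threshold of `d_factor` × the inter-ear distance `D`
(default `d_factor = 0.25`, i.e. PCK@0.25). `D` is taken per frame from
the ground-truth track rather than as a session constant — the stricter
reading, which degrades gracefully when the animal's apparent scale changes.
Correctness is inclusive (error ≤ radius, a closed disc). The metric is
invariant to joint rigid translation and equivariant under joint isotropic
scaling, and the test suite checks both.

## Behavior label denoising

Raw per-frame class probabilities from a behavior classifier are denoised in
two stages. First, `kalman_label_filter()` runs a discrete-state forward
filter: per frame the class distribution is propagated through a
row-stochastic "behavior matrix" `T` (predict `p' = Tᵀp`), multiplied
element-wise by the observed probabilities, and renormalized. The default
matrix has 0.9 self-transition and 0.05 off-diagonal mass; it is a
configuration knob, not an estimate. With uniform `T` the prediction step
is uninformative and the filter returns the observations; with identity `T`
it reduces to a renormalized cumulative product, in which case an
observation stream that contradicts an already-certain state has an exactly
zero posterior — the filter reports this as an error naming the frame rather
than guessing. Second, `mode_smooth()` stabilizes the label stream over
non-overlapping 25-frame blocks (about 1.7 s at 15 Hz), replacing each block
by its modal label; ties go to the label of the block's central frame. The
block (rather than sliding-window) form makes the operation idempotent.

## Kinematics

`compute_velocity()` differentiates a reference point (by default the ear
midpoint, which is always present and robust to tail/limb jitter) and
smooths the speed trace with a Savitzky–Golay filter
(`signal::sgolayfilt`; default window 15 frames = 1 s at 15 Hz, order 3,
floored at zero since speed is non-negative). `occupancy_and_ethogram()`
tallies seconds per arena zone, behavior fractions, and exports per-frame
tables and a binned position heatmap for plotting.

## Manifold construction

Calcium transients are sparse, so single frames are poor manifold points.
`flatten_windows()` instead concatenates the population vectors of 30
consecutive frames (2 s at 15 Hz) frame-major into one vector per window:
element `i·N + j` (0-based) is neuron `j` at window frame `i`. Windows are
non-overlapping, start at the first frame, and a trailing partial window is
dropped. One session of 4500 frames yields 150 points of dimension `30 N`.

`embed_windows()` reduces these to `dim` dimensions (default 2, matching
the 2-D manifold portraits the descriptors are defined on) with one of five
standard methods, all delegated to established implementations: Barnes–Hut
t-SNE (`Rtsne`, perplexity 30, clamped to `(n−1)/3` with a warning on small
sessions), PCA (`prcomp`), FastICA (`ica::icafast`), classical MDS
(`stats::cmdscale` — the Torgerson solution; a SMACOF stress optimizer is
not used, which matters only for non-Euclidean dissimilarities), and UMAP
(`uwot`). All stochastic methods run under an explicit seed and the
parameters actually used are recorded in the result. Traces are not
standardized before flattening by default; a `standardize` flag is provided.

Manifold compactness is quantified by the intracluster distance

$$\mathrm{ICD}(C_k) \;=\; \frac{1}{n_k\,(n_k-1)}\sum_{i}\sum_{j\ne i}
\lVert x_i - x_j\rVert_2 ,$$

the mean pairwise Euclidean distance in the embedding space (ordered pairs;
identical to the unordered mean). Lower values mean tighter, less variable
population dynamics. Sessions are embedded separately (per session) before
the metric is taken; the metric itself is translation invariant and scales
linearly under isotropic scaling of the cloud.

## Behavior epochs and ellipse descriptors

`assign_epochs()` maps each 30-frame window to its predominant behavior
(ties to the central frame's label), and `fit_ellipse()` summarizes each
behavior's sub-cloud by the eigenvalues λ₁ ≥ λ₂ of its sample covariance
(n − 1 denominator). Two descriptor conventions are provided because two are
in circulation:

* `convention = "direct"` (default): area `S = π λ₁ λ₂`, eccentricity
  `c = √(1 − λ₂²/λ₁²)` — the formulas applied directly to the eigenvalues;
* `convention = "conf95"`: the textbook 95% confidence ellipse with
  semi-axes `√(χ²₂,₀.₉₅ λᵢ)`, giving `S = π χ²₂,₀.₉₅ √(λ₁λ₂)` and
  `c = √(1 − λ₂/λ₁)`.

The default follows the former because all group comparisons here are
relative, so the choice only rescales descriptors; the switch exists for
users who need the geometric 95% ellipse. A behavior needs at least
`min_points = 3` windows for a well-defined 2×2 covariance; sparser
behaviors are reported absent rather than failing the session.

## Group classification and shuffle controls

`encode_classify()` reproduces a minimal encoder protocol: over `n_repeats`
independent stratified train/test resplits (default 10 repeats, 30% of each
group held out), a single feature is classified by a decision threshold
(cut at midpoints between consecutive sorted training values, direction
chosen by training accuracy — fitted on training rows only), and two or more
features by a Fisher linear discriminant (`MASS::lda`). Accuracy, precision,
recall and F1 (positive class = first-named group) are computed on held-out
sessions and aggregated as mean ± SEM. Splits iterate groups in sorted label
order, so swapping the group naming leaves the splits, and hence accuracy,
unchanged.

`temporal_shuffle()` provides the negative control: `permute_frames`
permutes each neuron's time axis independently (destroying cross-neuron
coordination while preserving per-neuron value multisets), and
`phase_randomize` randomizes Fourier phases while preserving each neuron's
amplitude spectrum. `shuffled_control_run()` re-runs the whole chain on
shuffled recordings with identical downstream seeds, and
`compare_reports()` tests original versus shuffled metrics (Mann–Whitney by
default, or Student's t; identical zero-variance samples give p = 1 by the
midrank convention).

Two caveats about this control are worth stating plainly. First, it tests
*temporal coordination* specifically: per-neuron marginal statistics survive
the shuffle by construction, so when two groups differ in marginals (as the
default synthetic cohort deliberately does — saturated dense traces versus
sparse transients), a residual, marginal-driven discriminability can remain
after shuffling even though the coordination-driven bulk of the effect is
gone. Second, the repeats being train/test *resplits of the same sessions*,
they are correlated samples; a rank test comparing original and shuffled
repeat vectors is therefore anti-conservative, and its p-values should be
read as descriptive rather than calibrated.

## The synthetic cohort generator

The generator emulates what the pipeline consumes, not the biophysics of
the preparation. Per neuron, a Bernoulli event train is drawn at
`event_rate` (events/s); a fraction `shared_factor` of each neuron's events
is copied from a single population-wide train, which plants cross-neuron
correlation. Events are convolved with a difference-of-exponentials kernel
(rise 0.07 s, decay 0.6 s, peak-normalized — the asymmetry of a fast
genetically encoded calcium indicator), passed through a saturating
indicator response, and observed with additive Gaussian noise
(`noise_sd = 0.05` in units of single-transient peak amplitude).

The saturation stage `f(x) = f_{max}(1 − e^{-x/f_{max}})` deserves its own
paragraph. A purely linear events × kernel + noise model cannot express the
phenomenon the cohort is meant to plant: in such a model, raising the event
rate and the shared fraction strictly *adds* structure to the window
vectors, and every embedding — t-SNE included — spreads structured clouds
more widely than unstructured ones, so the "hyperactive" group would always
come out *less* compact. Real indicators, however, have a finite dynamic
range. With a shared ceiling (`f_ceiling = 0.3` for both groups), sparse
baseline activity stays in the indicator's linear range and keeps its
resolved, structured transients, while dense near-synchronous activity
drives the fluorescence into the ceiling, producing exactly the stereotyped,
low-variability traces that make a population's manifold compact. The
ceiling is a property of the recording model shared by all groups; the
planted group difference remains confined to `(event_rate, shared_factor)`.

The default study conditions used throughout the tests and the acceptance
script are: two groups × 12 sessions, N = 80 neurons, T = 4500 frames at
15 Hz (a 5-minute session); baseline group `event_rate = 0.1` ev/s,
`shared_factor = 0.6` (sparse firing with the population-burst co-activation
normal for hippocampal ensembles); compact group `event_rate = 5` ev/s,
`shared_factor = 0.9` (near-tonic, near-globally synchronous activity at the
indicator ceiling — a deliberately strong planted effect for a desk-scale
cohort). These sizes keep a full 10-cohort validation within minutes on one
CPU while leaving ~150 windows per session, comfortably above the t-SNE
perplexity constraint.

Behavior sequences are semi-Markov with geometric dwell times (means:
running 2 s, sitting 4 s, grooming 3 s — short bouts for locomotion, longer
quiescence) and uniform transitions to the other two states. Key-point
tracks attach a rigid 7-point body template to a smoothly random-walking,
wall-reflecting body frame, so the inter-ear distance is exact by
construction. Arena images are high-contrast rings on a light background.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: spatial neuron footprints and crosstalk,
photobleaching and motion artifacts, place-field or task structure in the
activity, behavior-dependent neural activity (behavior labels are
independent of the calcium model, so behavior-specific ellipse differences
between groups reflect overall manifold geometry, not behavioral coding),
multi-animal variability, and real pose-estimation error statistics.

## Numerical choices

* Composite pixels: float internally, stored 8-bit by round-half-up.
* Zone bins: half-open, outer boundary inclusive; `outside` beyond it.
* PCK: closed disc (≤ radius); per-frame reference distance.
* Mode smoothing: non-overlapping blocks; trailing short block smoothed
  with its own mode; ties to the block's central frame, falling back to
  alphabetical order if the central label is not among the tied modes.
* t-SNE: perplexity clamped to `(n−1)/3` with a logged warning; embeddings
  error out on non-finite coordinates.
* Covariance: `n − 1` denominator; eigenvalues clipped at zero within
  `1e-12` for round-off; zero total variance is a degenerate-geometry
  error.
* Savitzky–Golay speeds floored at zero.
* All randomness flows from explicit integer seeds through
  `withr::with_seed`; no function leaves a footprint on the caller's RNG
  state. Derived per-session seeds are reduced modulo 2³¹ − 1.

## Limitations

The intracluster distance is computed on per-session embeddings; absolute
values are therefore not comparable across embedding methods, and for
stochastic methods they carry seed-to-seed variability (group *contrasts*
are the stable quantity). The ellipse descriptors assume 2-D embeddings; no
3-D ellipsoid fitting is provided. The classifier deliberately stops at a
threshold rule and an LDA — no cross-validation of hyperparameters, no
nonlinear models — because its role is to quantify separability of one or
two descriptors, not to maximize it.
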