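---
title: "Models and methods behind placerep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind placerep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`placerep` analyses hippocampal place-cell recordings from foraging on
a rectilinear city-block maze: a walled platform with a 2×3 grid of
square blocks whose interstitial spaces form 17 alleys and 12
intersections. The scientific questions it serves are (i) whether a
cell's multiple fields repeat at structurally similar locations more
than chance field placement would produce, and (ii) how nonpositional
variables — the travel direction through an alley and slow time —
modulate in-field firing rates, including whether that modulation is
shared across a cell's repeating fields. This vignette records the
models, parameter choices, numerical conventions and limitations; the
README shows the user-facing workflow.

## Maze geometry

Coordinates are centimetres in the image frame: the origin at the
platform's north-west corner, x growing east, y growing south, so
*north means decreasing y* — directions are camera-relative, not
compass-relative. The standard platform is 60.96 × 91.44 cm with
19.1 cm blocks (the drawn layout); the 18.4 cm physical block size is
available through `buildStandardMaze(blockSizeCm = 18.4)`, and nothing
downstream depends on which is chosen beyond the bin geometry. The
camera scale defaults to 10 px = 2.1 cm, giving 2.1 cm ratemap bins.

Rectangle membership is half-open, `[x0, x1) × [y0, y1)`, so every
point on a shared boundary belongs to exactly one region; the walkable
mask is defined by bin-centre membership, which makes region bin sets
an exact partition of the mask. Corridors are the rows/columns of
collinear alleys (3 vertical + 4 horizontal); the alley graph connects
alleys sharing an intersection and underlies both the reward
replacement rule and inter-field path lengths.

## Synthetic sessions

The generator's purpose is to emulate the statistical structure the
analysis chain assumes, with known ground truth.

**Behaviour.** A random walk on the region graph, rendered to 30 Hz
frames: intersection centre → alley centre → next intersection centre,
with per-leg speeds drawn from a truncated normal (mean 14, sd 4,
floor 2 cm/s — plausible for a maze that forces a turn every ~20 cm).
Choices at intersections are weighted by a direction bias (north/east
versus south/west), an exponential attraction toward the nearer of the
two primed reward sites, and a penalty against immediate
backtracking. A configurable fraction of alley entries are turnarounds
(enter, reach the centre, exit the same end) — these are what the
turnaround-exclusion rule must catch. Two reward sites are primed at
all times; a visited site triggers a reward event, a 1.5 s dwell (the
low-speed samples the speed filter removes), and replacement by an
alley at graph distance ≥ 2, uniformly. Tracking noise is 0.3 cm
Gaussian jitter clamped into the current region.

**Cells.** About a third of cells are single-fielded; multi-field
cells draw 2–7 fields with mean ≈ 3.5. Fields are hosted by distinct
regions; with probability 0.15 the host is an intersection, otherwise
an alley whose orientation matches the cell's preferred orientation
with probability `alignmentStrength` (default 0.7 — strong but
imperfect alignment, so shuffle tests have signal without being
degenerate). The spatial profile is an isotropic Gaussian (σ = 4 cm)
clipped implicitly by where the animal can walk; the profile is not
derived from data — it is the simplest shape whose detected extent is
predictable. Peak rates are lognormal (median 5 Hz, log-sd 0.4),
baseline 0.05 Hz. Directional gain multiplies the field's rate in its
host orientation's positive direction by a lognormal factor
(log-sd 0.35) and divides it in the opposite direction, so the
geometric mean rate is gain-invariant. Drift envelopes come in four
families — constant, linear ramp, exponential with onset delay, slow
sinusoid — mirroring the qualitative patterns seen in recorded fields;
default magnitude lets a field's rate change by up to ±100% across the
hour.

**Spiking.** Inhomogeneous-Poisson by frame-resolution thinning:
counts are Poisson with mean λ(t)·Δt per 33.3 ms frame, times placed
uniformly within the frame. The discretization error is O(λΔt), i.e.
negligible at place-cell rates. Direction enters λ through the
*pass-level* travel direction of the current alley leg (not the
instantaneous heading), matching how the analysis labels passes.

**What the generator does not emulate** — and hence what passing tests
cannot show about real data: theta rhythmicity and phase precession,
spike-sorting contamination, head-direction dependence distinct from
travel direction, off-track exploratory head movements, and any
behavioural stereotypy beyond the turn biases above.

## Ratemaps and field detection

Running speed is a centred finite difference of 5-frame-smoothed
positions (the estimator is not critical; the threshold, 1.5 cm/s,
is). Spike counts and occupancy are binned at 2.1 cm, each smoothed
with a truncated Gaussian (σ = 1.5 bins, support 3σ), and divided;
because both maps are smoothed identically and zeroed off the mask,
the ratio is unbiased at mask edges. Bins with zero smoothed occupancy
are *invalid*, not zero — they are excluded from peak finding and from
the walkable-area denominator of the size rule.

Detection proceeds: local maxima (8-neighbourhood, plateau-tolerant)
with a minimum Chebyshev separation of 4 bins (= 40 px), greedily
enforced in decreasing-rate order with row-major tie-breaks for
determinism; the ≥ 1 Hz peak criterion is applied to the *seed
maximum* before expansion — otherwise sub-hertz noise maxima grow
enormous low-rate regions that swallow genuine fields; 8-connected
region growing stopping below 20% of the seed peak; a size threshold
of 1% of valid bins; merging of overlapping expansions; then iterative
watershed splitting. The watershed floods the region from all in-field
maxima in decreasing rate order (ties row-major), assigning each bin
to its highest-rate labelled neighbour's basin and recording
inter-basin saddle heights; basins merge whenever a candidate split
fails the acceptance rule — both parts passing the size and peak
thresholds *and* the boundary rate at most 75% of the larger peak.
The test suite validates the saddle heights against a brute-force
threshold-connectivity search. After splitting, a field is kept only
if the 95th percentile of its bin rates is ≥ 1 Hz. Oversized fields
(> 15% of the walkable area) are flagged `oversized`, never modified
or dropped — automated QC flags replace the original manual curation
step.

Region assignment: a field is a member of a region covering ≥ 30% of
the region's bins; among multiple qualifying regions, each must carry
≥ 25% of the field's summed rate. Member alleys are regrouped by
orientation into the vertical/horizontal *portions* used by every
directional analysis. Where a single label per field is required (the
repetition summary), the dominant orientation by summed portion rate
is used, falling back to "intersection".

Units with log10 session mean rate above 0.6 (≈ 3.98 Hz) are excluded
as putative interneurons before any mapping; the inequality is strict
and the base-10 reading is adopted (a natural-log reading would put
the cutoff at 1.8 Hz, implausibly low for a pyramidal/interneuron
boundary); the threshold is a parameter.

## Passes and normalized rates

Passes through a *field* are consecutive in-field frames, with bouts
re-entering within 2 s grouped as one pass, and are kept only when at
least two points lie deeper than 5% of the field's shorter side
(length = y-extent, width = x-extent; depth is Euclidean distance to
the nearest boundary-bin centre). Alley *traversals* use the same
machinery but a 0.5 s bridge gap instead of 2 s: merging at 2 s would
fuse back-to-back genuine traversals (exit the far end, turn at the
intersection, re-enter) into spurious same-end "turnarounds" and
distort the turnaround statistics — at 0.5 s the simulator's
configured turnaround fraction is recovered within ±0.01. An alley's
entrances are its two short ends; the entry/exit end is the one
nearest the first/last frame, the direction is named for the exit end,
and same-end passes are turnarounds (excluded from rate analyses).
A pass is rewarded if a reward event in its alley falls inside its
time span; rewarded passes are excluded by default and retained by the
`keepRewarded` toggle for robustness re-analysis. A field portion
needs at least two passes in each direction to enter directional
analyses.

The normalized pass rate is the mean over visited bins of the
single-pass occupancy-normalized map divided bin-wise by the session
map (bins with zero session rate excluded). This controls for passes
clipping different parts of the field.

## Repetition and the OAS

A repeating cell has ≥ 2 fields in one location type (vertical alley,
horizontal alley, intersection); violations of the pattern are not
penalized. The OAS ranks a cell's alignment ratio `max(n_V, n_H)/n`
within the achievable ratios for `n` alley fields (`k/n`,
`k = ⌈n/2⌉ … n`) and normalizes by the list length, so it lies in
(0, 1] with 1 = fully aligned. Intersection fields count toward the
repeating classification but are excluded from alignment arithmetic.
The population test pools all alley-field orientation labels, permutes
them, and re-deals them to cells preserving each cell's field count —
the minimal reading of reassigning fields while keeping the totals —
1000 times; the empirical mean OAS across multi-fielded cells is
compared one-sided at α = 0.05. Note that the permutation null
preserves the global V/H ratio: a population in which *every* field
shares one orientation is degenerate for this test (the null
collapses to the observed value), which is why mixed preferred
orientations across cells are required for power. Internally the
shuffle uses a rank lookup table by (field count, majority count), so
calibration studies with hundreds of replicates stay cheap.

## Directional statistics

North and east are the positive directions. Per field portion:
a two-sided Mann-Whitney test (midranks; a fully tied sample returns
p = 1) on normalized pass rates by direction; the directionality index
`DI = (mean_pos − mean_neg) / mean_all`; and a Gamma GLM with inverse
link on `normalized rate + 1` (the offset guarantees positivity, as
the Gamma family requires). The base model carries a natural spline of
pass start time with 3 degrees of freedom (boundary knots at the first
and last pass — "three knots" and "three degrees of freedom" are taken
as the same specification); the alternative adds binary current
direction, and the likelihood-ratio statistic is referred to χ²(1).
Prospective/retrospective effects add the previous or next traversal
direction to a base containing time *and* current direction. Fitting
uses iteratively reweighted least squares (relative deviance change
< 1e-8, ≤ 100 iterations); non-convergent or degenerate fits are
flagged and excluded from population counts, which is why denominators
can differ between the Mann-Whitney and GLM summaries.

Two calibration facts shape how results should be read. The
Mann-Whitney test is essentially exact, and it is the statistic used
for per-field type-I calibration claims in the test suite. The
chi-square LRT on a Gamma GLM with estimated dispersion and the +1
offset is mildly anti-conservative at realistic sample sizes (observed
≈ 6–9% at nominal 5% in simulation); this is a property of the
procedure itself, and it is exactly why the label-shuffle control
(`shuffleDirectionControl`) exists — fictive-effect rates should be
judged against the shuffle, not the nominal level. Orientation-split
portions are tested at the Bonferroni level α/2; the time GLM at
α/6 ≈ 0.0083 when used in the orientation-split population analysis
(single synthetic fields in the recovery studies use the nominal
level, having no multiplicity).

## Field pairs

All unordered same-orientation field pairs within a cell are compared:
OLS of one DI on the other (r² equals squared Pearson r — asserted as
an identity test), quadrant counts for the sharing χ² (zero DIs
excluded), and the corridor split (same/different) with a Fisher
r-to-z comparison (`z = (atanh r1 − atanh r2)/√(1/(n1−3)+1/(n2−3))`)
and a label shuffle preserving the two group sizes (Δr² against the
null 95th percentile). The per-field "maximum" normalization seen in
published pair scatters affects only visualization scaling, not the
correlation structure computed here, and is omitted. Sampling bias is
the majority-direction pass fraction; trajectory responses are mean
normalized rates per (previous, current, next) direction triplet,
correlated across the ≥ 3 types shared by both fields.

**The dip test.** No dip implementation is available as a dependency,
so the Hartigan dip statistic is implemented in the package using the
modal-interval algorithm: iteratively compute the greatest convex
minorant and least concave majorant of the ecdf on a shrinking modal
interval, accumulate the forced one-sided deviations on the abandoned
flanks, and return half the largest deviation. Unimodality is taken
relative to continuous unimodal CDFs (atoms only matter under heavy
ties, which continuous rate data do not produce). The implementation
is validated in the test suite against an exact linear-programming
formulation (a slope-unimodal polyline must fit between the two ecdf
staircases shifted by ±d; solved with `boot::simplex`) on random small
samples, plus closed forms: dip({0,1}) = 1/4, equispaced grids give
1/(2n), and a balanced two-point mixture gives 1/4. p-values come from
a uniform-null Monte-Carlo at matched n (default 10,000 draws),
table-free and reproducible by seed.

## Temporal dynamics

The time GLM mirrors the direction GLM with roles swapped (base:
direction; alternative adds the time spline; χ²(3)). Field time series
are resampled by PCHIP — monotonicity-preserving, non-overshooting —
onto a uniform grid of length equal to the longer series (the
correlation is insensitive to the grid once it is dense; tests assert
|Δr| < 0.01 between 10× and 20× oversampling). The implementation is
`pracma::pchip`; the test suite checks it against an independently
coded Fritsch–Carlson construction to 1e-10.

Population-vector drift: the session is cut into six equal windows;
a window's population vector holds each unit's mean normalized
alley-pass rate; window pairs are correlated (pairwise-complete over
units) and the correlation is regressed on absolute window lag. One
structural point deserves emphasis: a *purely common* multiplicative
drift leaves mean-rate PV correlations nearly unchanged — the lag
slope responds to *heterogeneous* drift across units, which is what
the generator's per-field envelope families produce. Empty windows are
dropped with a warning.

## Decoding

Direction: one population vector per complete, unrewarded alley
traversal of the analysed orientation; entry i is unit i's pass rate
divided by its session-wide mean rate over that alley's bins. A random
forest (1000 trees by default, √p features per split) supplies the
out-of-bag accuracy; significance requires exceeding the 95th
percentile of both a label-shuffle null (forests refit on permuted
labels) and a naïve null that guesses labels in proportion to their
session frequencies (expected accuracy Σp²). The conjunctive rule
keeps the false-positive rate at or below the nominal 5% even under
class imbalance; overall (not balanced) accuracy is used, precisely
because the naïve control absorbs imbalance.

Position: spike trains are convolved with a Gaussian kernel
(σ = 25 frames, truncated at 4σ; an 8-frame variant is provided and
leads to the same conclusions on synthetic data), standardized, and
regressed linearly onto x and y. The session is tiled into training
(8000 frames) / buffer (500) / test (1000) / buffer (500) cycles; the
buffer exceeds the kernel's half-support, so no smoothed spike
influences both a training and a test frame. The tiling is circularly
rotated with uniform offsets; performance is r² = 1 − SSE/SST on the
pooled test frames. The control circularly shifts position against
the features, with shifts drawn uniformly outside ±10 s to avoid
near-identity shifts. Temporal decoding uses 10,000/1000/1000 windows,
training each window separately and correlating (Spearman) test
performance with window time before versus after the training window;
drifting codes give positive pre- and negative post-correlations. The
repeating/non-repeating comparison downsamples the larger unit group
to the smaller one (10 draws per rotation) and reports the paired r²
difference distribution.

## Determinism and problem sizes

Every stochastic routine takes an explicit seed and is bit-reproducible
given it; the pipeline derives per-stage seeds from one master seed.
The test suite exercises the chain at sizes chosen to make the
statistics stable but the run short: 15-minute default sessions for
integration tests, one 60-minute ~20-cell session for the
parameter-recovery and decoding studies, 150–500 replicates for power
and calibration claims, and 20–40 seeds for the conjunctive-rule and
PV-slope reliability checks. These are the package's validation
conditions; real recordings of course run at their native sizes.

## Known limitations

- The trajectory model is a plausible stand-in, not a behavioural fit;
  stereotypy in real rats is both stronger and more structured.
- Field profiles are isotropic Gaussians; curved or elongated real
  fields will exercise the watershed and region rules differently.
- The Gamma-LRT's mild anti-conservatism means nominal per-field
  direction/time counts overstate significance; use the shuffle
  controls for population claims.
- The dip statistic assumes effectively continuous data; heavy ties
  inflate it.
- The OAS shuffle is uninformative when all fields share one
  orientation (the null degenerates).
- Theta-scale structure, spike sorting and cross-session stability are
  out of scope.
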