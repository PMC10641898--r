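---
title: "Methods: locomotion-conditioned CA1 calcium imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locomotion-conditioned CA1 calcium imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1net)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where the
underlying procedure is underspecified, and what the synthetic-data tests do
and do not demonstrate about real recordings.

## The analysis problem

A head-fixed mouse runs voluntarily on a spherical treadmill while a
wide-field microscope records GCaMP6f fluorescence from individual CA1
neurons at 20 Hz (1,024 × 1,024 px covering 1.343 × 1.343 mm). The analysis
asks three nested questions: (1) how do single-cell calcium event rates and
shapes differ between resting and running; (2) which cells are reliably
movement-modulated, and which cell pairs are functionally correlated beyond
what their event rates explain; (3) how does network-level connectivity,
summarized by a weighted closeness centrality, change between behavioral
states. Every statistical comparison against chance uses circular-shift
surrogates, which preserve each train's event count and autocorrelation while
destroying its alignment with behavior or with the partner cell.

## Locomotion

Speed comes from two displacement sensors mounted an angle θ apart
(θ ≈ 78° in the rigs emulated here): X = (L − R cos θ)/sin θ, Y = R,
V = √(X² + Y²). The denominator of the X formula is taken as sin θ, the only
reading under which the orthogonal-sensor limit X = L at θ = 90° holds.

Bout segmentation maps each speed sample through a sigmoid membership
F(V) = 1/(1 + e^(−a(V−c))) with steepness a = 0.8 and midpoint
c = max(20th percentile of the session speed, 5 cm/s); the membership trace
is smoothed with a centered 1.5-s moving average and thresholded at 10% of
its session maximum. Stretches at least 2 s long become run (supra-threshold)
or rest (sub-threshold) bouts; everything else is unclassified. Numerical
choices where the procedure is open:

* **Degenerate sessions.** For an animal that never moves, the smoothed
  membership trace is constant at its resting floor and "10% of its maximum"
  would label the entire session as running. The threshold maximum is floored
  at 0.5 — the membership of a sample moving exactly at the midpoint `c` — so
  an all-quiet session becomes one long rest bout.
* **Boundary refinement.** The 1.5-s smoothing otherwise stretches every bout
  by roughly 0.6 s per side (and lets a 1-s speed burst masquerade as a 2-s
  bout). Candidate intervals are therefore found on the smoothed trace but
  trimmed to the first and last raw-membership threshold crossings inside
  them before the 2-s rule is applied.
* Ties exactly at the threshold count as supra-threshold; percentiles use
  linear interpolation between order statistics (R's default type 7);
  the 2-s rule converts to `ceiling(min_s * fs)` samples.

Sessions with less than 60 s in either state or fewer than 5 run bouts are
flagged ineligible for locomotion-conditioned analyses (`session_qc()`).

## Imaging

Motion correction is rigid and integer-pixel: a reference (pixel mean of the
first 2,047 frames) and each frame are contrast-enhanced — background removal
by a σ = 50 px Gaussian, edges as the difference of σ = 2 and σ = 1 px
Gaussians added back with gain 100, then z-normalization — and the shift is
read off the peak of their FFT cross-correlation (mean-subtracted,
zero-padded). Integer shifts keep the procedure exactly invertible and
testable against planted translations; no subpixel interpolation is
attempted. Trace extraction subtracts, per frame, the mean of a background
ring (radii 15–50 px) around each ROI, excluding all ROI pixels and a 25-px
border. Traces are interpolated to 20 Hz, linearly detrended, and min-max
normalized to [0, 1]; constant traces are rejected.

## Event detection

The detector works in two stages.

**Candidates.** The trace is smoothed with a 1-s moving average (for power
estimation only — amplitudes are always measured near the raw trace), and a
sliding multitaper spectrogram (DPSS tapers, time-bandwidth 2, 3 tapers; 1-s
window, 0.05-s step; per-window mean removed) is averaged below 2 Hz.
Outliers of the power first-difference beyond 3 scaled MADs (consistency
factor 1.4826, matching the common outlier routine) are merged into
consecutive runs. Two screens follow from the construction: only runs with a
positive mean power change are onset candidates (negative runs mark event
falls), and a run must span at least `window_s / step_s` (= 20) consecutive
steps — a genuine transient elevates every window that overlaps it, while
noise blips flag only a few isolated steps. DPSS tapers are computed from the
standard tridiagonal eigenproblem, as no installed package provides them.

**Localization.** Within each candidate span every local maximum of a
5-sample (0.25 s) smoothed copy is a potential peak, so that two events close
enough to share one outlier run are still separated. The onset is the last
crossing of 10% of the local height before the peak, measured against the
median of the 2 s preceding the peak; the median baseline is robust to the
rise itself and caps the apparent height of pure-noise candidates near the
noise SD, which is what makes the iterative threshold below terminate.
Candidates whose rising phases overlap are collapsed to the tallest.

**Iterative acceptance.** Iteration k (k = 0, 1, ...) accepts candidates with
rise ≥ 3 samples (150 ms) and amplitude above `7·(1 − 0.4)^k` SDs of the
trace in the `10·(1 + 0.75)^k` s before onset. Samples of accepted events
(onset through the first post-peak sample below the onset value, capped at
the next candidate onset) are excluded from later SD windows; candidates with
fewer than 20 usable window samples are deferred to the next iteration. The
procedure stops at the first iteration that accepts nothing; acceptance is
monotone and termination is guaranteed (each continuing iteration consumes at
least one candidate).

FWHM is the time between the half-height crossings on the rise and decay
(sub-sample linear interpolation), excluded when the next event starts before
the decay crossing or when the event has more than one peak above 75% of its
height (counted as upward crossings of the 75% level on the smoothed copy,
which is robust to single-sample noise at the plateau).

## Permutation tests

Binarized trains carry 1 over each event's rising phase (onset to peak,
inclusive) — the rising phase tracks spiking, while the slow indicator decay
would inflate correlations.

* **Movement modulation** (per cell): A = (Σ_run x / Σ_run t −
  Σ_rest x / Σ_rest t) × 100, with time counted in samples over the
  concatenated state periods. The null is A under 1,000 circular shifts of
  the binarized train by integer lags uniform on 1..L−1; cells strictly above
  the null's 97.5th percentile are modulated.
* **Pairwise correlation** (per pair, per scope): Pearson r between the 0/1
  trains, concatenated to the rest, run, or full-session scope. The null is r
  under 2,000 circular shifts of the higher-numbered cell's concatenated
  train; pairs strictly above the 95th percentile with r > 0 are correlated,
  non-negative sub-threshold pairs are random, negative pairs are excluded
  (GCaMP sparseness makes negative r uninterpretable), constant trains are
  ineligible. Shifting after concatenation (not before) preserves
  state-specific event counts exactly, which is the point of the rate
  control. Pairs closer than 20 px (26.2 μm at 1.343 mm/1,024 px) are
  excluded against optical cross-talk.

Both tests are computed exactly for all lags at once through FFT circular
cross-correlation of the 0/1 vectors (Pearson r has a closed form in the
overlap count), and the random lags are then sampled from the precomputed
values; tests assert bit-level agreement with direct rotation. This makes the
2,000-shuffle null essentially free per pair.

A note on calibration: with very sparse trains and short (0.5 s) rising
phases the overlap count takes few distinct values, ties accumulate at the
null's 95th percentile, and the strict inequality makes the pair test
conservative (≈2% empirical rate at nominal 5%). With rising phases near the
1.4–1.6 s measured for real CA1 GCaMP6f events the overlap distribution is
fine-grained and the empirical rate is ≈4.7% over 2,000 independent pairs.
The calibration suite therefore simulates trains with 1.5-s rises; the
modulation test, whose statistic is not integer-valued, calibrates at its
nominal 2.5% under both settings.

## Network centrality

Correlated pairs of one behavioral state form an undirected simple graph over
all recorded cells; the edge weight is the pair's state-restricted Pearson r
and the edge length is d = log(1/w). Per node, c(i) = (A_i/(N−1))² · 1/C_i,
where A_i counts reachable nodes and C_i sums their shortest-path distances
(Dijkstra, via igraph); isolated nodes score 0. The network value is the node
mean times N (equal to Σ c_i), and the rest − run difference of network
values measures desynchronization during locomotion. Decisions on open
points:

* **Log base**: natural log (exposed as `log_base = "e" | "10"`). The
  published 4-node worked example constrains only A and C, not the base; the
  scale check `w = e^{−1} → c = 1` in the tests documents the choice.
* **Isolated cells stay in the graph** and enter N and the network mean with
  c = 0; otherwise the "multiply by node count" normalization has no stable
  meaning across states of the same session.
* Weights are clipped to at most 1 − 10⁻⁹ so lengths stay positive (r = 1
  between distinct cells would give an unbounded centrality).

## Statistical layer

Proportions carry normal-approximation binomial CIs (half-width
1.96·√(P(1−P)/n), percent scale); proportions are compared with Fisher's
exact test; two-group comparisons use Wilcoxon rank-sum and zero-median tests
use the signed rank. Factorial session-level comparisons use a Gaussian
linear model `y ~ f1 * f2` (OLS = ML here) gated by an ML likelihood-ratio
deviance test against the intercept-only model; when the interaction is
significant at 0.05, per-level post-hoc models `y ~ f2` are fitted — with
two-level factors no other post-hoc comparison is needed. No multiple-testing
correction is applied anywhere, and the report records that fact. The
significance threshold is 0.05 throughout.

## The synthetic-data generator

`sim_config()` defaults describe the emulated recording: 600-s sessions at
20 Hz; ~20 running bouts of mean duration 12 s (8–18 cm/s plateaus with
smooth edges, small non-negative rest jitter); per-cell Poisson events at
1.71 events/min at rest and 2.79 events/min during running for modulated
cells (non-modulated cells stay at the rest rate); kernel with a linear rise
(default 0.5 s — deliberately sharp so detector-recovery tests have
unambiguous onsets; set `rise_s = 1.5` to match measured event shapes) and
1-s exponential decay; amplitudes N(0.5, 0.1) dF/F against 0.02 noise SD.
Correlated pairs copy events from a latent per-pair Poisson source with
probability `shared_fraction`, which may differ between rest and run
(`c(rest =, run =)`) — that is what lets planted cohorts reduce the run-state
correlated-pair fraction while keeping strengths equal. Private rates are
reduced so totals stay at the configured rate. All randomness flows from one
seeded generator per stage; identical configs give bit-identical output.

The generator emulates event statistics, bout structure, and shared-source
correlations. It does **not** emulate optics (photon noise, neuropil
contamination beyond the ring fixture's uniform background, focal drift),
overlapping cells, non-Poisson burstiness, or slow rate drift. Tests passing
on this generator therefore validate the algorithmic chain — segmentation,
detection, surrogate tests, graph analysis — under the stated event model,
not the upstream image-quality assumptions of a real recording.

## Validation problem sizes

The test suite validates at sizes chosen to make sampling error negligible
while keeping a full run in minutes: permutation calibration on 2,000 null
cells (5 × 400) and 2,000 independent pairs (20 × 100 disjoint pairs) at the
full 1,000/2,000 shuffle counts; detector recovery on 18 sessions' worth of
traces (~340 events) plus 8 pure-noise traces; closeness centrality against a
dense Floyd–Warshall oracle on 200 random graphs of up to 8 nodes; and
planted-effect cohorts of 8 + 8 sessions of 24 cells. The cohort analysis
reproduces the expected directions: rest-sharing sessions show a positive
rest − run closeness difference, equal-sharing sessions with more source
pairs show a near-zero difference and a larger correlated-pair fraction.

## Known limitations

* The detector's onset localization (median-baseline 10% crossing) and the
  minimum outlier-run length are this package's resolutions of steps the
  original description leaves open; both are documented above and covered by
  recovery tests, but other resolutions exist.
* At event amplitudes below ~7 noise SDs the first iteration accepts nothing
  and the detector is blind by construction; the sensitivity contract is
  stated for amplitudes well above that gate.
* Sample indices are 1-based and bout intervals are closed `[start, end]`,
  the R convention, throughout.
* Sessions are treated as independent in all statistics (no mixed effects),
  matching the analysis this package reimplements.
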