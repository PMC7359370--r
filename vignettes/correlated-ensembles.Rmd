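---
title: "Correlated ensemble analysis for calcium imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated ensemble analysis for calcium imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caensemble)
```

## The scientific problem

During contextual fear conditioning, a mouse explores a context (session A1),
receives a brief foot shock at the end, and is tested the next day in the
same context (A2, memory retrieval) and in a novel context (B). One-photon
miniscope imaging of GCaMP6f in ventral hippocampal CA1 yields per-neuron
fluorescence traces across all three sessions, with cells tracked by
concatenating the videos before segmentation. The analyses this package
implements ask how *pairwise co-activity* among vCA1 neurons reorganizes
with memory: which cells respond to the shock, which cells become
correlated with those shock cells during retrieval ("A2 shock-partners"),
how the correlation-graph structure changes from encoding to retrieval, and
whether that change scales with behavioral memory strength (the change in
percent time freezing).

The package consumes extracted traces (cells x frames, plus a session
timeline); segmentation, motion correction, and behavioral scoring are out
of scope. Because real recordings are not required, a ground-truthed
synthetic generator reproduces the statistical structure the analyses
assume, and every stage is validated against it.

## Transient event detection

Traces are converted to per-cell event trains in three steps.

1. **z-scaling.** The silent-timepoint threshold is the pooled 0.50
   quantile of all fluorescence values from all cells in the field of view;
   frames below it are "silent". Each cell is scaled by a robust estimate
   of its Gaussian noise level (1.4826 x MAD of the trace) and centered on
   its silent-timepoint mean. The mean of a sub-quantile subset of
   symmetric noise is biased low by $\sigma\,\varphi(\Phi^{-1}(q))/q$
   (truncated-Gaussian identity, with $q$ the cell's silent fraction), and
   that correction is applied so a pure-noise trace maps to z units with
   mean ~0 and s.d. ~1. Without the correction the baseline would sit
   ~0.8 s.d. below zero and both thresholds below would be mis-referenced.
2. **Downsampling.** Frames are block-averaged to 5 frames/s. Noise is
   estimated *before* this step, at the acquisition rate, where the MAD is
   a clean noise statistic; averaging then suppresses frame noise (by 2x
   for 20-fps input) while leaving the slow transient kernel largely
   intact. Z-scaling after downsampling would renormalize the suppressed
   noise back to 1 s.d. and make the detector's false-positive behavior on
   quiet cells far worse; this ordering is a deliberate design choice.
3. **Envelope detection.** A candidate transient runs from an upward
   crossing of the 0.5-s.d. baseline to the return below it. It is accepted
   when its peak reaches 2 s.d. *and* its supra-baseline duration reaches
   the minimum duration for that amplitude (below). Within an accepted
   envelope, additional rising peaks with prominence >= 1.5 s.d. and
   separation >= 1 s are split into separate events (multi-peaked
   transients). The event time is the peak frame time and the amplitude the
   peak z value.

**The minimum-duration rule.** A transient of amplitude $A$ must outlast
$t_{1/2}\log_2(A/A_0)$ with $t_{1/2} = 0.2$ s (GCaMP6f decay half-time) and
$A_0 = 0.5$: the time an exponential with that half-time needs to decay
from $A$ to the baseline level. This is the time-dimensioned reading of the
duration rule; it rejects fluctuations that decay faster than the indicator
physically can. Note that for an *ideal* indicator kernel the rule is
exactly marginal — the noise-free supra-baseline time equals the required
duration plus the rise time — so the implementation measures duration with
linearly interpolated baseline crossings rather than whole-frame counts;
frame counting is biased low by up to one frame and rejects genuine
transients at every amplitude.

**Operating characteristics.** With the default synthetic conditions
(amplitudes drawn at mean 4, s.d. 1 noise units — deliberately near
threshold — rendered at 20 fps and analyzed at 5 fps), measured recall is
~0.85 and precision >0.99, with <0.05 false events per quiet cell per
3-min session. The recall ceiling is structural: block-averaging a
0.2-s-half-life transient into 0.2-s bins attenuates its peak by a factor
of ~0.72-0.80 depending on phase, so events drawn below ~2.7 s.d. present
below the 2-s.d. threshold in the analysis domain. Raising the planted
amplitudes would hide this; the package reports it instead.

## Binarized rasters and correlation graphs

Event trains are binarized into 1-s occupancy bins (half-open
`[b, b+1)`; a bin is 1 if it contains at least one peak, regardless of
count). Pearson's R is computed for every cell pair; pairs with a constant
series (silent cells) are undefined and can never form an edge, but such
cells stay in the field-of-view denominators. An edge requires R
*strictly* above the threshold — the fixed `R > 0.3` rule of the primary
analyses, or per-pair shuffle-calibrated thresholds: each cell's occupied
bins are re-drawn uniformly (preserving event counts; a circular-shift
option is provided), R is recomputed over 1000 iterations, and the
per-pair threshold is the 0.95 null quantile (optionally Bonferroni
corrected by the number of pair comparisons in the FOV).

A conservatism note worth knowing: for binary rasters the null R
distribution is supported on a handful of atoms (the possible overlap
counts), the 0.95 quantile falls *on* an atom, and the strict inequality
keeps only the mass beyond it. On independent Poisson cells at realistic
rates the realized edge rate is therefore ~0.01-0.03 rather than the
nominal 0.05. This is a generic property of permutation tests on sparse
discrete data, not an implementation artifact; the Bonferroni variant is
conservative a fortiori.

Node metrics follow the published definitions exactly: correlated pair
ratio = degree / total FOV cells; clustering coefficient = edges among
neighbors / possible edges among neighbors (0 for degree < 2); component
membership = 1 iff the cell's connected component contains at least two
other neurons (size >= 3); component probability = FOV mean of the
membership flags. Pair ratio and clustering are computed directly from the
adjacency matrix; components come from igraph. The test suite checks all
of them against an independent brute-force oracle (neighbor-pair
enumeration, reachability by matrix powers) on thousands of random graphs.

FOVs with fewer than 20 cells are refused by default (`min_cells`),
because sparse FOVs under-sample potential correlation partners.

## Stimulus-responsive cells

A cell is shock- (or tone-, or opto-) responsive when its pooled event
rate over the response windows exceeds the mean of a shuffle null by 1
null-s.d.; the null re-draws the cell's event times uniformly over the
session 1000 times. The shock-response window defaults to shock onset to
onset + 6 s (178-184 s), matching the optogenetic silencing window that
brackets the 2-s shock; A1 sessions are extended to 184 s to contain it.
Tone windows are the full pooled 20-s tones; opto windows are the first
6 s of each 30-s LED pulse.

Two calibration facts follow from the discreteness of event counts and are
verified empirically. First, on unmodulated Poisson cells the 1-s.d. rule
flags ~10-20% of cells — the one-sided tail mass above mean + 1 s.d. of a
discrete rate distribution, not 16% of a Gaussian. (The published shock
fraction, 111 of 848 cells, is consistent with a liberal 1-s.d.
criterion.) Second, sensitivity is count-limited: with a 6-s window, a
cell whose in-window rate is only 3x a 1/min background expects 0.3
in-window events, so no criterion can flag more than
$1 - e^{-0.3} \approx 26\%$ of such cells. Detecting 80% of responders
requires roughly two expected in-window events — e.g. a 10x elevation over
a 2/min background, which is where the synthetic shock cells sit (a
near-certain transient during the shock, matching the robust shock
responses in the recordings).

The opto response heatmap averages transient-filtered activity
(non-transient frames zeroed via the detection mask) in 200-ms bins over
the 6 s before and the first 6 s of each pulse, min-max normalizes over
the whole matrix (a per-row option exists), and sorts cells by their mean
ON - OFF change.

## Partner partitioning, deltas, and the bias control

Shock cells are classified in A1; every non-shock cell with at least one
A2 edge to a shock cell is an A2 shock-partner; all remaining cells are
non-partners. The three classes are disjoint and exhaustive, and shock
cells are never partners. Per-cell metric changes are computed against A1
(A2 - A1, B - A1) over cells tracked in both sessions.

Partners have, by definition, at least one A2 correlated pair, so their
metric changes could be inflated by selection alone. The control resamples
size-matched sets from the non-partner population restricted to cells with
at least one A2 edge (10,000 iterations) and reports the add-one empirical
p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$ per metric, which
cannot be zero. Three properties discovered during validation are worth
recording.

First, the default scheme builds its null from the eligible pool *alone*
(as the original procedure describes). A without-replacement null from a
finite pool under-disperses relative to an independent partner mean
(finite-population correction), and the pool mean is itself estimated, so
under the null this scheme rejects at ~8-10% rather than 5% whenever the
pool is only a few times the partner count — and at matched proportions
that inflation does not vanish with FOV size. A `scheme = "permutation"`
option resamples partner-sized sets from the *union* of partners and
eligible cells, which is an exact randomization test (conservative under
ties); the test suite verifies its calibration. The default remains the
published scheme; choose the permutation scheme when the control's p-value
is itself a primary endpoint.

Second, the control needs a non-degenerate eligible pool: in a sparse FOV
the pool can shrink to one or two cells and the empirical p collapses to a
coin flip. This is another face of the 20-cell FOV inclusion rule.

Relatedly, the ≥1-edge restriction removes *most* but not *all* of the
selection effect: even on fully independent rasters, a cell selected for
having an edge into the small shock-cell set keeps an essentially free +1
edge on top of an unconditioned remainder, whereas an eligible cell's ≥1
edge is absorbed by the bulk of its possible partners — so true partners
are slightly degree-advantaged under the null and *both* schemes reject
above nominal (measured ~0.10-0.25 for the published scheme, ~0.05-0.10
for the permutation scheme, on default-sized null FOVs). The permutation
scheme is exactly calibrated when partner labels are genuinely
exchangeable with eligible labels, which the test suite verifies by
assigning the labels at random.

Third, for the *binary* component-membership metric the control is
intrinsically weak under strong planted structure:
an eligible non-partner whose single chance edge happens to attach to the
retrieval ensemble's component scores a delta of 1 — the same as a true
partner — so the resampled null overlaps the partner effect by
construction. The package therefore treats the pair-ratio control as the
primary gate in its own end-to-end recovery checks while still reporting
all three.

The memory-strength analysis regresses the per-FOV mean A2 - A1 change
over the union of shock cells and their A2 partners on the per-animal
change in freezing (ordinary least squares; slope, R^2, F on (1, n-2)
degrees of freedom, two-sided p). The union (rather than the partner class
alone) matches the described per-FOV aggregation; a class-restricted
variant is a one-line filter on the delta table.

State-restricted graphs use freeze/non-freeze bin masks: a 1-s bin is
"frozen" when more than half of it overlaps a scored freezing bout, and
masked-out bins are dropped before correlation, which is equivalent to
cropping the raster.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions of every recovery check.

* **Sessions**: A1 184 s with the shock at 178-180 s (extended past 180 s
  to contain the response window), A2 and B 180 s; a tone variant of B
  (360 s, three 20-s tones at minutes 3/4/5) and a homecage opto session
  (six 30-s ON epochs interleaved with seven 60-s OFF epochs) are
  available.
* **Background activity**: homogeneous Poisson events at 2/min per cell —
  the sparse-transient regime of ventral CA1 pyramidal cells.
* **FOV size**: 70 cells, matching the whole-population recordings
  (~848 cells over 12 mice). Sparser FOVs starve the bias control's
  eligible pool; the 20-cell inclusion rule exists for the same reason.
* **Correlated ensembles**: a latent-source copy model. A module is a
  latent Poisson train (default 4/min); each member receives each latent
  event with probability `participation` (default 0.8) at a Gaussian
  jitter (s.d. 0.2 s), so co-events mostly share a 1-s bin without
  committing to any spiking model. The default plant places one A2-only
  module spanning 3 of the 6 shock cells plus 9 prospective partners —
  only part of the shock population joins the retrieval ensemble, which is
  what makes the partner-class increase exceed the shock-class increase.
  After detection losses, planted pair correlations land at R ~0.25-0.4,
  i.e. deliberately near the 0.3 edge threshold rather than comfortably
  above it.
* **Shock responses**: shock cells multiply their rate by 10 inside the
  6-s response window (about two expected transients per shock — a robust,
  near-certain response; see the sensitivity arithmetic above).
* **Rendering**: each event contributes a linear 0.2-s rise to its
  amplitude followed by exponential decay with 200-ms half-time;
  amplitudes are i.i.d. normal (mean 4, s.d. 1) in units of the additive
  white trace noise, floored at 0.2; traces are rendered at 20 fps at
  frame centers. Overlapping kernels sum.
* **Behavior**: freezing bouts alternate with mobility as exponential
  intervals (freeze bouts mean 4 s, floored at the 1-s minimum), scaled to
  a per-session target fraction (A1 5%, A2 30%, B 10%); the cohort
  generator draws per-animal freezing changes uniformly and sets planted
  ensemble strength = slope x freezing change + Gaussian noise, in the
  units of the regression response, so the downstream fit recovers the
  slope. In rendered cohorts the A2 module participation is a clamped
  monotone map of strength (4x, clipped to [0.05, 0.95]).
* **Centroids**: uniform over a 300-um FOV with module members clustered
  (30-um Gaussian), so correlated pairs are spatially closer, as in
  tissue.

What the generator does **not** emulate: indicator nonlinearity and
saturation, photobleaching and slow drift, motion artifacts, correlated
(pink) noise, neuropil contamination, cross-session tracking errors, and
behavior-locked rate modulation beyond the shock window. Passing recovery
tests therefore validate the analysis logic under the stated statistical
structure, not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Seeds: every random stage takes an explicit seed; helpers restore the
  caller's RNG state. Child seeds are derived arithmetically and kept in
  the 32-bit range. A fixed-seed `run_pipeline()` is byte-identical across
  executions (the timestamped log file aside).
* Ties and boundaries: bins and windows are half-open; an event at
  exactly 1.0 s falls in bin `[1, 2)`; `R = 0.3` exactly is *not* an edge;
  duration comparisons carry a 1e-9 tolerance.
* Constant series: silent or saturated cells are untestable for
  correlation (no edges, recorded as such) but remain in FOV denominators;
  zero-variance traces are excluded from z-scaling with a warning.
* Peak selection within an envelope follows the findpeaks convention:
  candidates sorted by height, prominence measured to the higher of the
  two flanking bases, lower peaks within 1 s of an accepted peak dropped.
  The envelope maximum is always an event.
* Empty inputs: an empty train has rate 0 and is never responsive
  (degenerate all-zero null); an empty reference edge set makes
  persistence undefined (`NA` with a message) rather than 0.
* The regression refuses n < 3 or a zero-variance predictor.

## Problem sizes in the validation suite

The test suite validates the metric implementations against brute force on
1000 random graphs (<= 12 nodes), calibrates the shuffle edge test on 50
simulated 20-cell FOVs, measures detection recall/precision on 60 rendered
cells plus exact recovery on noise-free traces, runs 500-cell sensitivity
and 1000-cell specificity checks of the shock classifier, 50 end-to-end
planted-ensemble recoveries plus 200 null datasets for the bias control,
200 cohort replicates for CI coverage, and a byte-identity check of the
full pipeline. These sizes make the Monte-Carlo bands quoted above tight
enough to be meaningful while keeping the default suite around five
minutes on one core.

## Known limitations

* Detection recall saturates near 0.85 under the near-threshold amplitude
  regime (by design of that regime; see above).
* The shuffle-calibrated edge test and the 1-s.d. responsive-cell rule are
  both conservative/liberal respectively in ways driven by discreteness;
  both are characterized empirically in the test suite rather than assumed
  nominal.
* Cross-session cell identity is assumed given (ids are stable strings);
  no registration errors are modeled.
* Correlations are instantaneous at the 1-s scale; no time-lagged
  dependence, weighted graphs, or community detection beyond connected
  components.
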