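---
title: "Methods: spatial analysis of single-unit recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of single-unit recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spatunits)
```

## Scope

`spatunits` analyses sorted single-unit spike trains recorded while an
animal forages in a walled open arena. The pipeline runs from raw inputs
(a timestamped position/heading track and per-unit spike times) to
occupancy-normalised rate maps, scalar spatial metrics, cell-type labels,
burst statistics, an occupancy-matched downsampling control, and
condition-level presence statistics comparing how often spatial cells
appear in control versus lesion recordings. A synthetic-data module
generates foraging trajectories and tuned spike trains with known ground
truth, so every stage is testable without recorded data.

## Rate maps and scalar metrics

The arena is binned into 3 cm square pixels — the one bin size the
recording methodology states, applied uniformly. Occupancy accumulates
the tracking-sample intervals falling in each pixel; spike positions are
linearly interpolated from the track at each spike time. The raw rate is
`spikes / seconds` per visited pixel; unvisited pixels are masked as
`NA`, never zero. A pixel counts as visited after a single tracking
sample — the least surprising rule where none is stated.

A mask-aware Gaussian smoothed copy (sigma = 1 bin) is carried for
display and for field detection, where pixel contiguity matters. The
scalar metrics are computed on the *raw* map: spatial coherence is
defined as the correlation between a pixel's rate and its neighbours'
mean, and pre-smoothing would build in exactly the correlation the
statistic is meant to measure.

With occupancy probabilities $p_i$, pixel rates $\lambda_i$ and mean
rate $\bar\lambda = \sum_i p_i \lambda_i$:

* **Spatial information** (bits/spike):
  $\sum_i p_i (\lambda_i/\bar\lambda)\log_2(\lambda_i/\bar\lambda)$,
  with $0\log 0 \equiv 0$. Zero for uniform firing; $\log_2 N$ when all
  firing is confined to one of $N$ equally occupied pixels.
* **Spatial coherence**: Pearson correlation between each visited
  pixel's rate and the mean rate of its visited 8-neighbours (pixels
  with no visited neighbour are excluded). Raw correlation, no Fisher
  transform, so the 0.25 place-cell criterion stays interpretable.
* **Sparsity**: $(\sum_i p_i\lambda_i)^2 / \sum_i p_i\lambda_i^2$,
  roughly the active fraction of the environment.
* **Mean rate**: spikes over recording duration.

Undefined metrics (zero-rate maps, constant maps) propagate as `NA`,
never as 0, so they cannot silently pass or fail a classification
threshold.

Fields follow the nine-pixel rules: a *firing field* is a 4-connected
component ("sharing a side") of at least nine pixels with rate above
zero; a *place field* additionally requires its pixels to exceed 20 % of
the map peak. The plug-in information estimate is biased upward at low
spike counts; the place-cell criteria are conjunctive (information,
coherence, rate, and a field), which is what keeps untuned units out in
practice.

## Directional, grid and border analysis

Head-direction tuning uses 5 degree bins (72 bins): dwell time per bin
from the sample intervals, spike headings from the nearest preceding
sample, rate = spikes/dwell. Tuning strength is the resultant length of
the rate-weighted bin centres.

The spatial autocorrelogram is the Pearson correlation of the (smoothed)
map with itself at every integer-pixel lag, over pixels visited in both
copies; lags with fewer than 20 overlapping pixels are masked. The grid
score correlates the annulus between the central peak and 1.25 x the
estimated spacing with itself rotated by 30/60/90/120/150 degrees:
`min(r60, r120) - max(r30, r90, r150)`. The central-peak radius is the
first local minimum of the radial profile; the annulus is capped at
0.75 x the maximal axial lag because corner lags have too little overlap
to estimate. Spacing is the median distance of the six inner peaks and
orientation the angle of the lowest-angle peak modulo 60 — measured from
the autocorrelogram peaks, which lie 30 degrees off the underlying plane
wave directions.

Two estimator properties worth knowing:

* For any 4-fold-symmetric map (a central bump, a disk), the
  square-window autocorrelogram has r90 essentially equal to 1, so such
  maps score strongly *negative* (around -1), not 0. This is the
  behaviour of the standard sliding-window estimator and is precisely
  why place cells are a reliable negative control for grid
  classification.
* On the synthetic battery the score is strongly bimodal: clean grid
  cells score above 1.3 while place, head-direction and untuned cells
  stay below about 0.5. The grid-label threshold defaults to 0.8, the
  middle of that empty margin (calibrated once on the battery,
  configurable like every threshold).

The border score uses the coverage-versus-distance construction:
`c` is the largest fraction of one wall's adjacent pixels covered by a
single field, `d` the rate-weighted mean distance of field pixels to the
nearest wall normalised by half the arena's shorter side, and the score
is `(c - d)/(c + d)`. Fields here are *place* fields (20 % of peak):
using all positive-rate pixels makes `c = 1` for any broadly active
unit. Note that a spatially uniform map scores exactly 0.5 in
expectation (`c = 1`, `d = 1/3`), i.e. the conventional 0.5 threshold
sits on the null value. The border *label* therefore additionally
requires spatial coherence above 0.25 — border cells are spatial cells,
and an untuned map should not qualify on arena geometry alone.

## Classification

Spatial labels are assigned by precedence — grid, then head-direction,
then border, then place, then nonspatial — which resolves conjunctive
cells deterministically. The place criteria (information > 0.5
bits/spike, coherence > 0.25, rate > 0.25 Hz, at least one place field;
all strict) are the study's stated inclusion rules; the other thresholds
are package defaults exposed in `classification_thresholds()`. Labels
are pure functions of the stored metrics and thresholds.

Firing-type labels: *bursting* if the propensity to burst is at least
0.05; *fast-spiking* if the mean rate is at least 10 Hz with spike width
under 150 us; *theta* if the theta index is at least 1.5; else
*regular*. The underlying report delegates these criteria to earlier
in-vitro/in-vivo classification work without restating them, so the
numbers here are package defaults. The theta index is the mean power of
the spike-train autocorrelogram spectrum inside 4-12 Hz over the mean
power outside it (flat spectrum: about 1). A binned-count periodogram
version was tried first and rejected: a narrow spectral line averaged
over a 8 Hz-wide band dilutes to near 1 even for strongly rhythmic
trains.

## Bursts

A burst is a maximal run of interspike intervals of at most 6 ms
containing at least two spikes. The source phrasing "each ISI was a
minimum of 6 ms" is read as a maximum: the literal reading contradicts
the burst-analysis lineage it cites and every conventional definition
(`isi_rule = "min"` flips to the literal variant). The 50 ms minimum
inter-burst interval is enforced as a minimum gap between distinct
events: qualifying runs closer than that are concatenated into one burst
event. The duty cycle is the session mean burst duration over the
session mean inter-burst interval, which makes
`duty_cycle = mean_burst_duration / mean_ibi` an exact identity.

Waveform metrics follow the peak/trough definitions: amplitude from the
last pre-peak negative trough (or zero if none), height from the global
minimum, width as the post-peak time to first fall below 25 % of peak,
linearly interpolated between samples.

## Presence statistics

Let `PC` and `PL` be the probabilities that a control or lesion
recording contains a spatial cell. With a uniform prior on the unit
square and independent recordings, the likelihood of the contingency
counts is a product of two binomial pmfs and the posterior is evaluated
on a 1001 x 1001 midpoint grid, normalised to sum to 1 (the evidence is
the normalising constant). Grid integration rather than sampling: the
posterior is two-dimensional and cheap, and a deterministic result
supports exact regression tests. Grid points exactly on the boundary
`PC = k PL` contribute half mass, removing resolution-parity artifacts;
marginals converge to the conjugate Beta forms as the grid refines.

`P(PC > PL)` computed this way on the published counts (15/53 control,
0/47 lesion) is 0.99999 — at four decimals this is one unit above the
printed 0.9999, consistent with the source's own "~99.99 %" phrasing.
`P(PC > 5 PL)` reproduces 0.9328 exactly.

Barnard's unconditional exact test orders outcomes by the absolute Wald
statistic `(p1 - p2)/sqrt(p1(1-p1)/CR + p2(1-p2)/LR)` (degenerate
proportions contribute zero variance; equal degenerate proportions give
statistic 0 by convention). All `(CR+1)(LR+1)` tables are enumerated and
the tail probability is maximised over a 2001-point midpoint grid of the
common nuisance proportion on (0, 1), endpoints excluded.

## Occupancy-matched downsampling

To separate tuning loss from under-exploration, each recording is
reduced to one list entry per tracking sample `(x, y, spikes in that
sample interval)` — one sample is the finest faithful time-bin
granularity. The target recording B is binned into 3 cm squares; the
downsampled recording A reuses B's bin *counts* scaled to A's arena
extent (the two arenas may differ in size). Per repetition (200 by
default), entries of A are drawn per bin with replacement, the per-bin
draw count being the minimum of the two recordings' counts there, and
coherence, information and sparsity are recomputed from the sampled
entries. Downsampling a recording against itself is the calibration
case: per-bin minima equal the original counts and only resampling noise
remains. On the synthetic battery, coherence moves less than information
under self-downsampling — the rank analogue of the original
observation; the published mean decreases (0.015 against self) are
data-dependent and not targeted.

## Synthetic data

The trajectory is a smoothed random walk: Ornstein-Uhlenbeck speed
around 25 cm/s (relaxation 1 s, fluctuation 0.45 x mean), Gaussian
direction increments (1.4 rad/sqrt(s)), reflection at the walls, heading
equal to motion direction plus 3 degrees of noise. These values were
chosen once so that a 20-minute session covers at least 90 % of the
60 x 60 cm arena at 3 cm bins — the session-inclusion rule applied to
recorded data — with realised speed within 20 % of nominal.

Tuning models are standard forms: Gaussian place fields (sigma 8 cm,
peak 5 Hz, baseline 0.1 Hz), rectified three-cosine grids (spacing
35 cm), von Mises head-direction tuning (kappa 4), exponential
wall-distance border tuning (sigma 6 cm), constant nonspatial rate.
Spikes are drawn by thinning an inhomogeneous Poisson process against
the maximum rate along the track (with a 5 % margin for between-sample
interpolation) — chosen over time-rescaling for its simpler correctness
argument. Burst trains are renewal processes alternating left-truncated
exponential inter-burst intervals with fixed-ISI bursts, returning the
exact emitted burst count as ground truth.

"Lesion-condition" units are nonspatial cells rate-matched to a paired
spatial cell's mean rate along the same trajectory — firing persists,
tuning vanishes. Battery place-field centres are drawn from the central
half of the arena: a Gaussian field truncated by a wall is genuinely
ambiguous between place and border ground truth, and a labelled battery
must not contain ambiguous labels.

What the generator does *not* emulate: theta-modulated locomotion,
speed-dependent firing, conjunctive tuning, electrode drift,
cluster-cutting contamination, or inhomogeneous arena sampling biases.
Passing recovery tests therefore demonstrates that the estimators and
thresholds behave correctly under clean Poisson conditions, not that
they are robust to every pathology of tetrode data.

## Problem sizes and numerical choices

The test suite exercises: recovery and specificity on 100 cells per
spatial type plus 100 rate-matched controls (20-minute sessions);
burst-detector equivalence with a brute-force scanner on 1000 random
trains and exact ground-truth recovery on 50 generator seeds;
autocorrelogram equivalence with a scalar-accumulation oracle at 1e-10;
posterior-marginal agreement with conjugate Beta means at 1e-3; a
20-cell, 200-repetition self-downsampling control; and an 80-recording
end-to-end lesion-contrast simulation. Comparisons of floating-point
identities use 1e-12; probability grids use midpoint rules throughout so
no mass sits on region boundaries by construction.

## Known limitations

* The plug-in information estimate is upward-biased for sparse trains;
  no bias correction is applied because the classification criteria are
  conjunctive and the published criteria are stated for the plug-in
  form.
* Grid spacing/orientation need all six inner autocorrelogram peaks; in
  small arenas with large spacing they can be undefined while the score
  is still returned.
* The border score is a reproducible quantitative stand-in for what the
  source describes only qualitatively ("firing profile parallel to the
  border"); its absolute values should not be compared against other
  packages' variants.
* Coordinates assume a rectangular arena with the origin at the
  lower-left corner; circular arenas are unsupported.
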