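---
title: "Measuring the pre-mitotic nuclear-export phase of cyclin B"
author: "nucexport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the pre-mitotic nuclear-export phase of cyclin B}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In fission yeast, the mitotic cyclin Cdc13 is enriched in the nucleus
through interphase. Shortly before mitosis a fraction of the nuclear
pool relocates to the cytoplasm; this export phase begins together with
the enrichment of the polo kinase Plo1 at the spindle pole bodies
(SPBs), ends abruptly at SPB separation, and is followed at anaphase by
cyclin degradation. The phase is transient (minutes) and only visible
in single cells: in population averages that are not aligned to a
common mitotic event it washes out entirely.

`nucexport` implements the quantification needed to time this phase
from fluorescence time-lapse movies: compartment segmentation,
concentration and amount decomposition, event-aligned ensemble
averaging, and change-point estimation of when export starts and
stops. Because no raw movies are available to ship, the package also
contains a ground-truth simulator and movie renderer, so every stage
can be validated against known truth and the whole pipeline can be
exercised end to end without any download.

## The kinetic model behind the simulator

The generator is the single source of truth for the event structure.
Per cell, with anaphase as the reference:

* export onset: `export_onset_offset` = 15 min before anaphase,
* SPB separation (export stop): `spb_separation_offset` = 7 min before
  anaphase,
* Plo1 enrichment onset: `plo1_onset_offset` = 8 min before SPB
  separation (so it coincides with export onset under the defaults),
* degradation onset: at anaphase (`degradation_onset_offset` = 0,
  configurable because the event is only approximately placed),
* division: `post_anaphase_duration` = 20 min after anaphase.

Compartment amounts (nucleus `N`, cytoplasm `C`, SPB focus `S`, in
arbitrary units that the renderer maps 1:1 to expected photon counts)
follow an ODE with logistic smooth switches. Each switch has a 10-90%
width `transition_width` (default 0.5 min, so that each switch runs
its course in under a minute):

* synthesis at `synthesis_rate` (default 700 a.u./min), split between
  nucleus and cytoplasm in their interphase proportions
  (`nuclear_fraction`, default 0.30), and stopping at degradation
  onset;
* a *constant* export flux during the export window, sized so that
  `export_fraction` (default 0.4) of the nuclear amount present at
  onset moves to the cytoplasm by SPB separation. A constant flux
  makes the nuclear trace fall linearly between two sharp corners,
  which is the shape observed traces show; a first-order alternative
  was rejected because its exponential curvature is absorbed by any
  corner estimator as spurious transition width;
* first-order degradation of all compartments after degradation onset
  (`degradation_halflife` = 3 min);
* for focus-forming species, first-order binding to a finite pool of
  SPB sites: `dS/dt = spb_rate (1 - S/spb_max)` after Plo1 onset
  (defaults 400 a.u./min and 1600 a.u., i.e. a 4-min rise
  time-constant, consistent with reported few-minute enrichment
  timescales).

Species variants re-use this machinery: `cdc2` exports without
degradation, `cut2` (securin-like) keeps a flat N/C ratio until SPB
separation and then imports, `mad3` is flat throughout, `plo1` forms
the SPB focus, `cdc13_NLS_KK` halves the nuclear fraction but keeps
the export window, and `cdc13_1_177_OE` scales synthesis 20-fold.
Total amount equals `N + C + S` identically (conservation is by
construction, tested to 1e-9), and the open question of whether the
flux is true export or reduced import is deliberately left
unresolved: the model implements a net flux.

Cell geometry is a rod (capsule) elongating at `growth_rate` = 0.06
um/min from its birth length, frozen from SPB separation to division;
cycle length is an affine function of birth length with negative slope
(`c(intercept = 220, slope = -12)` min), which builds size homeostasis
into every sampled population. Cell-to-cell variability is
multiplicative Gaussian jitter with per-parameter CVs (4-10%);
invalid draws (e.g. an export onset not preceding SPB separation) are
rejected and redrawn. One master seed yields counter-derived per-cell
substreams, so populations are order-independent.

## What the renderer emulates, and what it does not

Frames are projected 2-D images: the nucleus is a disc (splitting into
two discs at anaphase), compartment concentrations are uniform
per-pixel shares (amount / pixel count, so compartment pixel sums equal
amounts exactly before noise), SPB foci are sub-pixel point
depositions, and every channel is blurred with a Gaussian PSF
(`psf_sigma` = 1 px), scaled, offset by `background_level` = 100
counts, and corrupted with Poisson noise plus Gaussian read noise (SD
2 counts). Convolution uses circular boundaries, so integrated flux
over the field is conserved exactly. Channels: a cell-interior
"outline" proxy standing in for brightfield-based cell segmentation, a
nuclear marker (NLS-tagged red fluorophore in the real experiments), a
reporter channel, and an optional Plo1 focus channel. Pixel size
defaults to 0.11 um (plausible for a high-NA 60x objective; the real
optics are not published, so these are declared defaults, not derived
values). Frame intervals of 5 min, 3 min and 15 s cover the three
acquisition regimes; the timing analyses use 15 s.

Deliberately not emulated: 3-D structure (the real acquisition
integrates over the optical axis, which justifies areal
concentrations), deconvolution, autofluorescence (uncorrected in the
real quantification too, so concentrations are slightly overestimated
there; the generator can inject it to study the effect), nucleolar
exclusion structure inside the nucleus, cell crowding or touching
cells, stage drift, and photobleaching. Passing tests therefore show
correctness of the *quantification* given imaging of this character;
they cannot certify segmentation robustness against debris, dense
fields or focus drift in real movies.

## Segmentation and measurement rules

Nuclei: Gaussian blur (default 1.5 px) then a global Otsu threshold,
hole filling and connected labeling. Otsu is computed on a 256-bin
histogram of the min-max-scaled image; between-class variance ties are
broken toward the lower cut, and the test suite holds the
implementation equal to a brute-force search over all cut points.
Cells: the same operators on the outline channel (blur 1 px, minimum
area 200 px), with an optional watershed split for touching cells and a
truth-mask passthrough mode so downstream stages can be tested
independently of segmentation quality. Cells touching the image border
are removed. Each nucleus is assigned to the cell under its centroid;
post-anaphase, both daughter nuclei of a cell are retained and summed
for nuclear measurements.

Measurements per cell and frame, after subtracting a per-frame
background `b` (mean of automatically placed off-cell ROIs; per frame
rather than per movie so illumination drift would be tracked):

* `I_cell`, `I_nuc`: background-subtracted integrated intensities;
  `A_cell`, `A_nuc`: areas in px^2;
* cytoplasm by subtraction: `I_cyt = I_cell - I_nuc`,
  `A_cyt = A_cell - A_nuc`, `c_cyt = I_cyt / A_cyt`;
* concentrations are integrated signal per area; the N/C ratio is
  `c_nuc / c_cyt`, and cross-strain comparisons divide by the mean
  wild-type ratio of the same experiment;
* `topk_mean`: mean of the k = 40 brightest in-cell pixels, the proxy
  used for nuclear or SPB-focus concentration when no nuclear marker
  exists; decreasing k can only increase it (tested);
* the two-ROI cytoplasmic mean places two disc ROIs on the long axis
  flanking the nucleus, repositioning once if an ROI touches the
  nucleus.

Whole-cell integrals include SPB focus pixels (they are inside the
cell mask); this matches the subtraction-based bookkeeping and is
documented rather than corrected. Traces are smoothed with loess
(degree 2, tricube weights, span 0.3, exact "direct" fit); min-max
normalization per cell cycle maps each trace onto [0, 1].

## Event detection and alignment

* Anaphase: first frame at which a cell's assigned nucleus count goes
  from 1 to 2 and stays there for at least 2 frames (single-frame
  splits are noise). Nuclear separation and sister-chromatid
  separation are treated as the same anchor: the generator places them
  at the same truth time, a documented simplification.
* SPB separation: per frame, up to two foci are detected inside the
  cell as 8-neighborhood local maxima above `median + 6 MAD` of the
  matched-filtered (1 px Gaussian) in-cell intensities; separation is
  the first frame with two foci more than 3 px apart persisting 2
  frames.
* Plo1 onset: the loess-smoothed top-40 trace must exceed its
  baseline mean + 4 SD (baseline = earliest quartile of the smoothed
  trace) for at least 3 frames. Using the smoothed baseline keeps the
  threshold tight; with the raw baseline the detector lags the true
  onset by over a minute at this amplitude.

Aligned ensembles shift each cell so its anchor is 0 and snap to the
acquisition grid; cells are never interpolated across frames, so all
pooled traces must share one interval. The mean is reported wherever a
cell contributes; the SD is the sample SD for n >= 2 and 0 for a
single cell, with per-point n exposed so consumers can restrict to
n >= 2.

## Change-point estimation

The published timings are read qualitatively off plotted traces; this
package formalizes them — the central design decision of the repo. The
estimator is a continuous piecewise-linear least-squares fit with
breakpoints restricted to observed frame times and found by exhaustive
search (the normal equations are assembled from suffix sums, so each
candidate costs O(1) beyond a fixed 4x4 solve; for traces of <= 60
frames the test suite verifies the returned RSS against full
enumeration). Ties break toward earlier breakpoints. The export window
uses a 2-breakpoint fit on the loess-smoothed pre-anaphase 25 min of
the nuclear concentration trace — fitting only up to anaphase excludes
the degradation phase by construction — and requires the middle
segment to fall faster than both flanking segments; cells violating
this (e.g. non-exporting species) are flagged and excluded from
ensemble summaries rather than silently dropped.

Transition sharpness is the 10-90% width of a local logistic blend of
the two adjoining segments, fitted to the raw trace within +/- 3 min
of the breakpoint. The blend acts on the *slope* (the fitted curve is
`c + s1 t + (s2 - s1) tau softplus((t - b)/tau)`, width `2 log(9)
tau`), which matches the integrated-flux corner exactly: on noise-free
traces the generator's 0.5-min width is recovered to machine accuracy,
and a hard corner collapses to ~0. A value-space blend of the two
lines was rejected because it cannot represent a slope corner and
produced widths biased in both directions. The linear coefficients are
profiled out by least squares (variable projection), leaving a 2-D
Nelder-Mead search over `(b, log tau)` from three width starts.

## Population statistics

Cycle length is division-to-division time; lengths are read at the
birth frame and the last frame before division; incomplete cycles are
excluded and counted. Group comparisons use the Wilcoxon rank sum test
with continuity correction (the approximate test, matching the named R
test; exact enumeration is available for n <= 10 and serves as the
oracle in the suite). The size-homeostasis fit is ordinary least
squares of cycle length on birth length with the product-moment
Pearson R. Box summaries use type-7 (linear interpolation) quantiles —
the convention is fixed here because the source material does not
state one — with whiskers at the most extreme data points within 1.5
IQR of the quartiles.

## Numerical choices and degenerate inputs

* Constant images: Otsu warns and returns an empty map; constant
  traces are an error for min-max normalization and the piecewise fit.
* Loess spans too small for a local quadratic reduce to degree 1 with
  a warning and a widened span floor.
* Negative background-corrected integrals clamp at 0 with a flag;
  `c_cyt` is missing (not an error) when `A_cyt = 0`.
* Event detectors return missing values, with machine-readable warning
  records, when their persistence rules are never met.
* ODE integration uses `lsoda` at rtol/atol 1e-8 on a 0.05-min dense
  grid, cross-checked in the tests against an independent fixed-step
  RK4 oracle at a 100x finer step (1% tolerance).
* All randomness flows from one master seed through counter-derived
  substreams (cells, frames, channels), so rendering is reproducible
  and order-independent; analysis is RNG-free.

## Problem sizes used by the tests

The acceptance-style checks simulate 30 cells at 15 s intervals over
30 min (anaphases placed 26-28.5 min in, so each cell carries the full
25-min pre-anaphase fit window), run the full pipeline, and compare
ensemble medians to the calibrated truth: onset 15 min and stop 7 min
before anaphase (+/- 1 min), Plo1 onset leading SPB separation by 8
min (+/- 1 min), and onset transition width under 1 min. Simulation
studies use 200 noisy traces for breakpoint RMSE and a 3x3 grid of
onset/stop combinations at 50 traces each for recovery error; these
sizes are the package's chosen balance between statistical resolution
and a test suite that stays pleasant to run.

## Known limitations

Beyond the renderer simplifications above: the tracker is greedy
overlap linking, adequate for non-motile rod cells but not for dense
or fast-moving fields; detection thresholds (m = 6, q = 4, d_min = 3
px, persistence 2-3 frames) are defaults tuned to the synthetic SNR
regime and should be revisited for other optics; the transition-width
estimator assumes two locally linear regimes around each breakpoint;
and the Plo1-onset detector inherits a small positive lag (fractions
of a minute) because a threshold rule can only fire once signal has
accumulated. The per-cell export-window estimator needs the full
25-min pre-anaphase window at the 15 s interval; at 5-min sampling
only ensemble-level statements are meaningful.
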