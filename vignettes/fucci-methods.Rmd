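---
title: "Methods: FUCCI cell-cycle quantification in fuccicycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FUCCI cell-cycle quantification in fuccicycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuccicycle)
```

## The measurement problem

Dual-color FUCCI reporters read out cell-cycle position in live cells:
mCherry-hCdt1 is high in G0/G1 and degraded at S entry, mVenus-hGeminin is
high through S/G2/M and destroyed at the metaphase–anaphase transition, and
both overlap briefly at G1/S. In cardiomyocytes, the interesting question is
not just *whether* a cell cycles but *how the cycle ends*: cytokinesis
(division), karyokinesis without cytokinesis (binucleation), or no mitosis
at all (endoreplication, yielding a polyploid nucleus). These outcomes have
distinct FUCCI signatures in time-lapse data, and distinct consequences for
regeneration.

`fuccicycle` implements four analyses over this readout — snapshot state
classification, single-cell trace fate calling, plate-screen scoring, and
DNA-content ploidy analysis — plus a synthetic-data generator that emulates
all of the corresponding inputs with ground truth attached. The generator is
first-class, tested code: every pipeline stage is validated by recovering
what the generator put in.

## The kinetic trace model

Reporter kinetics are modelled piecewise (`generate_trace`). The published
traces show characteristic *patterns*, not parametric curves, so the model
is the simplest shape family that reproduces all three cycling signatures:

- **G1**: mCherry at its plateau, mVenus at background.
- **G1/S overlap** (`onset_overlap_h`, default 2 h): mCherry declines
  linearly to background while mVenus rises linearly to its plateau — the
  YELLOW window where both reporters exceed threshold.
- **S/G2(/M)**: mVenus plateau.
- **Exit, fate-specific**:
  - *division / binucleation*: a linear mVenus collapse over
    `sharp_drop_h` (default 0.5 h) — anaphase-promoting-complex-driven
    geminin destruction at mitosis — followed by mCherry re-accumulation in
    the daughters. The two fates are kinetically identical; they differ
    only in the post-mitosis daughter-object annotation (`"2-separate"`
    vs. `"2-same-cell"`), mirroring the fact that only watching the movie
    (or a tracking stage) can tell them apart.
  - *polyploidization*: no mitosis. mVenus decays exponentially with time
    constant `slow_decay_tau_h` (default 8 h) and mCherry re-accumulates
    *before* mVenus is lost — the G2-arrest signature.
- **Non-cycling**: mVenus stays at background for the whole movie.

Phase durations are log-normal with configured mean and CV (strictly
positive, right-skewed, two parameters). Defaults encode the study
conditions: 20-min sampling over 72 h, and mean S/G2(/M) durations of
16.38 h (division), 17.29 h (binucleation), and 24.5 h (polyploidization).
`duration_cv = 0.15` sits mid-range of the per-fate spreads implied by the
reported standard errors (~0.10–0.25). The G1 duration has no reference
measurement in this system; its default (12 h) is a free parameter chosen so
that onset plus the longest S/G2 duration comfortably fits the 72-h movie,
and it is not used by any acceptance check. Noise is multiplicative Gaussian
on the signal plus an additive component scaled by the background level
(`noise_sd_frac`, default 0.1); traces are *not* floored at zero, because
background-subtracted intensities are legitimately negative under noise and
flooring would distort the noise floor estimate below.

The generator records its ground-truth boundary times at the 20%-of-peak
crossing convention. This matches the default classifier configuration but
is a generator constant: truth never depends on the analysis configuration.

## Trace classification rules

`detect_phase_boundaries` median-filters each channel (3-point window:
removes single-frame spikes without moving a crossing by more than one
interval) and then works entirely in units of the trace's own mVenus peak,
which makes classification invariant to uniform intensity rescaling:

- **Cycling vs. non-cycling**: a trace is cycling only if its smoothed peak
  exceeds `noise_floor_mult` (default 10) times the noise level. The noise
  level is estimated as `mad(diff(raw))/√2` — first differences cancel the
  slow reporter kinetics, so a long G2-arrest decay does not inflate the
  estimate, and the raw (unsmoothed) series keeps the differenced noise
  i.i.d. For pure noise the peak is ~3σ, an order of magnitude below the
  cut; for real signals it is ~100σ at 10% noise.
- **Onset / offset**: first upward crossing of `onset_frac·peak` and last
  downward crossing of `offset_frac·peak` after the peak (defaults 0.2),
  linearly interpolated between frames. The reference "peak" is the median
  of the smoothed values within 80% of the maximum — a plateau estimate —
  because the raw maximum is biased upward by noise extremes, which would
  otherwise shift the offset of a slow exponential decay early by
  `τ·log(peak_max/peak_plateau)` (~0.8 h at 10% noise).
- **Sharp vs. slow exit**: `drop_sharpness_h` is the time from the last
  half-peak crossing to the offset. A linear collapse over 0.5 h gives
  ~0.15 h; an exponential decay gives `τ·log(2.5)` ≈ 7.3 h at τ = 8 h. The
  cuts (`sharp_drop_max_h = 1 h`, `slow_decay_min_h = 5 h`) sit well apart
  from both; no quantitative criterion is published for this contrast, so
  both are declared configuration, not reference values.
- **Fate**: no onset → non-cycling; sharpness ≥ `slow_decay_min_h`, or
  mCherry re-entry before the offset without a sharp drop →
  polyploidization; otherwise mitotic, split by the daughter annotation,
  and `"mitotic-unresolved"` when the annotation is missing or the offset
  is censored by the movie end. Returning an explicit unresolved value is
  deliberate: intensities alone cannot separate division from binucleation,
  and guessing would silently corrupt downstream fractions.

S/G2(/M) duration is offset − onset. On noiseless traces this matches the
configured duration within one sampling interval; at 10% noise the
estimator is unbiased to well within the sampling interval and fate
accuracy on balanced 1000-trace cohorts is ≥ 95% (in practice ~100%).

## Snapshot classification and thresholds

`derive_channel_threshold` offers Otsu's criterion on `log1p` intensities
(default; robust for skewed fluorescence histograms with an empty gap
between background and positive modes) and a two-component Gaussian mixture
(`mclust`, variance prior for stability) with the threshold at the
equal-likelihood boundary. If the fitted components are not separated by at
least twice the pooled SD the channel is treated as unimodal and the method
falls back to Otsu with a warning — a two-component fit on a unimodal or
zero-inflated histogram otherwise places an arbitrary boundary inside the
background. Positivity is strict (`> thr`); values exactly at threshold are
negative. This tie rule, like every other in the package, is deterministic.

The screen's main parameter counts YELLOW (double-positive) nuclei as
mVenus-positive by default (`include_yellow = TRUE`): they are
mVenus-positive by the state truth table. Whether the original screen
counted them is not documented, so the switch is exposed.

## Segmentation and intensity measurement

Nuclei are segmented from the DNA channel (EBImage): adaptive local-mean
thresholding (default; tolerates uneven illumination) or global Otsu, hole
filling, connected-component labelling, an area filter
(`min_area_px`–`max_area_px`), and an optional distance-transform watershed
for touching nuclei (off by default; the synthetic fixtures enforce
non-overlap, so the verification surface does not exercise it).
Coordinates are 0-based (row, col).

Background subtraction offers a local annulus (default: mean intensity in a
ring 3 px beyond each nucleus, excluding all nuclei — an automatable
equivalent of drawing a region around the cell) and a global 5th-percentile
mode. Measured intensities are floored at 0, as required before state
classification. Sarcomere spacing is the median inter-peak distance of a
line profile (peaks = local maxima with prominence ≥ 10% of range); the
reference description of this measurement conflates "amplitude" and
"spacing", and inter-peak *distance* is the interpretation implemented.

## Screen scoring

Site QC excludes sites with nucleus counts more than 2 sample SDs *below*
their plate × timepoint group mean (one-sided: only low counts indicate
acquisition failure); groups smaller than 3 are skipped with a warning. The
averaging group (plate × timepoint rather than whole run) is a declared
choice — the procedure's description does not specify it, and per-plate
grouping protects against plate effects. Wells aggregate retained sites by
summed counts (unbiased under unequal site populations; a `mean-of-sites`
switch restores the literal per-site-average reading, and the two agree
exactly on homogeneous sites). Normalization divides by the mean control
main parameter of the same plate and timepoint (control wells average to
100% per plate by construction). Treatment QC excludes a compound ×
timepoint when the replicate SD exceeds half the mean (equality retains);
sample SD (n−1) is used throughout. Timepoint selection minimizes the
control CV with ties to the earlier timepoint; ranking is by mean
normalized value, then lower SD, then compound id.

The plate generator reproduces the screen geometry: 96 wells with the outer
ring unused, 54 compounds + 6 interleaved `CTRL` wells on the 60 inner
wells, 5 sites per well, triplicate plates sharing the layout, acquisitions
at 0/24/48/72 h. A compound's true effect multiplies the cycling probability
P(mVenus+ | FUCCI+) from 24 h on (the baseline acquisition directly after
compound addition is unaffected). Site counts are Poisson (mean 150 per
site, matching a binned 10× field of a ~4000-cell well); dropout sites are
Poisson at 5% of the mean. Notably, pure counting noise at these settings
already yields control CVs of ~10–13%, the order observed in real screens,
so no extra overdispersion term is added.

## Ploidy analysis

Gated nuclei are marker-positive (cardiomyocyte identity) and, for the
non-cycling analysis, Ki-67-negative. Both thresholds are derived from the
*full* record set before any gating, so gate order is irrelevant. A channel
whose log-histogram shows no separable second mode (Otsu separation score
< 3; a unimodal distribution split at its body scores ~2.6) is treated as
uninformative and gates nothing — an all-positive and an all-negative
population are indistinguishable from the histogram alone, so the honest
automatic behavior is no gating, and explicit thresholds can always be
supplied.

DNA content uses integrated (summed) nuclear intensity in the generator's
convention, since integrated intensity tracks DNA content under varying
nuclear area. Thresholds come from a kernel density estimate of log
intensity (Silverman's rule-of-thumb bandwidth): the dominant mode is the 2N
reference, boundaries sit at density minima between successive modes, and
where a minimum is absent (a class missing or unresolved) the fallback is
the geometric midpoint of the class centers (√2 and 2√2 times the 2N mode).
Working on the log scale makes the whole chain exactly scale-equivariant —
multiplying all intensities by k multiplies thresholds by k and leaves every
class call unchanged. Boundary ties fall to the lower class. 8N+ is
open-ended.

## What the synthetic data do and do not emulate

The generators reproduce the *statistical* structure the analyses assume:
fate mixtures and duration distributions, reporter on/off kinetics,
snapshot state fractions, plate layout with replicate structure, site
dropout, and log-normal DNA-content mixtures with 1:2:4 means. They do not
simulate optics (no point-spread function, no photobleaching), cell
migration or track breaking, segmentation-confounding nuclear shapes
(nuclei are discs with enforced non-overlap), or biological well-to-well
heterogeneity beyond counting noise. Passing recovery tests therefore
demonstrates that the analysis rules are implemented correctly and are
unbiased under the stated noise model — not that segmentation or tracking
would be robust on arbitrary real microscopy data.

## Problem sizes and numerical choices

The validation suite uses desk-scale problems chosen to make sampling error
small relative to the tolerances: 570-trace cohorts for fraction recovery
(the size of the tracked-cell study), 100 traces per fate for duration
recovery, 2,000 rendered nuclei (8 sites × 250 at 640×480) for snapshot
recovery, 100-site plates for QC checks, 100 seeded simulations for ranking
power, and 5,000-nucleus populations for ploidy. All generators and both
umbrella workflows (`run_trace_study`, `run_screen_study`) are deterministic
given their seed; substreams are derived from the top-level seed by a
counter/tag hash so that stages never share a stream.

Degenerate inputs are handled explicitly rather than by accident: all-zero
images segment to an empty result; zero FUCCI-positive wells yield an `NA`
main parameter with a QC flag; empty gates and empty control sets raise
errors naming the offending step; mitotic traces without annotations are
`"mitotic-unresolved"`.

## Known limitations

- Division vs. binucleation requires the daughter annotation; there is no
  image-based tracking stage.
- The G1 duration default is a modelling convenience, not a measured value.
- The sharp/slow exit cuts are configuration; cohorts whose true decay
  constants approach the mitotic collapse time would need them re-declared.
- Threshold derivation assumes a background mode plus at most one positive
  mode per channel; multi-population channels need explicit thresholds.
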