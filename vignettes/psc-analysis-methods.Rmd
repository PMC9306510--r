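---
title: "Methods: simulating and analysing spontaneous postsynaptic currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing spontaneous postsynaptic currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psckit)
```

## Scope

`psckit` implements an analysis chain for spontaneous and miniature
postsynaptic currents (PSCs) recorded in whole-cell voltage clamp:

1. a synthetic recording generator with per-event ground truth;
2. event detection by sliding template correlation;
3. per-event kinetic measurement and artifact filtering;
4. a data-driven rise-time cutoff separating fast (perisomatic) from slow
   (dendritic) events, with fast/slow contingency tables;
5. event-count-equalized two-group statistics (Kolmogorov–Smirnov on pooled
   distributions, Mann–Whitney on cell averages, Fisher's exact test on
   fast/slow proportions);
6. relative-optical-density (ROD) quantification of immunofluorescence grey
   values with hierarchical averaging and Student's *t* comparisons.

Because no laboratory recordings ship with the package, every quantitative
claim made by the test suite is made against the generator's ground truth or
against an independent brute-force oracle.

## The synthetic recording model

A recording of duration $T$ sampled at $f_s$ (default 120 s at 10 kHz) is

$$x(t) = b + \sum_k A_k\, g(t - t_k;\ \tau_r^{(k)}, \tau_d) + \eta(t),$$

where events are rendered as inward (negative) deflections — at a holding
potential of −70 mV with a high-chloride internal solution both IPSCs and
EPSCs are inward, and all downstream amplitudes are absolute magnitudes.
The kernel is a peak-normalized difference of exponentials
$g(t) = (e^{-t/\tau_d} - e^{-t/\tau_r})/g_{\max}$, so a rendered event's
peak excursion equals its nominal amplitude exactly (the contract the
measurement stage is tested against).

Event times are a homogeneous Poisson process per cell. Each event belongs
to the *fast* population with probability `fast_fraction` and draws its
20–80 % rise time from a log-normal around the population mean (defaults
1 ms fast, 3 ms slow, CV 0.25); the rise constant $\tau_r$ is obtained by
numerically inverting the kernel's continuous 20–80 % rise time (a cached
monotone spline accurate to ~10⁻⁶ ms). The biexponential family has a
finite maximum rise for a given decay constant (the alpha-kernel limit), so
the log-normal tail is capped there (≈ 4.7 ms at $\tau_d$ = 12 ms).
Amplitudes are log-normal (CV 0.5) with the fast population's mean 1.5×
the slow one's, reproducing the association between fast kinetics and
large amplitudes that perisomatic events show.

Noise is Gaussian white noise passed through a 4-pole low-pass Butterworth
at 3 kHz, emulating an acquisition anti-aliasing filter. The filter is
applied forward–backward (zero phase): a causal filter would add a kinetic
distortion (rise-time stretching and onset delay) that the analysis would
then have to undo; zero-phase filtering keeps the generator's declared
kinetics the measurable truth. With `noise_sd` = 1.5 pA the post-filter
noise SD is ≈ 1.1 pA, placing a 10 pA event near SNR 9.

Default condition parameters follow the two-arm slice-incubation design:
vehicle rate 3.717 events/s, treated arm multiplied by 5.143/3.717 ≈ 1.38;
vehicle fast fraction 0.60, treated 0.70; 8 vehicle vs 9 treated cells.
Cell-to-cell rate variability is log-normal with CV 0.35, the scale implied
by the group SEMs (SEM × √n ≈ 1.4–1.5 events/s on means of 3.7–5.1).
Recording duration per cell is not fixed by the design; 120 s is the
package default, and the demonstration configuration uses 300 s so that
typical cells accumulate comfortably more than the 545 accepted events the
equalization step requires.

Per-cell rate deviates are keyed by cell *index*, not by arm, so matching
cells across arms share their deviate and the arms differ exactly by the
rate multiplier (common random numbers). With multiplier 1 the arms are
exchangeable by construction, which is what the null calibration of the
downstream statistics requires; with independent per-arm draws at CV 0.35,
two 8–9-cell arms differ in pooled IEI distribution by D ≈ 0.06 on average
purely through cell sampling, and the pooled K-S comparison would flag
"effects" in almost half of null runs — a known pathology of pooled
(pseudoreplicated) distribution tests, not a property of the method under
study.

What the generator does **not** emulate: series-resistance and seal drift,
electrode artifacts, non-stationary rates, correlated (bursty) event
timing, dendritic filtering beyond the rise-time surrogate, and any
postsynaptic receptor kinetics. Passing tests therefore demonstrate
correctness of the analysis chain under the declared statistical structure,
not robustness to every property of real recordings.

## Detection by template correlation

For every window start the Pearson correlation between the trace window and
a biexponential template is computed (FFT cross-correlation plus rolling
sums, O(n log n)); windows that are affine copies of the template score
exactly 1, so detection is invariant to baseline offsets and amplitude
scaling. Zero-variance windows score 0 by convention. Candidate onsets are
local maxima of the correlation series above the threshold (0.6).

Three numerical choices matter and deviate from the naive formulation:

* **Correlation window.** The template spans 6 decay constants (72 ms) so
  that it captures the full waveform, but the *correlation window* is only
  its first 8–14 ms (rise plus early decay). At physiological rates the
  72 ms window spans several interevent intervals, and a larger neighbour
  inside the window dominates its variance and masks the event at the
  window start: with full-length windows, recall at 4 events/s saturates
  near 0.75 regardless of SNR.
* **Two templates.** Recordings contain two kinetically distinct
  populations, and a single template under-detects whichever population it
  matches worse (slow events correlate below 0.6 with a fast template under
  noise). Detection runs once with a fast-rise (τ_r 0.8 ms, 8 ms window)
  and once with a slow-rise (τ_r 2.8 ms, 14 ms window) template and merges
  the detections, keeping the higher correlation within the refractory
  span. Per-recording templates can instead be fitted from averaged
  detected events (`fit_template_from_events()`).
* **Within-window detrending.** The correlation is computed as a partial
  correlation controlling for a linear trend inside the window: an event
  riding on a neighbour's decay tail sees a locally linear baseline, and
  plain correlation misses a large fraction of such events. Detrending
  raises the detection-rate accuracy at study conditions from ≈ −5 % to
  ≈ −1 % bias.

Detected onsets are refined on the raw waveform: the 20–80 % rising chord
is extrapolated back to baseline (onset ≈ t₂₀ − rise/3; exact on the
continuous kernel to within 0.5 ms across the rise range). Refinement
windows are capped at the next candidate so small events do not lock onto
a larger neighbour's rising edge; candidates that refine onto the same
onset are collapsed by the 2 ms refractory rule. Splitting suprathreshold
regions at every interior local minimum (rather than requiring a minimum
dip) and letting refinement collapse duplicates keeps the detection count
monotone in the threshold.

## Kinetic measurement and filters

Per event: baseline = median of the 5 ms preceding the onset; amplitude =
maximal absolute deviation within a 12 ms peak-search window (the kernel
peak lags the onset by at most a few ms even for the slowest rises —
searching the whole 72 ms window would let late noise excursions inflate
amplitudes); 20–80 % rise time and halfwidth from linearly interpolated
level crossings. Crossing times are the *mean* of all interpolated
crossings of a level on the relevant segment: on a noise-free monotone rise
this is the single exact crossing, while under noise the first or last
crossing is systematically early or late (taking the last sub-80 %
crossing biases rise times up by 1–3 ms at moderate noise). The
measurement window is capped at the next detection's onset; events whose
peak sits at a window edge or that never decay below half amplitude inside
the window are flagged truncated.

Acceptance requires, in this order: correlation > 0.6, amplitude > 3 pA
(amplifier noise floor), 20–80 % rise < 5 ms, halfwidth > rise time;
the rejection reason records the first failed criterion and truncated
events are rejected outright. The accepted-event frequency (count/duration)
therefore deliberately undercounts the underlying rate by the filter's
rejection fraction; `summarize_cells()` reports the raw detection rate
alongside, which is the estimator of the underlying event rate (misses and
false positives roughly balance; bias ≈ 1 % at study conditions).

## Fast/slow cutoff selection

For cutoff candidates $\tau_c = k\,\delta\tau$ ($\delta\tau$ = 0.1 ms, the
sampling resolution; rise times are re-quantized to this grid first), each
group's smoothed count ratio is

$$r_{s:f}(\tau_c) = \frac{n(\tau > \tau_c) + 1}{n(\tau \le \tau_c) + 1},$$

monotone non-increasing with a spike at the start of the range. Its
derivative is assessed on a logarithmic scale,
$\delta r_{s:f}/(\ln 10 \cdot r_{s:f}\cdot\delta\tau)
= \delta\log_{10} r_{s:f}/\delta\tau$, i.e. the slope of the log-scaled
ratio curve. This reading matters: for two groups that differ in their
fast fraction the log-slope curves genuinely cross inside the between-mode
valley (at the simulator's defaults the continuous-mixture crossing is at
≈ 1.8 ms), whereas a derivative additionally divided by $r_{s:f}$ never
crosses and no cutoff would exist.

The selected cutoff is the smallest grid point that is simultaneously

* past the initial ratio spike ($r_{s:f} < 0.5\,\max r_{s:f}$ in both
  groups);
* *populated*: at least 5 % of each sample lies at or below and at least
  5 % above the candidate — in an empty tail the ratio is locally flat
  simply because no events live there, and the equality criterion would be
  satisfied trivially while splitting nothing;
* *locally stable*: each group's |log-slope| is within a factor 2 of its
  minimum over the admissible range — during the initial descent both
  groups' derivatives are large and near-proportional, so equality alone
  fires long before the valley; the valley floor is where the log curve is
  flattest;
* *approximately equal between groups*: relative derivative difference
  ≤ 10 % (with an absolute floor of 10⁻⁶), or a sign change of the
  difference between neighbouring grid points (a sign change brackets exact
  equality even when no single grid point is within tolerance).

Derivatives are compared after a 5-bin (0.5 ms) running mean of
$\log_{10} r_{s:f}$: raw per-bin finite differences on count data are too
noisy for any pointwise comparison. `log_derivative()` itself returns the
unsmoothed grid derivative.

On samples whose pooled rise-time histogram shows no bimodality (smoothed
histogram with fewer than two well-separated peaks) the selection is
flagged low-confidence or raises, never silently returning a
mode-splitting value. At the defaults the selected cutoff falls at
1.5–2.0 ms for every sample size tried (500–4000 events per group);
boundary events with rise time exactly $\tau_c$ count as fast.

## Group statistics

Pooled-distribution comparisons (IEI, amplitude, rise time) equalize the
number of events per cell first, so that no high-frequency cell dominates
the pooled ECDF. Equalization keeps each cell's **first** *n* accepted
events. A uniform random subsample without replacement — the other obvious
choice — thins each cell's Poisson process to exactly
$n/T$ events per second and thereby *erases* the between-group frequency
signal the IEI comparison exists to detect; a contiguous prefix preserves
the interevent-interval distribution (it is equivalent to truncating the
recording). The random method remains available (`method = "random"`,
seeded and reproducible) and is unproblematic for amplitude and kinetics.

The battery: two-sample Kolmogorov–Smirnov on pooled distributions with the
dual significance criterion *p* < .01 **and** D > .05; Mann–Whitney on
cell averages (*p* < .05), exact by enumeration for tie-free samples up to
n₁+n₂ = 12, otherwise normal approximation with tie correction; Fisher's
exact test (two-sided by hypergeometric probability summation) on the
fast/slow counts at the selected cutoff (*p* < .05). All tests are
two-sided; no multiple-testing correction is applied (comparisons are
reported individually). The implementations delegate to R's `ks.test`,
`wilcox.test`, `fisher.test` and are verified in the test suite against
independent brute-force oracles: a pooled-support ECDF sweep, full
enumeration of rank assignments, and hypergeometric summation.

Calibration at the defaults (ground-truth event tables, no detector): under
the paired null the K-S comparisons flag in ≤ 4 % of 100 runs and each
test's type-I rate is at or below its nominal level; under the 1.38 rate
multiplier the IEI K-S comparison flags in essentially every run with mean
D ≈ 0.12. Note that the familywise rate across all seven uncorrected tests
is necessarily above any single nominal level.

## Densitometry

Grey values (8-bit) are converted to relative optical densities after
background subtraction, $\mathrm{ROD} = \log_{10}(256/(255 - g))$;
a background-subtracted value of 255 saturates the formula and raises,
negative values are clamped to zero with a warning (or rejected). The
background is subtracted from the grey value *before* conversion, matching
the stated order of operations. Averaging follows the sampling hierarchy —
cryotome sections within a vibratome section, vibratome sections within a
mouse — so group statistics are computed on one value per mouse (n = 4 per
arm in the reference design); unbalanced branches average over available
children. Group comparison uses the equal-variance Student's *t* test
(two-sided, α = .05); degenerate zero-variance inputs return p = 1
(identical groups) or p = 0 (perfectly separated constants). Percentages
of control are rounded half-up to integers; with the published CA3 stratum
oriens means, 0.125/0.164 → 76 %.

## Reproducibility and problem sizes

All randomness fans out from one integer seed through a deterministic
mixing function keyed by stage name and cell index, so any stage can be
re-run in isolation and the full pipeline is bit-reproducible (the
acceptance test runs the demonstration twice and compares report bytes).
The pipeline writes a manifest with the configuration hash and every
per-cell seed.

Problem sizes used by the shipped tests are chosen to exercise each claim
at meaningful power while keeping the whole suite in the minutes range:
detector benchmarks pool four 60 s cells; frequency-recovery uses ten
120 s recordings; statistical calibration uses 100 null and 20–25 effect
cohorts on ground-truth tables; cutoff recovery uses 2000 events per
group; the demonstration pipeline is the full 17-cell, 300 s, 545-events
design.

## Known limitations

* Overlapping events closer than the 2 ms refractory span are detected as
  one; halfwidths of events whose decay is cut by a follower are reported
  as truncated rather than extrapolated.
* The cutoff-selection guards (populated fractions, stability factor,
  smoothing width) are heuristics calibrated on the generator's mixture
  geometry; data with modes much closer than a factor ~2 in rise time will
  be flagged low-confidence rather than split.
* The K-S dual criterion on pooled events is anti-conservative under
  strong cell heterogeneity (see the common-random-numbers discussion
  above); hierarchical models are out of scope.
* Trace I/O is CSV only; proprietary acquisition formats are not read.
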