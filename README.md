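# psckit

Simulation and analysis of spontaneous and miniature postsynaptic currents
(PSCs) recorded in whole-cell voltage clamp.

Electrophysiologists comparing synaptic drive between two treatment groups
typically: detect PSCs in gap-free current traces, measure each event's
amplitude and kinetics, reject artifacts, split events into fast-rising
(perisomatic) and slow-rising (dendritic) classes, and compare groups both
on pooled event distributions and on per-cell averages. `psckit` implements
that chain end to end, together with a synthetic recording generator that
provides ground truth for validating every stage, and a
relative-optical-density module for quantifying immunofluorescence grey
values.

## The core methods

* **Detection** — sliding Pearson correlation of the trace against a
  peak-normalized biexponential template
  g(t) = (e^(−t/τ_d) − e^(−t/τ_r))/g_max; candidate onsets are correlation
  maxima above r = 0.6. Events are accepted if r > 0.6, amplitude > 3 pA,
  20–80 % rise time < 5 ms and halfwidth > rise time.
* **Fast/slow classification** — for cutoff candidates τ_c on a 0.1 ms
  grid, the smoothed slower:faster count ratio
  r_s:f = (n(τ > τ_c) + 1)/(n(τ ≤ τ_c) + 1) is computed per group; the
  cutoff is the smallest τ_c, past the initial ratio spike, where the two
  groups' log-scale rates of change d log10(r_s:f)/dτ agree and the curve
  is locally stable. Counts at the cutoff feed Fisher's exact test.
* **Group statistics** — per-cell event counts are equalized (first-n),
  pooled IEI/amplitude/rise distributions are compared by two-sample
  Kolmogorov–Smirnov with the dual criterion p < .01 and D > .05, cell
  averages by Mann–Whitney, fast/slow proportions by Fisher's exact test.
* **Densitometry** — ROD = log10(256/(255 − grey)) after background
  subtraction, averaged cryotome → vibratome → mouse, compared by
  equal-variance Student's t.

## Worked example

```r
library(psckit)

# one synthetic cell: 30 s at 10 kHz, ~4 events/s, two rise-time populations
cfg <- simulation_config(duration = 30, event_rate = 4, seed = 42)
truth <- generate_event_train(cfg, cell_id = "cell1")
trace <- render_trace(truth, cfg)

det <- detect_events(trace)          # fast + slow template pair
ev  <- filter_events(measure_events(trace, det, condition = "vehicle"))
summary_tbl <- summarize_cells(ev)
summary_tbl$cells
#>   cell_id condition n_events_used frequency mean_amplitude mean_rise detection_rate
#> 1   cell1   vehicle           108       3.6       14.93114  2.266268            4.5
```

108 accepted events in 30 s give an accepted-event frequency of 3.60 /s;
the raw detection rate (4.50 /s) is the estimator of the underlying event
rate, since the acceptance filters deliberately reject truncated and
artifact-like events. Mean amplitude (14.9 pA) and mean 20–80 % rise time
(2.27 ms) reflect the generator's fast/slow mixture.

A full two-arm experiment, from simulation through the statistical report:

```r
report <- run_pipeline(demo_pipeline_config(seed = 1))
report$comparison
#> <psc_comparison> 545 events/cell equalized
#>   K-S iei        D = 0.085, p = 1.12e-12  *
#>   K-S amplitude  D = 0.035, p = 0.0148
#>   K-S rise       D = 0.066, p = 8.15e-08  *
#>   M-W frequency  U = 13, p = 0.0304  *
#>   M-W amplitude  U = 22, p = 0.194
#>   M-W rise       U = 72, p = 0.000636  *
#>   Fisher fast:slow at 1.8 ms: p = 3.92e-07  *
```

The treated arm's higher event rate shows up as a left-shifted interevent
interval distribution (K-S D = 0.085 at p < .01, flagged under the dual
criterion) and a higher cell-averaged frequency (Mann–Whitney p = .030);
its larger fast fraction shows up in the fast/slow contingency table at
the automatically selected 1.8 ms cutoff.

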