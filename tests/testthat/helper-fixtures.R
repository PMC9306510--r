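# Shared fixtures: small, fast configurations and hand-built traces.

quiet_config <- function(...) {
  args <- utils::modifyList(
    list(duration = 10, event_rate = 3, amplitude_mean = 20,
         amplitude_cv = 0.4, noise_sd = 1.5, seed = 101L),
    list(...))
  do.call(simulation_config, args)
}

# noise-free trace containing the given events (data.frame with onset_s,
# amplitude_pA, rise_ms); kernel decay 12 ms unless overridden
noise_free_trace <- function(onsets, amplitudes, rises, duration = 2,
                             decay_ms = 12, fs = 10000) {
  cfg <- simulation_config(duration = duration, sampling_rate = fs,
                           event_rate = 0, noise_sd = 0, decay_ms = decay_ms,
                           seed = 1L)
  ev <- data.frame(cell_id = "t", onset_s = onsets,
                   amplitude_pA = amplitudes,
                   population = "fast", rise_ms = rises,
                   tau_r_ms = vapply(rises, tau_r_for_rise, numeric(1),
                                     tau_d = decay_ms),
                   tau_d_ms = decay_ms)
  class(ev) <- c("psc_ground_truth", "data.frame")
  list(trace = render_trace(ev, cfg, cell_id = "t"), events = ev, config = cfg)
}

# bimodal rise-time sample mirroring the simulator's fast/slow mixture
bimodal_rises <- function(n, fast_fraction, seed,
                          fast_ms = 1, slow_ms = 3, cv = 0.25) {
  set.seed(seed)
  fast <- stats::runif(n) < fast_fraction
  m <- ifelse(fast, fast_ms, slow_ms)
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(m) - sdl^2 / 2, sdl)
}

# minimal accepted-events table for statistics tests
toy_event_table <- function(cell_ids, onset_lists, condition = "vehicle",
                            duration = 100, amplitude = 10, rise = 1.5) {
  rows <- mapply(function(cid, on) {
    data.frame(cell_id = cid, condition = condition, event_class = "sIPSC",
               onset_s = on, amplitude_pA = amplitude, rise_ms = rise,
               halfwidth_ms = rise + 5, correlation = 0.9,
               duration_s = duration)
  }, cell_ids, onset_lists, SIMPLIFY = FALSE)
  filter_events(do.call(rbind, rows))
}
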