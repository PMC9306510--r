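# Synthetic voltage-clamp recording generator.
#
# Emulates gap-free whole-cell recordings from CA1 pyramidal neurons held at
# -70 mV with a high-chloride internal solution: all PSCs are inward
# (negative) deflections, and every amplitude downstream is reported as an
# absolute magnitude. Events arrive as a homogeneous Poisson process per cell,
# each drawn from one of two rise-time populations ("fast" perisomatic ~1 ms,
# "slow" dendritic ~3 ms 20-80% rise), with log-normal amplitudes (the fast
# population larger on average) and biexponential waveforms on top of
# band-limited Gaussian noise.

#' Configuration for the synthetic PSC recording generator
#'
#' @param duration recording length per cell (s)
#' @param sampling_rate sampling rate (Hz)
#' @param event_rate mean event rate across cells (events/s)
#' @param rate_dispersion coefficient of variation of the per-cell rate
#'   (log-normal across cells; 0 disables cell-to-cell rate variability)
#' @param amplitude_mean mean amplitude of the slow population (pA)
#' @param amplitude_cv coefficient of variation of event amplitudes
#' @param fast_amp_factor ratio of fast-population to slow-population mean
#'   amplitude (fast perisomatic events are larger)
#' @param fast_fraction probability that an event belongs to the fast
#'   rise-time population
#' @param fast_rise_ms mean 20--80% rise time of the fast population (ms)
#' @param slow_rise_ms mean 20--80% rise time of the slow population (ms)
#' @param rise_cv coefficient of variation of rise times within a population
#'   (log-normal)
#' @param decay_ms decay time constant of the event kernel (ms)
#' @param noise_sd standard deviation of the white noise before low-pass
#'   filtering (pA)
#' @param noise_cutoff low-pass corner frequency of the noise filter (Hz),
#'   emulating the acquisition anti-aliasing filter
#' @param event_class label attached to generated events (sIPSC, mIPSC,
#'   sEPSC or mEPSC); a label only, it does not change the generator
#' @param seed master seed; all randomness in the generator fans out from it
#' @return an object of class `psc_sim_config`
#' @export
simulation_config <- function(duration = 120,
                              sampling_rate = 10000,
                              event_rate = 3.717,
                              rate_dispersion = 0.35,
                              amplitude_mean = 9,
                              amplitude_cv = 0.5,
                              fast_amp_factor = 1.5,
                              fast_fraction = 0.6,
                              fast_rise_ms = 1,
                              slow_rise_ms = 3,
                              rise_cv = 0.25,
                              decay_ms = 12,
                              noise_sd = 1.5,
                              noise_cutoff = 3000,
                              event_class = "sIPSC",
                              seed = 1L) {
  cfg <- list(duration = duration, sampling_rate = sampling_rate,
              event_rate = event_rate, rate_dispersion = rate_dispersion,
              amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
              fast_amp_factor = fast_amp_factor,
              fast_fraction = fast_fraction,
              fast_rise_ms = fast_rise_ms, slow_rise_ms = slow_rise_ms,
              rise_cv = rise_cv, decay_ms = decay_ms,
              noise_sd = noise_sd, noise_cutoff = noise_cutoff,
              event_class = event_class, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "psc_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.finite(cfg$duration) || cfg$duration <= 0) {
    stop("invalid configuration: duration must be > 0", call. = FALSE)
  }
  if (!is.finite(cfg$sampling_rate) || cfg$sampling_rate <= 0) {
    stop("invalid configuration: sampling_rate must be > 0", call. = FALSE)
  }
  if (cfg$event_rate < 0) {
    stop("invalid configuration: event_rate must be >= 0", call. = FALSE)
  }
  if (cfg$fast_fraction < 0 || cfg$fast_fraction > 1) {
    stop("invalid configuration: fast_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$fast_rise_ms >= cfg$slow_rise_ms) {
    stop("invalid configuration: fast_rise_ms must be < slow_rise_ms",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("invalid configuration: noise_sd must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

# log-normal parameterized by mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a ground-truth PSC event train for one cell
#'
#' Onsets follow a homogeneous Poisson process at `rate` (defaults to the
#' config's `event_rate`); each event is assigned to the fast population with
#' probability `fast_fraction`, draws a log-normal 20--80% rise time around
#' its population mean and a log-normal amplitude (fast population mean
#' `fast_amp_factor` times the slow one).
#'
#' @param config a [simulation_config()]
#' @param cell_id identifier used both as a label and in the seed fan-out
#' @param rate optional per-cell rate override (events/s)
#' @return data.frame of class `psc_ground_truth` with columns `cell_id`,
#'   `onset_s`, `amplitude_pA`, `population`, `rise_ms`, `tau_r_ms`,
#'   `tau_d_ms`
#' @export
generate_event_train <- function(config, cell_id = 1L, rate = NULL) {
  validate_sim_config(config)
  rate <- if (is.null(rate)) config$event_rate else rate
  if (rate < 0) stop("invalid configuration: rate must be >= 0", call. = FALSE)
  set.seed(fanout_seed(config$seed, "events", cell_id))
  n <- stats::rpois(1, rate * config$duration)
  if (n == 0) {
    out <- data.frame(cell_id = character(0), onset_s = numeric(0),
                      amplitude_pA = numeric(0), population = character(0),
                      rise_ms = numeric(0), tau_r_ms = numeric(0),
                      tau_d_ms = numeric(0))
  } else {
    onset <- sort(stats::runif(n, 0, config$duration))
    fast <- stats::runif(n) < config$fast_fraction
    rise_mean <- ifelse(fast, config$fast_rise_ms, config$slow_rise_ms)
    rise <- rise_mean
    if (config$rise_cv > 0) {
      sdlog <- sqrt(log(1 + config$rise_cv^2))
      rise <- stats::rlnorm(n, log(rise_mean) - sdlog^2 / 2, sdlog)
    }
    amp_mean <- ifelse(fast, config$amplitude_mean * config$fast_amp_factor,
                       config$amplitude_mean)
    amp <- amp_mean
    if (config$amplitude_cv > 0) {
      sdlog <- sqrt(log(1 + config$amplitude_cv^2))
      amp <- stats::rlnorm(n, log(amp_mean) - sdlog^2 / 2, sdlog)
    }
    # keep rise times physically renderable: the biexponential family has a
    # finite maximum 20-80% rise for a given decay constant (the alpha-kernel
    # limit tau_r -> tau_d); cap the log-normal tail there
    rise_cap <- biexp_rise_20_80(0.99 * config$decay_ms, config$decay_ms)
    rise <- pmin(rise, rise_cap)
    tau_r <- psckit_tau_r(rise, config$decay_ms)
    out <- data.frame(cell_id = as.character(cell_id), onset_s = onset,
                      amplitude_pA = amp,
                      population = ifelse(fast, "fast", "slow"),
                      rise_ms = rise, tau_r_ms = tau_r,
                      tau_d_ms = config$decay_ms)
  }
  class(out) <- c("psc_ground_truth", "data.frame")
  attr(out, "duration") <- config$duration
  attr(out, "rate") <- rate
  out
}

#' Render a ground-truth event train into a current trace
#'
#' The trace is `baseline + sum_k A_k g(t - onset_k) + noise` with `g` the
#' peak-normalized biexponential kernel rendered as an inward (negative)
#' deflection, and the noise Gaussian white noise passed through a 4-pole
#' low-pass Butterworth filter at `noise_cutoff` (applied forward-backward,
#' so zero-phase).
#'
#' @param events a `psc_ground_truth` data.frame from [generate_event_train()]
#' @param config the [simulation_config()] used to generate them
#' @param cell_id cell identifier (defaults to the events' cell); also seeds
#'   the noise stream
#' @param baseline_pA holding-current baseline (pA)
#' @return object of class `psc_trace`: list with `current` (pA), `time_s`,
#'   `sampling_rate`, `cell_id`
#' @export
render_trace <- function(events, config, cell_id = NULL, baseline_pA = 0) {
  validate_sim_config(config)
  if (is.null(cell_id)) {
    cell_id <- if (nrow(events) > 0) events$cell_id[1] else "cell"
  }
  if (nrow(events) > 0 && any(events$onset_s < 0 | events$onset_s >= config$duration)) {
    stop("event onset out of range [0, duration)", call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  x <- rep(baseline_pA, n)
  if (nrow(events) > 0) {
    # cache tau_r lookups on a fine grid of rise times
    for (k in seq_len(nrow(events))) {
      tau_r <- events$tau_r_ms[k]
      tau_d <- events$tau_d_ms[k]
      onset <- events$onset_s[k]
      L <- ceiling((biexp_peak_time(tau_r, tau_d) + 8 * tau_d) / 1000 * fs)
      i0 <- floor(onset * fs) + 1L
      idx <- i0:min(i0 + L, n)
      t_ms <- ((idx - 1) / fs - onset) * 1000
      x[idx] <- x[idx] - events$amplitude_pA[k] * biexp_kernel(t_ms, tau_r, tau_d)
    }
  }
  if (config$noise_sd > 0) {
    set.seed(fanout_seed(config$seed, "noise", cell_id))
    w <- stats::rnorm(n, 0, config$noise_sd)
    x <- x + filter_noise(w, config$noise_cutoff, fs)
  }
  structure(list(current = x,
                 sampling_rate = fs,
                 cell_id = as.character(cell_id),
                 duration = config$duration,
                 baseline_pA = baseline_pA),
            class = "psc_trace")
}

# zero-phase 4-pole Butterworth low-pass; passthrough when the corner is at or
# above Nyquist
filter_noise <- function(x, cutoff, fs) {
  w <- cutoff / (fs / 2)
  if (w >= 1) return(x)
  b <- signal::butter(4, w)
  signal::filtfilt(b, x)
}

#' @export
print.psc_trace <- function(x, ...) {
  cat(sprintf("<psc_trace> cell %s: %.1f s at %g Hz (%d samples)\n",
              x$cell_id, x$duration, x$sampling_rate, length(x$current)))
  invisible(x)
}

#' Two-arm (or three-arm) cohort scenario
#'
#' Describes a slice-incubation experiment: a vehicle arm and a treated arm
#' that differs by a rate multiplier and a higher fast fraction, with an
#' optional third arm in which a blocker reverts the rate increase.
#'
#' @param n_vehicle,n_treated number of cells per arm (>= 2)
#' @param base_config [simulation_config()] for the vehicle arm
#' @param rate_multiplier treated-arm event rate relative to vehicle
#' @param treated_fast_fraction fast fraction in the treated arm
#' @param blocker_arm if `TRUE`, add a third arm (`treated+blocker`) whose
#'   rate reverts to `blocker_multiplier` times the vehicle rate
#' @param n_blocker cells in the blocker arm
#' @param blocker_multiplier rate multiplier of the blocker arm
#' @param seed scenario master seed
#' @return object of class `psc_scenario`
#' @export
cohort_scenario <- function(n_vehicle = 8, n_treated = 9,
                            base_config = simulation_config(),
                            rate_multiplier = 5.143 / 3.717,
                            treated_fast_fraction = 0.7,
                            blocker_arm = FALSE,
                            n_blocker = 7,
                            blocker_multiplier = 3.324 / 3.717,
                            seed = base_config$seed) {
  arms <- list(
    vehicle = list(n = n_vehicle, rate_multiplier = 1,
                   fast_fraction = base_config$fast_fraction),
    treated = list(n = n_treated, rate_multiplier = rate_multiplier,
                   fast_fraction = treated_fast_fraction)
  )
  if (blocker_arm) {
    arms[["treated+blocker"]] <- list(n = n_blocker,
                                      rate_multiplier = blocker_multiplier,
                                      fast_fraction = base_config$fast_fraction)
  }
  structure(list(arms = arms, base_config = base_config,
                 seed = as.integer(seed)),
            class = "psc_scenario")
}

#' Generate a paired-condition cohort
#'
#' Draws per-cell event rates (log-normal across cells with CV
#' `rate_dispersion`), generates ground-truth event trains per cell, and
#' optionally renders traces. Every cell's seed derives deterministically from
#' the scenario seed, the arm name and the cell index, so arms are independent
#' and the whole cohort is reproducible from one integer.
#'
#' @param scenario a [cohort_scenario()]
#' @param render if `FALSE`, skip trace rendering (ground truth only; used
#'   for statistical calibration where traces are not needed)
#' @return object of class `psc_cohort`: list with `cells` (each a list of
#'   `condition`, `cell_id`, `config`, `truth`, `trace`) and `scenario`
#' @export
generate_cohort <- function(scenario, render = TRUE) {
  stopifnot(inherits(scenario, "psc_scenario"))
  if (any(vapply(scenario$arms, function(a) a$n, numeric(1)) < 2)) {
    stop("invalid configuration: each arm needs at least 2 cells", call. = FALSE)
  }
  base <- scenario$base_config
  cells <- list()
  for (arm_name in names(scenario$arms)) {
    arm <- scenario$arms[[arm_name]]
    arm_rate <- base$event_rate * arm$rate_multiplier
    for (i in seq_len(arm$n)) {
      cell_id <- sprintf("%s_%02d", gsub("[^a-zA-Z0-9]", "", arm_name), i)
      cell_seed <- fanout_seed(scenario$seed, arm_name, i)
      cfg <- base
      cfg$seed <- cell_seed
      cfg$fast_fraction <- arm$fast_fraction
      # per-cell rate: log-normal around the arm mean. The draw is keyed by
      # the cell index only (not the arm), so matching cells across arms
      # share their rate deviate and arms differ exactly by the rate
      # multiplier: with multiplier 1 the arms are exchangeable by
      # construction (common random numbers), which is what a null
      # calibration of the downstream statistics needs
      set.seed(fanout_seed(scenario$seed, "rate", i))
      rate <- rlnorm_mean_cv(1, arm_rate, base$rate_dispersion)
      truth <- generate_event_train(cfg, cell_id = cell_id, rate = rate)
      trace <- if (render) render_trace(truth, cfg, cell_id = cell_id) else NULL
      cells[[cell_id]] <- list(condition = arm_name, cell_id = cell_id,
                               config = cfg, seed = cell_seed, rate = rate,
                               truth = truth, trace = trace)
    }
  }
  structure(list(cells = cells, scenario = scenario), class = "psc_cohort")
}

#' Ground-truth event table for a cohort
#'
#' Builds an event table directly from the generator's ground truth, bypassing
#' detection: amplitudes and rise times are the generated ones, halfwidths are
#' the closed-form kernel halfwidths and the template correlation is 1. Used
#' to calibrate the statistics stage independently of the detector.
#'
#' @param cohort a `psc_cohort`
#' @return an accepted-events table in the [filter_events()] output format
#' @export
truth_event_table <- function(cohort) {
  stopifnot(inherits(cohort, "psc_cohort"))
  rows <- lapply(cohort$cells, function(cell) {
    tr <- cell$truth
    n <- nrow(tr)
    if (n == 0) return(NULL)
    hw <- biexp_halfwidth_fast(tr$tau_r_ms, tr$tau_d_ms[1])
    data.frame(cell_id = tr$cell_id, condition = cell$condition,
               event_class = cell$config$event_class,
               onset_s = tr$onset_s, amplitude_pA = tr$amplitude_pA,
               rise_ms = tr$rise_ms, halfwidth_ms = hw,
               correlation = 1, duration_s = cell$config$duration)
  })
  ev <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  filter_events(ev)
}

#' Generate hierarchical grey-value measurements for densitometry
#'
#' Emulates the immunofluorescence quantification design: per mouse, several
#' thick vibratome sections each yielding several thin cryotome sections, a
#' grey value (0--255) measured per region per cryotome section plus a
#' background reading from an immunonegative reference region of the same
#' section.
#'
#' @param region_means named numeric vector of true mean grey values per
#'   region (each in \[0, 255))
#' @param background_mean true mean background grey value
#' @param noise_sd measurement noise SD (grey levels)
#' @param n_mice,n_vibratome,n_cryotome hierarchy cardinalities
#' @param condition condition label attached to all measurements
#' @param seed seed for the measurement noise
#' @return data.frame with columns `region`, `condition`, `mouse_id`,
#'   `vibratome_id`, `cryotome_id`, `grey`, `background`
#' @export
generate_grey_values <- function(region_means, background_mean, noise_sd = 5,
                                 n_mice = 4, n_vibratome = 3, n_cryotome = 2,
                                 condition = "aCSF", seed = 1L) {
  if (any(region_means < 0 | region_means >= 255) ||
      background_mean < 0 || background_mean >= 255) {
    stop("invalid configuration: grey-value means must lie in [0, 255)",
         call. = FALSE)
  }
  set.seed(fanout_seed(seed, "grey", condition))
  grid <- expand.grid(region = names(region_means),
                      mouse_id = sprintf("m%02d", seq_len(n_mice)),
                      vibratome_id = sprintf("v%d", seq_len(n_vibratome)),
                      cryotome_id = sprintf("c%d", seq_len(n_cryotome)),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$region, grid$mouse_id, grid$vibratome_id,
                     grid$cryotome_id), , drop = FALSE]
  mu <- region_means[grid$region]
  grid$grey <- pmin(pmax(stats::rnorm(nrow(grid), mu, noise_sd), 0), 255)
  grid$background <- pmin(pmax(stats::rnorm(nrow(grid), background_mean, noise_sd), 0), 255)
  grid$condition <- condition
  rownames(grid) <- NULL
  grid[, c("region", "condition", "mouse_id", "vibratome_id", "cryotome_id",
           "grey", "background")]
}
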