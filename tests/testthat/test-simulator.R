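# Synthetic recording generator: event trains, rendering, cohorts, grey
# values.

test_that("zero-rate and degenerate configurations behave as specified", {
  cfg <- quiet_config(event_rate = 0)
  expect_identical(nrow(generate_event_train(cfg)), 0L)

  cfg1 <- quiet_config(fast_fraction = 1, event_rate = 5)
  ev <- generate_event_train(cfg1)
  expect_true(all(ev$population == "fast"))

  expect_error(simulation_config(duration = -1), "duration")
  expect_error(simulation_config(fast_fraction = 1.5), "fast_fraction")
  expect_error(simulation_config(fast_rise_ms = 3, slow_rise_ms = 3),
               "fast_rise_ms")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
})

test_that("event counts follow the Poisson law at the reference rate", {
  # rate 3.717 events/s for 120 s: expected count = 446.04
  counts <- vapply(1:400, function(s) {
    cfg <- simulation_config(duration = 120, event_rate = 3.717, seed = s)
    nrow(generate_event_train(cfg))
  }, numeric(1))
  expected <- 3.717 * 120
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("generated trains are reproducible from the config seed alone", {
  cfg <- quiet_config()
  expect_identical(generate_event_train(cfg), generate_event_train(cfg))
  t1 <- render_trace(generate_event_train(cfg), cfg)
  t2 <- render_trace(generate_event_train(cfg), cfg)
  expect_identical(t1$current, t2$current)
})

test_that("rendered single event reproduces its amplitude (kernel contract)", {
  fx <- noise_free_trace(0.5, 20, 1)
  excursion <- abs(min(fx$trace$current) - 0)
  expect_equal(excursion, 20, tolerance = 0.01 * 20)
  # empty event list, zero noise: constant baseline
  cfg <- quiet_config(event_rate = 0, noise_sd = 0)
  tr <- render_trace(generate_event_train(cfg), cfg, cell_id = "z",
                     baseline_pA = -12)
  expect_true(all(tr$current == -12))
})

test_that("events beyond the trace duration are rejected", {
  fx <- noise_free_trace(0.5, 20, 1)
  bad <- fx$events
  bad$onset_s <- 99
  expect_error(render_trace(bad, fx$config), "out of range")
})

test_that("filtered noise variance matches the filter's transfer function", {
  cfg <- quiet_config(event_rate = 0, noise_sd = 2, duration = 20)
  tr <- render_trace(generate_event_train(cfg), cfg, cell_id = "n")
  # oracle: |H|^2 of the 4-pole Butterworth applied twice (zero-phase),
  # integrated over frequency
  w <- cfg$noise_cutoff / (cfg$sampling_rate / 2)
  f <- seq(0, 1, length.out = 4096)
  h2 <- 1 / (1 + (f / w)^(2 * 4))   # squared magnitude, one pass
  expected_sd <- 2 * sqrt(mean(h2^2))  # filtfilt applies the filter twice
  expect_equal(stats::sd(tr$current), expected_sd, tolerance = 0.15 * expected_sd)
})

test_that("cohorts have the requested design and record seeds", {
  sc <- cohort_scenario(n_vehicle = 8, n_treated = 9,
                        base_config = quiet_config(duration = 2), seed = 7)
  co <- generate_cohort(sc, render = FALSE)
  cond <- vapply(co$cells, function(cell) cell$condition, character(1))
  expect_identical(sum(cond == "vehicle"), 8L)
  expect_identical(sum(cond == "treated"), 9L)
  expect_true(all(vapply(co$cells, function(cell) is.integer(cell$seed),
                         logical(1))))
  expect_error(generate_cohort(cohort_scenario(n_vehicle = 1)), "at least 2")
})

test_that("treated arm is stochastically faster at the default multiplier", {
  sc <- cohort_scenario(base_config = quiet_config(duration = 60), seed = 3)
  co <- generate_cohort(sc, render = FALSE)
  ev <- truth_event_table(co)
  iei_v <- pooled_ieis(ev[ev$condition == "vehicle", ])
  iei_t <- pooled_ieis(ev[ev$condition == "treated", ])
  # direction check: treated IEIs stochastically smaller
  expect_lt(stats::median(iei_t), stats::median(iei_v))
  ks <- ks_two_sample(iei_v, iei_t)
  expect_gt(ks$D, 0)
})

test_that("grey-value generator respects the hierarchy and the scale", {
  g <- generate_grey_values(c(CA1_so = 120, CA3_so = 80), background_mean = 20,
                            noise_sd = 0, n_mice = 4, n_vibratome = 3,
                            n_cryotome = 2, seed = 5)
  expect_identical(nrow(g), 2L * 4L * 3L * 2L)
  expect_identical(sum(g$region == "CA1_so"), 24L)
  expect_true(all(g$grey[g$region == "CA1_so"] == 120))
  expect_true(all(g$background == 20))
  expect_error(generate_grey_values(c(a = 300), 10), "\\[0, 255\\)")
})
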