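# Template construction, sliding correlation, detection.

test_that("template argmax sits at the closed-form peak time", {
  tpl <- build_template(0.5, 10, 10000, length_ms = 60)
  t_peak <- biexp_peak_time(0.5, 10)
  expect_lte(abs((which.max(tpl$samples) - 1) * 0.1 - t_peak), 0.1)
  expect_equal(max(tpl$samples), 1, tolerance = 1e-9)
  expect_error(build_template(12, 12), "rise constant")
  expect_error(build_template(0.5, 12, length_ms = 20), "at least 5")
})

test_that("sliding correlation is affine-invariant with documented conventions", {
  tpl <- build_template(0.5, 8, 10000, length_ms = 40)
  m <- length(tpl$samples)
  # trace = affine copy of the (inverted) template embedded in a longer trace
  x <- c(rep(2, 50), 5 - 3 * tpl$samples, rep(2, 50))
  r <- sliding_correlation(x, tpl, polarity = -1)
  expect_equal(max(r), 1, tolerance = 1e-6)
  expect_identical(which.max(r), 51L)
  # window equal to +template (opposite polarity) scores -1
  r_pos <- sliding_correlation(c(rep(0, 50), tpl$samples, rep(0, 50)), tpl,
                               polarity = -1)
  expect_equal(min(r_pos), -1, tolerance = 1e-6)
  # constant trace: zero-variance windows score 0 by convention
  r0 <- sliding_correlation(rep(7, m + 100), tpl)
  expect_true(all(r0 == 0))
  expect_error(sliding_correlation(tpl$samples[1:10], tpl), "shorter")
})

test_that("template fitting recovers kernel constants from clean events", {
  onsets <- seq(0.3, 5.7, by = 0.45)
  fx <- noise_free_trace(onsets, rep(20, length(onsets)), rep(1, length(onsets)),
                         duration = 6)
  tau_r_true <- fx$events$tau_r_ms[1]
  fit <- fit_template_from_events(fx$trace, onsets)
  expect_equal(fit$rise_constant, tau_r_true, tolerance = 0.05 * tau_r_true)
  expect_equal(fit$decay_constant, 12, tolerance = 0.05 * 12)
  expect_error(fit_template_from_events(fx$trace, onsets[1:5]), "at least 10")
})

test_that("template fitting stays stable at SNR ~ 1 and falls back gracefully", {
  cfg <- quiet_config(duration = 20, event_rate = 3, amplitude_mean = 10,
                      amplitude_cv = 0, noise_sd = 10, seed = 31)
  tr <- generate_event_train(cfg, cell_id = "s")
  trace <- render_trace(tr, cfg, cell_id = "s")
  fit <- suppressWarnings(fit_template_from_events(trace, tr$onset_s))
  expect_s3_class(fit, "psc_template")
  expect_gt(fit$decay_constant, fit$rise_constant)
  expect_gt(fit$rise_constant, 0)
})

test_that("a single clean event yields exactly one detection near its onset", {
  fx <- noise_free_trace(0.7, 20, 1)
  det <- detect_events(fx$trace)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$onset_s - 0.7) * 1000, 1)
  expect_gt(det$correlation, 0.6)
  # flat trace: nothing
  cfg0 <- quiet_config(event_rate = 0, noise_sd = 0, duration = 2)
  flat <- render_trace(generate_event_train(cfg0), cfg0, cell_id = "f")
  expect_identical(nrow(detect_events(flat)), 0L)
  expect_error(detect_events(fx$trace, threshold = 1.2), "threshold")
})

test_that("detection count is monotone non-increasing in the threshold", {
  cfg <- quiet_config(duration = 15, event_rate = 4, seed = 17)
  trace <- render_trace(generate_event_train(cfg), cfg, cell_id = "m")
  counts <- vapply(c(0.6, 0.7, 0.8, 0.9), function(th) {
    nrow(detect_events(trace, threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is equivariant to trace scaling and baseline shifts", {
  cfg <- quiet_config(duration = 10, event_rate = 4, seed = 23)
  trace <- render_trace(generate_event_train(cfg), cfg, cell_id = "e")
  det0 <- detect_events(trace)
  shifted <- trace
  shifted$current <- 3 * trace$current - 40
  det1 <- detect_events(shifted)
  expect_identical(det0$onset_index, det1$onset_index)
  expect_equal(det0$correlation, det1$correlation, tolerance = 1e-6)
})

test_that("detector performance on a clean benchmark cohort", {
  # moderate-noise cohort; recall over events with amplitude >= 5x the
  # post-filter noise SD, precision against all ground truth, +-2 ms match
  rec <- c(); prec <- c()
  for (s in 1:3) {
    cfg <- quiet_config(duration = 30, event_rate = 4, seed = 900 + s,
                        amplitude_mean = 9, amplitude_cv = 0.5)
    tr <- generate_event_train(cfg, cell_id = "b")
    trace <- render_trace(tr, cfg, cell_id = "b")
    det <- detect_events(trace)
    big <- tr[tr$amplitude_pA >= 5 * 1.13, ]  # post-filter noise SD ~ 1.13 pA
    rec <- c(rec, match_detections(det, big)$recall)
    prec <- c(prec, match_detections(det, tr)$precision)
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
})

test_that("matched detections are centred within one template rise constant", {
  cfg <- quiet_config(duration = 30, event_rate = 4, seed = 41)
  tr <- generate_event_train(cfg, cell_id = "c")
  trace <- render_trace(tr, cfg, cell_id = "c")
  m <- match_detections(detect_events(trace), tr)
  expect_lt(abs(mean(m$onset_error_ms)), 1.2)
})
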