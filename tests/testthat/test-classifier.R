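# Fast/slow rise-time cutoff selection and contingency counting.

test_that("ratio curve reproduces the smoothed count-ratio formula", {
  # three identical fast rise times: r(1.0) = (0+1)/(3+1)
  c1 <- ratio_curve(c(0.5, 0.5, 0.5), tau_max = 1.5)
  expect_equal(c1$ratio[c1$tau_ms == 1.0], 0.25)
  # three slow: r(1.0) = (3+1)/(0+1)
  c2 <- ratio_curve(c(2, 2, 2), tau_max = 2.5)
  expect_equal(c2$ratio[c2$tau_ms == 1.0], 4)
  # cutoff at/above the maximum: r = 1/(n+1)
  expect_equal(c2$ratio[c2$tau_ms == 2.0], 1 / 4)
  expect_error(ratio_curve(numeric(0)), "empty")
})

test_that("ratio curve is monotone non-increasing for arbitrary samples", {
  for (s in 1:5) {
    set.seed(s)
    rt <- rlnorm(300, 0.3, 0.6)
    cv <- ratio_curve(rt)
    expect_true(all(diff(cv$ratio) <= 1e-12))
    expect_equal(cv$ratio[1], max(cv$ratio))
  }
})

test_that("log derivative matches a brute-force finite-difference oracle", {
  set.seed(9)
  rt <- rlnorm(200, 0.5, 0.5)
  cv <- ratio_curve(rt)
  d <- log_derivative(cv)
  brute <- diff(log10(cv$ratio)) / attr(cv, "delta_tau")
  expect_equal(d[seq_along(brute)], brute, tolerance = 1e-12)
  # constant segments give exactly zero; a single step is nonzero only there
  c_step <- ratio_curve(c(1, 1, 1, 1), tau_max = 3)
  d_step <- log_derivative(c_step)
  expect_true(all(d_step[c_step$tau_ms >= 1] == 0))
  expect_lt(d_step[c_step$tau_ms == 0.9], 0)
})

test_that("cutoff selection recovers the between-mode valley", {
  taus <- vapply(1:5, function(s) {
    ra <- bimodal_rises(2000, 0.6, seed = s)
    rb <- bimodal_rises(2000, 0.7, seed = s + 1000)
    suppressWarnings(select_cutoff_from_samples(ra, rb))$tau_c
  }, numeric(1))
  expect_true(all(taus >= 1.2 & taus <= 2.8))
})

test_that("cutoff selection is symmetric and permutation-invariant", {
  ra <- bimodal_rises(800, 0.6, seed = 3)
  rb <- bimodal_rises(800, 0.7, seed = 4)
  t1 <- suppressWarnings(select_cutoff_from_samples(ra, rb))$tau_c
  t2 <- suppressWarnings(select_cutoff_from_samples(rb, ra))$tau_c
  t3 <- suppressWarnings(select_cutoff_from_samples(sample(ra), rev(rb)))$tau_c
  expect_identical(t1, t2)
  expect_identical(t1, t3)
})

test_that("identical samples give equal derivatives at the selected cutoff", {
  ra <- bimodal_rises(600, 0.6, seed = 11)
  cv <- ratio_curve(ra, tau_max = max(ra) + 0.1)
  res <- suppressWarnings(select_cutoff(cv, cv))
  expect_identical(res$derivative_a, res$derivative_b)
  expect_false(is.na(res$tau_c))
})

test_that("unimodal samples are flagged, never silently split", {
  set.seed(21)
  u1 <- rlnorm(1500, log(2), 0.25)
  u2 <- rlnorm(1500, log(2), 0.25)
  out <- tryCatch(
    withCallingHandlers(
      select_cutoff_from_samples(u1, u2),
      warning = function(w) {
        expect_match(conditionMessage(w), "bimodality")
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (!inherits(out, "error")) expect_true(out$low_confidence)
  expect_error(
    suppressWarnings(select_cutoff_from_samples(u1, u2,
                                                on_unimodal = "error")))
})

test_that("classification at the cutoff uses the fast-inclusive boundary", {
  tab <- toy_event_table(c("v", "t"), list(c(1, 2, 3), c(4, 5, 6)),
                         duration = 10)
  tab$condition <- rep(c("vehicle", "treated"), each = 3)
  tab$rise_ms <- c(1.0, 1.4, 1.5, 0.9, 1.4, 2.0)
  counts <- classify_and_count(tab, 1.4)
  expect_equal(unname(counts["vehicle", ]), c(2, 1))
  expect_equal(unname(counts["treated", ]), c(2, 1))
  expect_equal(attr(counts, "tau_c"), 1.4)
  # all rise times below the cutoff: slow column empty
  tab$rise_ms <- rep(0.5, 6)
  c0 <- classify_and_count(tab, 1.4)
  expect_true(all(c0[, "slow"] == 0))
  expect_error(classify_and_count(tab, -1), "tau_c")
})

test_that("fast proportions are recovered within binomial error", {
  tab_v <- toy_event_table("v1", list(seq_len(4000) / 50), duration = 100)
  tab_v$rise_ms <- bimodal_rises(4000, 0.60, seed = 5)
  tab_t <- toy_event_table("t1", list(seq_len(4000) / 50),
                           condition = "treated", duration = 100)
  tab_t$rise_ms <- bimodal_rises(4000, 0.70, seed = 6)
  tab <- rbind(tab_v, tab_t)
  class(tab) <- c("psc_events", "data.frame")
  # cutoff at the geometric midpoint separates the populations almost purely
  counts <- classify_and_count(tab, 1.73)
  frac <- counts[, "fast"] / rowSums(counts)
  expect_lt(abs(frac["vehicle"] - 0.60), 0.02)
  expect_lt(abs(frac["treated"] - 0.70), 0.02)
})
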