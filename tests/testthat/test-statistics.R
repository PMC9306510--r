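# Count equalization and the two-group statistical battery, each checked
# against an independent brute-force oracle.

test_that("equalization retains exactly n events per cell, first-n by default", {
  tab <- toy_event_table(c("a", "b"),
                         list(seq(0.5, 50, by = 0.5), seq(1, 30, by = 1)))
  eq <- equalize_event_counts(tab, 20)
  expect_equal(as.integer(table(eq$cell_id)), c(20L, 20L))
  # first-n: the earliest onsets survive
  expect_equal(max(eq$onset_s[eq$cell_id == "a"]), 10)
  # a cell with exactly n events is retained whole
  eq30 <- suppressMessages(equalize_event_counts(tab, 30))
  expect_equal(sum(eq30$cell_id == "b"), 30L)
  expect_error(equalize_event_counts(tab, 1), "n_per_cell")
})

test_that("short cells are excluded with a notice", {
  tab <- toy_event_table(c("a", "b"), list(seq_len(50) / 2, seq_len(5)))
  expect_message(eq <- equalize_event_counts(tab, 20), "excluded")
  expect_identical(unique(eq$cell_id), "a")
})

test_that("random equalization is deterministic given the seed", {
  tab <- toy_event_table("a", list(seq_len(100) / 3))
  e1 <- equalize_event_counts(tab, 40, seed = 9, method = "random")
  e2 <- equalize_event_counts(tab, 40, seed = 9, method = "random")
  e3 <- equalize_event_counts(tab, 40, seed = 10, method = "random")
  expect_identical(e1$onset_s, e2$onset_s)
  expect_false(identical(e1$onset_s, e3$onset_s))
})

test_that("K-S D equals the brute-force pooled-support sweep", {
  brute_D <- function(x, y) {
    support <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(support) - ecdf(y)(support)))
  }
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(50); y <- rnorm(50, 0.3)
    expect_equal(ks_two_sample(x, y)$D, brute_D(x, y), tolerance = 1e-12)
  }
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney exact p equals full enumeration for small samples", {
  # oracle: enumerate all C(n+m, n) assignments of pooled ranks
  enum_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    U_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    combos <- combn(length(pooled), n)
    r <- rank(pooled)
    Us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
    mu <- n * length(y) / 2
    mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  }
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  set.seed(8)
  for (i in 1:4) {
    x <- round(rnorm(4), 3); y <- round(rnorm(4, 0.5), 3)
    expect_equal(mann_whitney(x, y)$p, enum_p(x, y), tolerance = 1e-9)
  }
  expect_equal(mann_whitney(1, 1)$p, 1)
})

test_that("Fisher exact p matches hypergeometric enumeration and symmetries", {
  enum_fisher <- function(m) {
    rs <- rowSums(m); cs <- colSums(m)
    ks <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- dhyper(ks, rs[1], rs[2], cs[1])
    obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p, 1)
  set.seed(12)
  for (i in 1:6) {
    m <- matrix(rpois(4, 8), 2)
    p <- fisher_exact(m)$p
    expect_equal(p, enum_fisher(m), tolerance = 1e-9)
    expect_equal(fisher_exact(t(m))$p, p, tolerance = 1e-12)
    expect_equal(fisher_exact(m[2:1, ])$p, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("cell summaries report frequency as count over duration", {
  on <- seq_len(446) / 4
  tab <- toy_event_table("c1", list(on), duration = 120)
  s <- summarize_cells(tab)
  expect_equal(s$cells$frequency, 446 / 120)  # 3.717 events/s
  expect_true(is.na(s$groups$frequency_sem))  # single cell: no SEM
  # identical cells: SEM exactly zero
  tab2 <- toy_event_table(c("c1", "c2"), list(on, on + 0.01), duration = 120)
  s2 <- summarize_cells(tab2)
  expect_equal(s2$groups$frequency_sem, 0)
  tab_nodur <- tab
  tab_nodur$duration_s <- NULL
  expect_error(summarize_cells(tab_nodur), "duration")
})

test_that("run_comparison flags a frequency effect and spares a paired null", {
  mk <- function(mult, seed, n_vehicle = 4, n_treated = 4, ff_t = 0.7) {
    base <- simulation_config(duration = 90, seed = seed)
    sc <- cohort_scenario(n_vehicle = n_vehicle, n_treated = n_treated,
                          base_config = base, rate_multiplier = mult,
                          treated_fast_fraction = ff_t, seed = seed)
    ev <- truth_event_table(generate_cohort(sc, render = FALSE))
    list(v = ev[ev$condition == "vehicle", ],
         t = ev[ev$condition == "treated", ])
  }
  # strong rate effect: IEI K-S must fire
  d <- mk(5.143 / 3.717, 71)
  cmp <- suppressMessages(run_comparison(d$v, d$t))
  expect_true(cmp$ks$iei$significant)
  expect_gt(cmp$ks$iei$D, 0.05)
  # paired null (identical configs): K-S comparisons stay silent
  d0 <- mk(1, 72, ff_t = simulation_config()$fast_fraction)
  cmp0 <- suppressMessages(run_comparison(d0$v, d0$t))
  expect_false(any(vapply(cmp0$ks, `[[`, logical(1), "significant")))
  expect_error(run_comparison(d$v[0, ], d$t), "accepted events")
})

test_that("three-arm scenario: the blocker arm reverts the IEI shift", {
  base <- simulation_config(duration = 90, seed = 55)
  sc <- cohort_scenario(n_vehicle = 4, n_treated = 4, blocker_arm = TRUE,
                        n_blocker = 4, base_config = base, seed = 55)
  ev <- truth_event_table(generate_cohort(sc, render = FALSE))
  tr <- ev[ev$condition == "treated", ]
  bl <- ev[ev$condition == "treated+blocker", ]
  cmp <- suppressMessages(run_comparison(tr, bl))
  expect_true(cmp$ks$iei$significant)
  # direction: blocker IEIs are longer (rate reverted down)
  expect_lt(median(pooled_ieis(tr)), median(pooled_ieis(bl)))
})
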