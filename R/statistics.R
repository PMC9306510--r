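# Event-count-equalized group statistics.
#
# Group comparisons are run on pooled event distributions (IEI, amplitude,
# rise time) after equalizing the number of events contributed per cell, so
# that no single high-frequency cell dominates the pooled empirical CDFs.
# Cell-averaged metrics (frequency, amplitude, rise) are compared with the
# Mann-Whitney U test, pooled distributions with the two-sample
# Kolmogorov-Smirnov test under a dual significance criterion (p < .01 AND
# D > .05), and fast/slow proportions with Fisher's exact test.

#' Equalize the number of events contributed per cell
#'
#' Cells with fewer than `n_per_cell` accepted events are dropped with a
#' message. The default method keeps each cell's first `n_per_cell` accepted
#' events (a contiguous recording prefix), which preserves the interevent
#' interval structure; `method = "random"` draws a seeded uniform subsample
#' without replacement instead (appropriate for amplitude/kinetics, but it
#' thins the event process and therefore distorts IEIs toward a common rate).
#'
#' @param events a `psc_events` table
#' @param n_per_cell events to keep per cell (> 1)
#' @param seed seed for `method = "random"`
#' @param method `"first"` (default) or `"random"`
#' @return the equalized table (accepted events only), sorted by cell and
#'   onset
#' @export
equalize_event_counts <- function(events, n_per_cell, seed = 1L,
                                  method = c("first", "random")) {
  method <- match.arg(method)
  if (!is.numeric(n_per_cell) || n_per_cell <= 1) {
    stop("invalid parameter: n_per_cell must be > 1", call. = FALSE)
  }
  ev <- accepted_events(events)
  ev <- ev[order(ev$cell_id, ev$onset_s), , drop = FALSE]
  cells <- unique(ev$cell_id)
  kept <- lapply(cells, function(cid) {
    sub <- ev[ev$cell_id == cid, , drop = FALSE]
    if (nrow(sub) < n_per_cell) {
      message(sprintf("cell %s excluded: %d accepted events < %d required",
                      cid, nrow(sub), n_per_cell))
      return(NULL)
    }
    if (method == "first") {
      sub[seq_len(n_per_cell), , drop = FALSE]
    } else {
      set.seed(fanout_seed(seed, "equalize", cid))
      idx <- sort(sample.int(nrow(sub), n_per_cell))
      sub[idx, , drop = FALSE]
    }
  })
  out <- do.call(rbind, c(kept, list(make.row.names = FALSE)))
  if (is.null(out)) {
    stop("no cell has enough accepted events for equalization", call. = FALSE)
  }
  class(out) <- c("psc_events", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' from the asymptotic two-sample distribution (ties, which arise from
#' grid-quantized measurements, are tolerated).
#'
#' @param x,y non-empty numeric samples
#' @return list with `D` and `p`
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Two-sample Mann-Whitney U test
#'
#' Two-sided. Exact p by enumeration when both samples are small
#' (`n_x + n_y <= 12`) and tie-free; otherwise the normal approximation with
#' tie correction.
#'
#' @param x,y non-empty numeric samples
#' @return list with `U` (the rank-sum statistic of `x`) and `p`
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (max(c(x, y)) == min(c(x, y))) {
    # fully tied pooled sample: no evidence either way
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p by summation of the hypergeometric probabilities of all tables
#' (at fixed margins) no more probable than the observed one.
#'
#' @param counts 2x2 matrix of non-negative integer counts (e.g. a
#'   `psc_fastslow_counts`)
#' @return list with `p`, `odds_ratio` and the table
#' @export
fisher_exact <- function(counts) {
  m <- unclass(counts)
  attr(m, "tau_c") <- NULL
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2))) stop("counts must be 2x2", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  res <- stats::fisher.test(m)
  list(p = res$p.value, odds_ratio = unname(res$estimate), table = m)
}

#' Per-cell summaries and group table
#'
#' Frequency is the accepted-event count divided by the recording duration of
#' the full recording (computed before any event-count equalization). When
#' the table still contains rejected rows, a `detection_rate` column
#' (all detections / duration) is reported alongside: the acceptance filters
#' deliberately exclude artifact-like and unmeasurable events, so the
#' accepted-event frequency undercounts the underlying event rate, while the
#' raw detection count is the better estimator of it (missed events and
#' false positives roughly balance at moderate noise).
#'
#' @param events a `psc_events` table with `cell_id`, `condition` and either
#'   a `duration_s` column or `durations` supplied
#' @param durations optional named vector of recording durations (s) per cell
#' @return list with `cells` (per-cell data.frame: `cell_id`, `condition`,
#'   `n_events_used`, `frequency`, `mean_amplitude`, `mean_rise`) and
#'   `groups` (per-condition mean, SEM and n for each metric)
#' @export
summarize_cells <- function(events, durations = NULL) {
  ev <- accepted_events(events)
  cells <- unique(ev$cell_id)
  get_dur <- function(cid, sub) {
    if (!is.null(durations)) {
      if (is.null(names(durations))) return(durations[[1]])
      if (!cid %in% names(durations)) {
        stop(sprintf("missing duration for cell %s", cid), call. = FALSE)
      }
      return(durations[[cid]])
    }
    if (!"duration_s" %in% names(sub)) {
      stop("recording durations unknown: supply `durations` or a duration_s column",
           call. = FALSE)
    }
    sub$duration_s[1]
  }
  all_rows <- as.data.frame(events)
  has_rejected <- "accepted" %in% names(all_rows) && any(!all_rows$accepted)
  per_cell <- do.call(rbind, lapply(cells, function(cid) {
    sub <- ev[ev$cell_id == cid, , drop = FALSE]
    dur <- get_dur(cid, sub)
    out <- data.frame(cell_id = cid, condition = sub$condition[1],
                      n_events_used = nrow(sub),
                      frequency = nrow(sub) / dur,
                      mean_amplitude = mean(sub$amplitude_pA),
                      mean_rise = mean(sub$rise_ms))
    if (has_rejected) {
      out$detection_rate <- sum(all_rows$cell_id == cid) / dur
    }
    out
  }))
  sem <- function(v) if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  groups <- do.call(rbind, lapply(split(per_cell, per_cell$condition), function(g) {
    data.frame(condition = g$condition[1], n_cells = nrow(g),
               frequency_mean = mean(g$frequency), frequency_sem = sem(g$frequency),
               amplitude_mean = mean(g$mean_amplitude), amplitude_sem = sem(g$mean_amplitude),
               rise_mean = mean(g$mean_rise), rise_sem = sem(g$mean_rise))
  }))
  rownames(groups) <- NULL
  list(cells = per_cell, groups = groups)
}

#' Full two-group comparison
#'
#' Equalizes event counts per cell, then compares: pooled IEI, amplitude and
#' rise-time distributions by Kolmogorov-Smirnov (significant when p <
#' `ks_p` AND D > `ks_D`); cell-averaged frequency, amplitude and rise by
#' Mann-Whitney (significant when p < `mw_p`); and fast/slow counts at the
#' rise-time cutoff by Fisher's exact test (significant when p <
#' `fisher_p`). The cutoff is selected from the two equalized rise-time
#' samples unless `tau_c` is supplied.
#'
#' @param vehicle,treated `psc_events` tables for the two groups
#' @param n_per_cell events per cell for equalization (NULL: use the largest
#'   count every cell can supply)
#' @param seed seed for random equalization (unused by the default method)
#' @param equalize_method see [equalize_event_counts()]
#' @param tau_c fast/slow cutoff (ms); NULL to select it from the data
#' @param durations optional named durations vector (s); otherwise taken from
#'   the tables' `duration_s` column
#' @param ks_p,ks_D,mw_p,fisher_p significance thresholds
#' @return object of class `psc_comparison`: per-metric test results with
#'   significance flags, cell summaries, fast/slow counts and the cutoff used
#' @export
run_comparison <- function(vehicle, treated, n_per_cell = NULL, seed = 1L,
                           equalize_method = "first",
                           tau_c = NULL, durations = NULL,
                           ks_p = 0.01, ks_D = 0.05, mw_p = 0.05,
                           fisher_p = 0.05) {
  va <- accepted_events(vehicle)
  ta <- accepted_events(treated)
  if (nrow(va) == 0 || nrow(ta) == 0) {
    stop("both groups need accepted events", call. = FALSE)
  }
  if (is.null(n_per_cell)) {
    n_per_cell <- min(table(c(va$cell_id, ta$cell_id)))
    if (n_per_cell <= 1) stop("too few events per cell", call. = FALSE)
  }
  # summaries (frequency) use the full tables, equalization only the pooled
  # distribution analyses
  summary_all <- summarize_cells(rbind(as.data.frame(vehicle),
                                       as.data.frame(treated)),
                                 durations = durations)
  veq <- equalize_event_counts(va, n_per_cell, seed, equalize_method)
  teq <- equalize_event_counts(ta, n_per_cell, seed, equalize_method)

  ks <- list(
    iei = ks_two_sample(pooled_ieis(veq), pooled_ieis(teq)),
    amplitude = ks_two_sample(veq$amplitude_pA, teq$amplitude_pA),
    rise = ks_two_sample(veq$rise_ms, teq$rise_ms))
  ks <- lapply(ks, function(r) {
    r$significant <- r$p < ks_p && r$D > ks_D
    r
  })

  cells <- summary_all$cells
  vcond <- unique(va$condition)[1]
  vc <- cells[cells$condition == vcond, , drop = FALSE]
  tc <- cells[cells$condition != vcond, , drop = FALSE]
  mw <- list(
    frequency = mann_whitney(vc$frequency, tc$frequency),
    amplitude = mann_whitney(vc$mean_amplitude, tc$mean_amplitude),
    rise = mann_whitney(vc$mean_rise, tc$mean_rise))
  mw <- lapply(mw, function(r) {
    r$significant <- r$p < mw_p
    r
  })

  cutoff <- NULL
  if (is.null(tau_c)) {
    cutoff <- tryCatch(
      suppressWarnings(select_cutoff_from_samples(veq$rise_ms, teq$rise_ms)),
      error = function(e) NULL)
    tau_c <- if (is.null(cutoff)) NA_real_ else cutoff$tau_c
  }
  fisher <- NULL
  counts <- NULL
  if (is.finite(tau_c)) {
    pooled <- rbind(as.data.frame(veq), as.data.frame(teq))
    counts <- classify_and_count(pooled, tau_c)
    fisher <- fisher_exact(counts)
    fisher$significant <- fisher$p < fisher_p
  }

  structure(list(ks = ks, mann_whitney = mw, fisher = fisher,
                 counts = counts, tau_c = tau_c, cutoff = cutoff,
                 n_per_cell = n_per_cell,
                 summary = summary_all,
                 thresholds = list(ks_p = ks_p, ks_D = ks_D, mw_p = mw_p,
                                   fisher_p = fisher_p)),
            class = "psc_comparison")
}

#' @export
print.psc_comparison <- function(x, ...) {
  cat(sprintf("<psc_comparison> %d events/cell equalized\n", x$n_per_cell))
  for (nm in names(x$ks)) {
    r <- x$ks[[nm]]
    cat(sprintf("  K-S %-10s D = %.3f, p = %.3g%s\n", nm, r$D, r$p,
                if (r$significant) "  *" else ""))
  }
  for (nm in names(x$mann_whitney)) {
    r <- x$mann_whitney[[nm]]
    cat(sprintf("  M-W %-10s U = %g, p = %.3g%s\n", nm, r$U, r$p,
                if (r$significant) "  *" else ""))
  }
  if (!is.null(x$fisher)) {
    cat(sprintf("  Fisher fast:slow at %.1f ms: p = %.3g%s\n",
                x$tau_c, x$fisher$p,
                if (x$fisher$significant) "  *" else ""))
  }
  invisible(x)
}
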