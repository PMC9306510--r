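# Fast/slow rise-time classification.
#
# Events split into a fast (perisomatic) and a slow (dendritic) rise-time
# class at a data-driven cutoff. For every candidate cutoff tau_c = k * dtau
# on a 0.1 ms grid, the smoothed slower-to-faster count ratio
#   r_sf(tau_c) = (n(tau > tau_c) + 1) / (n(tau <= tau_c) + 1)
# is computed per group, its derivative is taken on a log scale, and the
# selected cutoff is the smallest grid point past the initial ratio spike at
# which the two groups' rates of change agree to within a tolerance. Rise
# times are quantized to the grid (the sampling-rate resolution limit)
# before the curve is built.

#' Slower:faster count-ratio curve for one group
#'
#' @param rise_times rise times (ms), non-empty
#' @param delta_tau grid step (ms); 0.1 ms is the sampling-rate resolution at
#'   10 kHz
#' @param tau_max upper end of the cutoff grid (ms); default just past the
#'   largest observed rise time
#' @param quantize if `TRUE` (default), round rise times to the
#'   `delta_tau` grid before counting
#' @return data.frame of class `psc_cutoff_curve` with columns `tau_ms` and
#'   `ratio`; bin counts are kept in the `"bin_counts"` attribute
#' @export
ratio_curve <- function(rise_times, delta_tau = 0.1, tau_max = NULL,
                        quantize = TRUE) {
  rise_times <- rise_times[is.finite(rise_times)]
  if (length(rise_times) == 0) {
    stop("rise-time sample is empty", call. = FALSE)
  }
  if (is.null(tau_max)) tau_max <- max(rise_times) + delta_tau
  if (tau_max < max(rise_times)) {
    stop("tau_max must cover the largest rise time", call. = FALSE)
  }
  # integer grid indices avoid floating-point boundary ambiguity
  r_int <- if (quantize) round(rise_times / delta_tau) else rise_times / delta_tau
  k_max <- ceiling(tau_max / delta_tau)
  ks <- seq_len(k_max)
  n_le <- vapply(ks, function(k) sum(r_int <= k), numeric(1))
  n <- length(r_int)
  ratio <- (n - n_le + 1) / (n_le + 1)
  counts <- diff(c(0, n_le))
  out <- data.frame(tau_ms = ks * delta_tau, ratio = ratio)
  attr(out, "delta_tau") <- delta_tau
  attr(out, "n") <- n
  attr(out, "bin_counts") <- counts
  class(out) <- c("psc_cutoff_curve", "data.frame")
  out
}

#' Log-scale derivative of a ratio curve
#'
#' The rate of change of the ratio on a logarithmic scale,
#' `delta r_sf / (ln 10 * r_sf * delta_tau)`, which equals the finite
#' difference of `log10(r_sf)` per grid step. On the log scale the
#' derivative peaks flanking the between-mode valley are easy to identify,
#' and the two groups' derivative curves cross inside the valley when their
#' fast fractions differ. Forward differences on the grid; the last grid
#' point repeats the previous value.
#'
#' @param curve a `psc_cutoff_curve`
#' @return numeric vector, one value per grid point; exactly zero wherever
#'   the ratio is locally constant
#' @export
log_derivative <- function(curve) {
  stopifnot(inherits(curve, "psc_cutoff_curve"))
  r <- curve$ratio
  if (length(r) < 2) stop("curve needs at least 2 grid points", call. = FALSE)
  dt <- attr(curve, "delta_tau")
  d <- diff(log10(r)) / dt
  c(d, d[length(d)])
}

# crude bimodality check on the quantized rise-time histogram: smooth the bin
# counts, find interior peaks, and require two peaks separated by a valley
# clearly below both
.is_bimodal <- function(counts, smooth_bins = 5) {
  if (length(counts) < 5 || sum(counts) < 20) return(FALSE)
  k <- rep(1 / smooth_bins, smooth_bins)
  s <- as.numeric(stats::filter(counts, k, sides = 2))
  s[is.na(s)] <- 0
  peaks <- which(diff(sign(diff(s))) == -2) + 1
  peaks <- peaks[s[peaks] >= 0.1 * max(s)]
  if (length(peaks) < 2) return(FALSE)
  peaks <- peaks[order(s[peaks], decreasing = TRUE)][1:2]
  lo <- min(peaks); hi <- max(peaks)
  valley <- min(s[lo:hi])
  valley < 0.7 * min(s[peaks])
}

# centred running mean that keeps endpoints (partial windows)
.runmean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Select the fast/slow rise-time cutoff from two groups
#'
#' Returns the smallest grid cutoff at which the two groups' rates of ratio
#' change agree, past the initial ratio spike. All of the following must
#' hold at the selected point:
#'
#' * past the spike: `r_sf < transient_fraction * max(r_sf)` in both groups;
#' * populated: at least `min_fast_fraction` of each group's events lie at
#'   or below the cutoff and at least `min_slow_fraction` lie above it (a
#'   cutoff in an empty tail, where the ratio is locally flat simply because
#'   no events live there, would trivially satisfy the derivative criterion
#'   while splitting nothing);
#' * approximately equal rates of change:
#'   `|d_a - d_b| <= tolerance * max(|d_a|, |d_b|, epsilon)`, where the
#'   derivatives are computed on a `smooth_bins`-wide running mean of
#'   `log10(r_sf)` (raw finite differences on count data fluctuate bin to
#'   bin; the comparison needs the underlying rate of change);
#' * locally stable: `|d| <= stability_factor * min |d|` for both groups,
#'   the minimum taken over the admissible (past-spike, populated) range.
#'   During the initial descent of the ratio both groups' derivatives are
#'   large and near-proportional, so equality alone would fire long before
#'   the between-mode valley; the valley floor is where the log-scale curve
#'   is flattest.
#'
#' If the pooled rise-time histogram shows no evidence of bimodality the
#' result is flagged low-confidence (or an error is raised with
#' `on_unimodal = "error"`): on unimodal data any returned cutoff would split
#' a single population, not separate two.
#'
#' @param curve_a,curve_b `psc_cutoff_curve`s on the same grid
#' @param tolerance relative tolerance for derivative agreement (default 0.10)
#' @param transient_fraction fraction of the maximum ratio defining the end
#'   of the initial spike (default 0.5)
#' @param min_fast_fraction minimal fraction of each sample at or below an
#'   admissible cutoff (default 0.05)
#' @param min_slow_fraction minimal fraction of each sample above an
#'   admissible cutoff (default 0.05)
#' @param stability_factor multiple of each group's minimal derivative
#'   magnitude still considered locally stable (default 2)
#' @param smooth_bins width (grid bins) of the running mean applied to
#'   `log10(r_sf)` before differencing (default 5, i.e. 0.5 ms at the
#'   default grid); 1 disables smoothing
#' @param epsilon absolute floor in the derivative comparison
#' @param on_unimodal `"flag"` (default: warn and flag) or `"error"`
#' @return list of class `psc_cutoff`: `tau_c` (ms), `index`,
#'   `derivative_a`, `derivative_b`, `low_confidence`, `criteria`
#' @export
select_cutoff <- function(curve_a, curve_b, tolerance = 0.1,
                          transient_fraction = 0.5,
                          min_fast_fraction = 0.05,
                          min_slow_fraction = 0.05, smooth_bins = 5,
                          stability_factor = 2, epsilon = 1e-6,
                          on_unimodal = c("flag", "error")) {
  on_unimodal <- match.arg(on_unimodal)
  stopifnot(inherits(curve_a, "psc_cutoff_curve"),
            inherits(curve_b, "psc_cutoff_curve"))
  if (nrow(curve_a) != nrow(curve_b) ||
      !isTRUE(all.equal(curve_a$tau_ms, curve_b$tau_ms))) {
    stop("curves must share the same cutoff grid", call. = FALSE)
  }
  dt <- attr(curve_a, "delta_tau")
  smoothed_deriv <- function(curve) {
    sl <- .runmean(log10(curve$ratio), smooth_bins)
    d <- diff(sl) / dt
    c(d, d[length(d)])
  }
  d_a <- smoothed_deriv(curve_a)
  d_b <- smoothed_deriv(curve_b)
  past_a <- curve_a$ratio < transient_fraction * max(curve_a$ratio)
  past_b <- curve_b$ratio < transient_fraction * max(curve_b$ratio)
  frac_le <- function(curve) {
    cum <- cumsum(attr(curve, "bin_counts"))
    cum / attr(curve, "n")
  }
  pop_a <- frac_le(curve_a) >= min_fast_fraction &
    (1 - frac_le(curve_a)) >= min_slow_fraction
  pop_b <- frac_le(curve_b) >= min_fast_fraction &
    (1 - frac_le(curve_b)) >= min_slow_fraction
  agree <- abs(d_a - d_b) <= tolerance * pmax(abs(d_a), abs(d_b), epsilon)
  # the difference of the two groups' derivative curves passes through zero
  # inside the valley; a sign change between neighbouring grid points brackets
  # exact equality even when no single grid point is within tolerance
  dd <- d_a - d_b
  flip <- c(FALSE, dd[-1] * dd[-length(dd)] <= 0)
  admissible <- past_a & past_b & pop_a & pop_b
  stable <- admissible
  if (any(admissible)) {
    m_a <- min(abs(d_a)[admissible])
    m_b <- min(abs(d_b)[admissible])
    stable <- abs(d_a) <= stability_factor * pmax(m_a, epsilon) &
      abs(d_b) <= stability_factor * pmax(m_b, epsilon)
  }
  ok <- admissible & stable & (agree | flip)
  if (!any(ok)) {
    stop(paste0(
      "no cutoff satisfies the selection criteria; ",
      "inspect the ratio curves"), call. = FALSE)
  }
  idx <- which(ok)[1]
  counts <- attr(curve_a, "bin_counts") + attr(curve_b, "bin_counts")
  bimodal <- .is_bimodal(counts)
  if (!bimodal) {
    msg <- paste("pooled rise-time distribution shows no bimodality;",
                 "cutoff is low-confidence")
    if (on_unimodal == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  structure(list(tau_c = curve_a$tau_ms[idx],
                 index = idx,
                 derivative_a = d_a[idx],
                 derivative_b = d_b[idx],
                 low_confidence = !bimodal,
                 criteria = list(tolerance = tolerance,
                                 transient_fraction = transient_fraction,
                                 min_fast_fraction = min_fast_fraction,
                                 min_slow_fraction = min_slow_fraction,
                                 smooth_bins = smooth_bins,
                                 stability_factor = stability_factor,
                                 epsilon = epsilon)),
            class = "psc_cutoff")
}

#' Build matched ratio curves and select the cutoff from two rise-time samples
#'
#' Convenience wrapper: puts both samples on a common grid and calls
#' [select_cutoff()].
#'
#' @param rise_a,rise_b rise-time samples (ms) for the two groups
#' @inheritParams ratio_curve
#' @inheritParams select_cutoff
#' @return a `psc_cutoff` (see [select_cutoff()])
#' @export
select_cutoff_from_samples <- function(rise_a, rise_b, delta_tau = 0.1,
                                       tolerance = 0.1,
                                       transient_fraction = 0.5,
                                       epsilon = 1e-6,
                                       on_unimodal = c("flag", "error")) {
  tau_max <- max(rise_a, rise_b, na.rm = TRUE) + delta_tau
  ca <- ratio_curve(rise_a, delta_tau, tau_max)
  cb <- ratio_curve(rise_b, delta_tau, tau_max)
  select_cutoff(ca, cb, tolerance = tolerance,
                transient_fraction = transient_fraction, epsilon = epsilon,
                on_unimodal = on_unimodal)
}

#' Fast/slow contingency counts at a cutoff
#'
#' Events with rise time `<= tau_c` count as fast, `> tau_c` as slow
#' (boundary events are fast). Only accepted events are counted.
#'
#' @param events a `psc_events` table with a `condition` column covering the
#'   conditions to tabulate
#' @param tau_c rise-time cutoff (ms), > 0
#' @param conditions row order of the table; default: order of appearance
#' @return matrix of class `psc_fastslow_counts` (rows = conditions, columns
#'   = fast/slow) with the cutoff in the `"tau_c"` attribute
#' @export
classify_and_count <- function(events, tau_c, conditions = NULL) {
  if (!is.numeric(tau_c) || tau_c <= 0) stop("tau_c must be > 0", call. = FALSE)
  ev <- accepted_events(events)
  if (is.null(conditions)) conditions <- unique(ev$condition)
  counts <- t(vapply(conditions, function(cond) {
    rt <- ev$rise_ms[ev$condition == cond]
    c(fast = sum(rt <= tau_c), slow = sum(rt > tau_c))
  }, numeric(2)))
  rownames(counts) <- conditions
  attr(counts, "tau_c") <- tau_c
  class(counts) <- c("psc_fastslow_counts", class(counts))
  counts
}

#' Dump cutoff curves for two groups as a data.frame
#'
#' @param curve_a,curve_b `psc_cutoff_curve`s on the same grid
#' @return data.frame with `tau_ms`, `ratio_a`, `ratio_b`, `deriv_a`,
#'   `deriv_b`
#' @export
cutoff_curve_table <- function(curve_a, curve_b) {
  data.frame(tau_ms = curve_a$tau_ms,
             ratio_a = curve_a$ratio, ratio_b = curve_b$ratio,
             deriv_a = log_derivative(curve_a),
             deriv_b = log_derivative(curve_b))
}
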