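# Template-correlation event detection.
#
# Candidate PSC onsets are found by sliding a peak-normalized biexponential
# template along the trace and computing the Pearson correlation between each
# window and the template; local correlation maxima above a threshold
# (default 0.6) are kept. Pearson correlation is invariant to affine
# transformations of the window, so detection is insensitive to baseline
# offsets and amplitude scaling.

#' Build a biexponential detection template
#'
#' @param rise_constant kernel rise time constant (ms)
#' @param decay_constant kernel decay time constant (ms); must exceed
#'   `rise_constant`
#' @param sampling_rate sampling rate (Hz) of the traces the template will be
#'   correlated against
#' @param length_ms template duration (ms); default 6 decay constants, and at
#'   least 5 (so the template captures essentially the whole waveform)
#' @return object of class `psc_template`: list with `rise_constant`,
#'   `decay_constant`, `sampling_rate`, `length_ms` and peak-normalized
#'   `samples`
#' @export
build_template <- function(rise_constant, decay_constant, sampling_rate = 10000,
                           length_ms = NULL) {
  check_kernel_constants(rise_constant, decay_constant)
  if (is.null(length_ms)) length_ms <- 6 * decay_constant
  if (length_ms < 5 * decay_constant) {
    stop("template length must be at least 5 decay constants", call. = FALSE)
  }
  n <- max(2L, round(length_ms / 1000 * sampling_rate))
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  samples <- biexp_kernel(t_ms, rise_constant, decay_constant)
  samples <- samples / max(samples)   # discrete peak exactly 1
  structure(list(rise_constant = rise_constant,
                 decay_constant = decay_constant,
                 sampling_rate = sampling_rate,
                 length_ms = length_ms,
                 samples = samples),
            class = "psc_template")
}

#' Default detection templates
#'
#' Generic IPSC (0.5 / 12 ms) and EPSC (0.3 / 4 ms) rise/decay constants;
#' per-recording templates fitted with [fit_template_from_events()] are
#' preferred when enough events are available.
#'
#' @param event_class one of `"IPSC"` or `"EPSC"` (s/m prefixes accepted)
#' @param sampling_rate sampling rate (Hz)
#' @return a `psc_template`
#' @export
default_template <- function(event_class = "IPSC", sampling_rate = 10000) {
  if (grepl("EPSC", event_class)) {
    build_template(0.3, 4, sampling_rate)
  } else {
    build_template(0.5, 12, sampling_rate)
  }
}

#' Default fast/slow detection template pair
#'
#' Recordings contain two kinetically distinct event populations (perisomatic
#' fast rise, dendritic slow rise), and a single template under-detects
#' whichever population it matches worse; detection therefore runs once with
#' a fast-rise and once with a slow-rise template and merges the results.
#' Each template carries its own correlation window (attribute
#' `"window_ms"`).
#'
#' @param event_class `"IPSC"` or `"EPSC"` (s/m prefixes accepted)
#' @param sampling_rate sampling rate (Hz)
#' @return named list of two `psc_template`s (`fast`, `slow`)
#' @export
detection_templates <- function(event_class = "IPSC", sampling_rate = 10000) {
  if (grepl("EPSC", event_class)) {
    fast <- build_template(0.3, 4, sampling_rate)
    slow <- build_template(1.2, 4, sampling_rate)
    attr(fast, "window_ms") <- 4
    attr(slow, "window_ms") <- 7
  } else {
    fast <- build_template(0.8, 12, sampling_rate)
    slow <- build_template(2.8, 12, sampling_rate)
    attr(fast, "window_ms") <- 8
    attr(slow, "window_ms") <- 14
  }
  list(fast = fast, slow = slow)
}

#' Fit a template from averaged detected events
#'
#' Aligns event windows at their onsets, averages them, and least-squares fits
#' a difference-of-exponentials waveform to the (sign-corrected) average. On
#' non-convergence a supplied fallback template is returned with a warning.
#'
#' @param trace a `psc_trace`
#' @param onsets event onset times (s); at least 10 required
#' @param fallback template returned if the fit fails (default: the generic
#'   IPSC template at the trace's sampling rate)
#' @param window_ms averaging window length (ms)
#' @param polarity -1 for inward (negative) events, +1 for outward
#' @return a `psc_template` with fitted constants
#' @export
fit_template_from_events <- function(trace, onsets, fallback = NULL,
                                     window_ms = 72, polarity = -1) {
  stopifnot(inherits(trace, "psc_trace"))
  if (length(onsets) < 10) {
    stop("at least 10 onsets are required to fit a template", call. = FALSE)
  }
  fs <- trace$sampling_rate
  m <- round(window_ms / 1000 * fs)
  n <- length(trace$current)
  base_w <- max(1L, round(0.005 * fs))
  segs <- lapply(onsets, function(on) {
    i0 <- floor(on * fs) + 1L
    if (i0 + m - 1 > n || i0 < 1) return(NULL)
    seg <- trace$current[i0:(i0 + m - 1)]
    b <- stats::median(trace$current[max(1, i0 - base_w):max(1, i0 - 1)])
    polarity * (seg - b)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) < 10) {
    stop("at least 10 onsets are required to fit a template", call. = FALSE)
  }
  avg <- Reduce(`+`, segs) / length(segs)
  t_ms <- (seq_len(m) - 1) / fs * 1000
  dat <- data.frame(t = t_ms, y = avg)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (exp(-t / td) - exp(-t / tr)),
                      data = dat,
                      start = list(A = max(avg), tr = 0.5, td = 10),
                      lower = c(A = 1e-6, tr = 1e-3, td = 1e-2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit)
  if (ok) {
    cf <- stats::coef(fit)
    ok <- is.finite(cf[["tr"]]) && is.finite(cf[["td"]]) &&
      cf[["tr"]] > 0 && cf[["td"]] > cf[["tr"]]
  }
  if (!ok) {
    warning("template fit did not converge; using fallback template",
            call. = FALSE)
    if (is.null(fallback)) fallback <- default_template("IPSC", fs)
    return(fallback)
  }
  build_template(cf[["tr"]], cf[["td"]], fs,
                 length_ms = max(6 * cf[["td"]], 5 * cf[["td"]]))
}

#' Sliding Pearson correlation of a trace against a template
#'
#' For every window start `i`, the Pearson correlation between
#' `trace[i, ..., i + m - 1]` and the template's `m` samples. Computed with an
#' FFT cross-correlation plus rolling sums, so it is O(n log n). Windows with
#' (numerically) zero variance are assigned a correlation of 0 by convention.
#'
#' @param trace a `psc_trace` (or plain numeric vector)
#' @param template a `psc_template` (or plain numeric sample vector)
#' @param polarity sign applied to the template before correlating; -1 (the
#'   default) matches inward, negative-going events
#' @param window_ms optional correlation window (ms): correlate against only
#'   the first `window_ms` of the template. With a long template the full
#'   window spans several mean interevent intervals at physiological rates,
#'   and a larger neighbouring event inside the window dominates its variance
#'   and masks the event at the window start; a window covering the rise and
#'   early decay avoids this
#' @param detrend if `TRUE`, compute the partial correlation controlling for
#'   a linear trend within each window (removes the locally linear baseline
#'   an event sitting on a neighbour's decay tail experiences)
#' @return numeric vector of length `n - m + 1` with values in \[-1, 1\]
#' @export
sliding_correlation <- function(trace, template, polarity = -1,
                                window_ms = NULL, detrend = FALSE) {
  x <- if (inherits(trace, "psc_trace")) trace$current else as.numeric(trace)
  tpl <- if (inherits(template, "psc_template")) template$samples else as.numeric(template)
  if (!is.null(window_ms)) {
    fs <- if (inherits(template, "psc_template")) template$sampling_rate
          else if (inherits(trace, "psc_trace")) trace$sampling_rate
          else stop("window_ms requires a sampling rate", call. = FALSE)
    tpl <- tpl[seq_len(min(length(tpl), max(2L, round(window_ms / 1000 * fs))))]
  }
  tpl <- polarity * tpl
  n <- length(x)
  m <- length(tpl)
  if (m >= n) stop("template must be shorter than the trace", call. = FALSE)
  conv_with <- function(kernel) {
    # sum_j x[i+j-1] * kernel[j] for every window start i, via FFT
    L <- stats::nextn(n + m - 1, 2)
    fx <- stats::fft(c(x, numeric(L - n)))
    fy <- stats::fft(c(rev(kernel), numeric(L - m)))
    Re(stats::fft(fx * fy, inverse = TRUE))[m:n] / L
  }
  cs <- cumsum(x)
  cs2 <- cumsum(x * x)
  s1 <- cs[m:n] - c(0, cs[seq_len(n - m)])
  s2 <- cs2[m:n] - c(0, cs2[seq_len(n - m)])
  if (!detrend) {
    ty <- tpl - mean(tpl)
    sy <- sqrt(sum(ty^2))
    num <- conv_with(ty)
    varx <- s2 - s1 * s1 / m
  } else {
    # partial correlation given an intercept and a linear trend: project the
    # window and the template off span{1, t} (an event riding on a
    # neighbour's decay tail sees a locally linear baseline)
    t_idx <- seq_len(m)
    tn <- (t_idx - mean(t_idx)) / sqrt(sum((t_idx - mean(t_idx))^2))
    ty <- tpl - mean(tpl)
    ty <- ty - sum(ty * tn) * tn
    sy <- sqrt(sum(ty^2))
    num <- conv_with(ty)   # ty is orthogonal to 1 and t already
    cw <- conv_with(tn)    # projection of each window on the trend basis
    varx <- s2 - s1 * s1 / m - cw * cw
  }
  varx[varx < 0] <- 0
  tol <- 1e-12 * pmax(s2, m)
  r <- numeric(length(varx))
  ok <- varx > tol & sy > 0
  r[ok] <- num[ok] / (sqrt(varx[ok]) * sy)
  pmin(pmax(r, -1), 1)
}

#' Detect PSC onsets by template correlation
#'
#' Onsets are local maxima of the sliding correlation series that exceed
#' `threshold`; maxima closer together than the refractory span are merged
#' keeping the higher correlation (a guard against one event producing
#' multiple correlation peaks).
#'
#' @param trace a `psc_trace`
#' @param template a `psc_template`, or a list of templates whose detections
#'   are merged (closer than the refractory span, the higher correlation
#'   wins); default [detection_templates()] for IPSCs
#' @param threshold correlation threshold in (0, 1); default 0.6
#' @param refractory_ms minimum separation between detections (ms)
#' @param min_dip minimum correlation dip separating two detections within
#'   one suprathreshold region; 0 (the default) splits at every interior
#'   local minimum and relies on onset refinement to collapse duplicates,
#'   which also keeps the detection count monotone in the threshold
#' @param window_ms correlation window (ms), see [sliding_correlation()]
#' @param detrend remove a linear within-window baseline trend before
#'   correlating (see [sliding_correlation()]); on by default
#' @param polarity -1 for inward events (default)
#' @return data.frame of class `psc_detections` with columns `onset_index`,
#'   `onset_s`, `correlation`, sorted by onset
#' @export
detect_events <- function(trace, template = NULL, threshold = 0.6,
                          refractory_ms = 2, min_dip = 0, window_ms = NULL,
                          detrend = TRUE, polarity = -1) {
  stopifnot(inherits(trace, "psc_trace"))
  if (is.null(template)) template <- detection_templates("IPSC", trace$sampling_rate)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  if (is.list(template) && !inherits(template, "psc_template")) {
    dets <- lapply(template, function(tp) {
      detect_events(trace, tp, threshold = threshold,
                    refractory_ms = refractory_ms, min_dip = min_dip,
                    window_ms = window_ms, detrend = detrend,
                    polarity = polarity)
    })
    all <- do.call(rbind, lapply(dets, as.data.frame))
    all <- all[order(-all$correlation), , drop = FALSE]
    refr_s <- refractory_ms / 1000
    sel <- integer(0)
    for (k in seq_len(nrow(all))) {
      if (all(abs(all$onset_s[sel] - all$onset_s[k]) >= refr_s)) sel <- c(sel, k)
    }
    out <- all[sel, , drop = FALSE]
    out <- out[order(out$onset_s), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "trace_id") <- trace$cell_id
    attr(out, "threshold") <- threshold
    class(out) <- c("psc_detections", "data.frame")
    return(out)
  }
  if (is.null(window_ms)) {
    window_ms <- attr(template, "window_ms")
    if (is.null(window_ms)) window_ms <- min(template$length_ms, 16)
  }
  r <- sliding_correlation(trace, template, polarity, window_ms = window_ms,
                           detrend = detrend)
  # the correlation stays above threshold for an extended span around each
  # event (the template's decay tail correlates from many offsets), so every
  # contiguous suprathreshold region yields its best local maximum, and
  # additional maxima within a region are accepted only when separated from
  # an already-accepted peak by a sufficiently deep dip (overlapping events
  # produce prominent secondary peaks; plateau noise jitter does not)
  above <- r > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  refr <- max(1L, round(refractory_ms / 1000 * trace$sampling_rate))
  keep <- integer(0)
  for (j in which(runs$values)) {
    seg <- starts[j]:ends[j]
    rs <- r[seg]
    if (length(seg) < 3) {
      loc <- seg[which.max(rs)]
    } else {
      left <- c(-Inf, rs[-length(rs)])
      right <- c(rs[-1], -Inf)
      loc <- seg[rs >= left & rs > right]
      if (length(loc) == 0) loc <- seg[which.max(rs)]
    }
    acc <- integer(0)
    for (i in loc[order(r[loc], decreasing = TRUE)]) {
      if (length(acc) > 0 && any(abs(acc - i) < refr)) next
      if (length(acc) > 0) {
        # dip check against the nearest accepted peak
        nb <- acc[which.min(abs(acc - i))]
        gap <- r[min(i, nb):max(i, nb)]
        if (min(gap) > min(r[i], r[nb]) - min_dip) next
      }
      acc <- c(acc, i)
    }
    keep <- c(keep, acc)
  }
  keep <- sort(keep)
  # refine onsets on the raw waveform: the correlation peak lags the true
  # onset when the event's rise is slower than the template's, so the 20-80%
  # rising chord is extrapolated back to baseline. Each candidate's
  # refinement window is capped at the next candidate so a small event does
  # not lock onto a larger neighbour's rising edge
  fs <- trace$sampling_rate
  onset_s <- vapply(seq_along(keep), function(k) {
    i <- keep[k]
    lim <- if (k < length(keep)) keep[k + 1] - 1L else NA_integer_
    refine_onset(trace$current, i, fs, length(template$samples), polarity,
                 max_index = lim)
  }, numeric(1))
  ord <- order(onset_s)
  keep <- keep[ord]
  onset_s <- onset_s[ord]
  # refinement can collapse two correlation peaks onto one waveform onset
  if (length(keep) > 1) {
    dup <- c(FALSE, diff(onset_s) < refr / fs)
    keep <- keep[!dup]
    onset_s <- onset_s[!dup]
  }
  out <- data.frame(onset_index = keep,
                    onset_s = onset_s,
                    correlation = r[keep])
  attr(out, "trace_id") <- trace$cell_id
  attr(out, "threshold") <- threshold
  class(out) <- c("psc_detections", "data.frame")
  out
}

# Estimate the event onset near a correlation-peak index: locate the
# deviation peak, interpolate the 20% and 80% rising crossings, and
# extrapolate the chord back to the baseline level (onset ~ t20 - rise/3).
# Falls back to the correlation-peak position when the crossings cannot be
# found.
refine_onset <- function(x, i, fs, m, polarity = -1, max_index = NA) {
  n <- length(x)
  # the correlation peak sits within about [-1, +3] ms of the true onset, so
  # a short backward margin suffices and keeps neighbouring events out
  pre <- round(0.004 * fs)
  lo <- max(1L, i - pre)
  hi <- min(n, i + round(0.010 * fs))
  if (!is.na(max_index)) hi <- max(min(hi, max_index), lo + 4L)
  bw <- max(1L, round(0.005 * fs))
  b <- stats::median(x[max(1L, lo - bw):max(1L, lo - 1L)])
  d <- polarity * (x[lo:hi] - b)
  # light boxcar smoothing stabilizes the 20/80% crossings under noise
  sm <- max(1L, round(0.0005 * fs))
  if (sm > 1 && length(d) > 2 * sm) {
    ds <- as.numeric(stats::filter(d, rep(1 / sm, sm), sides = 2))
    d <- ifelse(is.na(ds), d, ds)
  }
  ip <- which.max(d)
  amp <- d[ip]
  fallback <- (i - 1) / fs
  if (amp <= 0 || ip <= 2) return(fallback)
  j <- ip
  while (j > 1 && d[j - 1] >= 0.8 * amp) j <- j - 1
  if (j <= 1) return(fallback)
  c80 <- .cross_before(d, j, 0.8 * amp)
  j2 <- floor(c80)
  while (j2 > 1 && d[j2 - 1] >= 0.2 * amp) j2 <- j2 - 1
  if (j2 <= 1) return(fallback)
  c20 <- .cross_before(d, j2, 0.2 * amp)
  onset_frac <- c20 - (c80 - c20) / 3
  max(0, (lo - 1 + onset_frac - 1) / fs)
}

#' Match detections against ground truth
#'
#' Greedy nearest-onset matching within a tolerance; each ground-truth event
#' can absorb at most one detection. Used for detector benchmarking.
#'
#' @param detections `psc_detections` (or any data.frame with `onset_s`)
#' @param truth ground-truth events with `onset_s`
#' @param tolerance_ms matching tolerance (ms)
#' @return list with `n_matched`, `recall`, `precision`, `onset_error_ms`
#'   (signed detection-minus-truth errors of matched pairs)
#' @export
match_detections <- function(detections, truth, tolerance_ms = 2) {
  det <- detections$onset_s
  tru <- truth$onset_s
  tol <- tolerance_ms / 1000
  used <- rep(FALSE, length(tru))
  err <- numeric(0)
  for (d in det) {
    dist <- abs(tru - d)
    dist[used] <- Inf
    j <- which.min(dist)
    if (length(j) == 1 && is.finite(dist[j]) && dist[j] <= tol) {
      used[j] <- TRUE
      err <- c(err, d - tru[j])
    }
  }
  n_matched <- sum(used)
  list(n_matched = n_matched,
       recall = if (length(tru) > 0) n_matched / length(tru) else NA_real_,
       precision = if (length(det) > 0) n_matched / length(det) else NA_real_,
       onset_error_ms = err * 1000)
}
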