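# Per-event kinetic measurement and acceptance filtering.
#
# Each detected onset is measured on the raw trace: baseline as the median of
# the 5 ms preceding the onset, amplitude as the absolute extremum deviation
# within one template length after onset, 20-80% rise time and halfwidth by
# linear interpolation between samples. Accepted events must jointly satisfy
# correlation > 0.6, amplitude > 3 pA (amplifier noise floor), 20-80% rise
# time < 5 ms, and halfwidth > rise time.

# interpolated crossing time (in samples, fractional) where d crosses `level`
# between index i-1 and i
.cross_before <- function(d, i, level) {
  if (i <= 1) return(NA_real_)
  d0 <- d[i - 1]; d1 <- d[i]
  if (d1 == d0) return(i - 1)
  (i - 1) + (level - d0) / (d1 - d0)
}

# mean of all linearly interpolated crossings of `level` within d[from..to]
# (fractional sample index). On a noise-free monotone segment there is exactly
# one crossing; under noise the mean of the crossing cluster is an unbiased
# estimate of the crossing location, where taking the first or last crossing
# would be systematically early or late.
.level_crossing <- function(d, from, to, level) {
  if (to <= from) return(NA_real_)
  k <- from:(to - 1)
  lo <- d[k] - level
  hi <- d[k + 1] - level
  hit <- which(lo * hi < 0 | (lo == 0 & hi != 0))
  if (length(hit) == 0) {
    if (d[from] >= level) return(from)
    return(NA_real_)
  }
  kk <- k[hit]
  mean(kk + (level - d[kk]) / (d[kk + 1] - d[kk]))
}

#' Measure one event on a trace
#'
#' @param trace a `psc_trace`
#' @param onset_s event onset (s)
#' @param template the detection template (defines the decay search window,
#'   one template length after onset)
#' @param baseline_ms pre-onset window for the median baseline (ms)
#' @param peak_window_ms peak search window after onset (ms); the
#'   biexponential peak lags the onset by at most a few ms even for the
#'   slowest rises, and restricting the search keeps late noise excursions
#'   on the decay from being mistaken for the peak
#' @param polarity -1 for inward events
#' @param max_time_s optional hard end of the measurement window (s),
#'   typically the next detection's onset, so a following event is not
#'   mistaken for this event's peak or decay
#' @return one-row data.frame: `onset_s`, `peak_time_s`, `amplitude_pA`,
#'   `rise_ms`, `halfwidth_ms`, `truncated`
#' @export
measure_event <- function(trace, onset_s, template = NULL, baseline_ms = 5,
                          peak_window_ms = 12, polarity = -1,
                          max_time_s = NULL) {
  stopifnot(inherits(trace, "psc_trace"))
  fs <- trace$sampling_rate
  if (is.null(template)) template <- default_template("IPSC", fs)
  if (is.list(template) && !inherits(template, "psc_template")) {
    template <- template[[1]]
  }
  x <- trace$current
  n <- length(x)
  m <- length(template$samples)
  i0 <- floor(onset_s * fs) + 1L
  i_end <- i0 + m - 1L
  if (!is.null(max_time_s)) i_end <- min(i_end, floor(max_time_s * fs))
  if (i0 < 1 || i_end > n || i_end - i0 < 3) {
    return(data.frame(onset_s = onset_s, peak_time_s = NA_real_,
                      amplitude_pA = NA_real_, rise_ms = NA_real_,
                      halfwidth_ms = NA_real_, truncated = TRUE))
  }
  bw <- max(1L, round(baseline_ms / 1000 * fs))
  b_idx <- max(1L, i0 - bw):max(1L, i0 - 1L)
  baseline <- stats::median(x[b_idx])
  win <- i0:i_end
  d <- polarity * (x[win] - baseline)
  pw <- min(length(d), max(4L, round(peak_window_ms / 1000 * fs)))
  ip <- which.max(d[seq_len(pw)])
  amp <- d[ip]
  truncated <- ip == 1L || ip == pw
  rise <- NA_real_
  hw <- NA_real_
  if (!truncated && amp > 0) {
    c20 <- .level_crossing(d, 1L, ip, 0.2 * amp)
    c80 <- .level_crossing(d, 1L, ip, 0.8 * amp)
    if (!is.na(c80) && !is.na(c20) && c80 > c20) rise <- (c80 - c20) / fs * 1000
    ch_up <- .level_crossing(d, 1L, ip, 0.5 * amp)
    # falling half crossing: search forward from the peak
    nfall <- length(d)
    kf <- ip:(nfall - 1)
    below <- which(d[kf] >= 0.5 * amp & d[kf + 1] < 0.5 * amp)
    if (length(below) == 0) {
      truncated <- TRUE  # never decays below half level within the window
    } else {
      ch_down <- .level_crossing(d, ip, nfall, 0.5 * amp)
      if (!is.na(ch_up) && !is.na(ch_down) && ch_down > ch_up) {
        hw <- (ch_down - ch_up) / fs * 1000
      }
    }
  }
  data.frame(onset_s = onset_s,
             peak_time_s = onset_s + (ip - 1) / fs,
             amplitude_pA = amp,
             rise_ms = rise,
             halfwidth_ms = hw,
             truncated = truncated)
}

#' Measure all detections on a trace
#'
#' @param trace a `psc_trace`
#' @param detections `psc_detections` from [detect_events()]
#' @param template the detection template
#' @param condition,event_class labels copied onto every row
#' @inheritParams measure_event
#' @return data.frame of measured (unfiltered) events, one row per detection,
#'   with the detection correlation attached
#' @export
measure_events <- function(trace, detections, template = NULL,
                           condition = NA_character_,
                           event_class = NA_character_,
                           baseline_ms = 5, peak_window_ms = 12,
                           polarity = -1) {
  if (is.null(template)) template <- detection_templates("IPSC", trace$sampling_rate)
  n_det <- nrow(detections)
  rows <- lapply(seq_len(n_det), function(k) {
    nxt <- if (k < n_det) detections$onset_s[k + 1] else NULL
    measure_event(trace, detections$onset_s[k], template,
                  baseline_ms = baseline_ms, peak_window_ms = peak_window_ms,
                  polarity = polarity, max_time_s = nxt)
  })
  out <- if (n_det > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  if (is.null(out)) {
    out <- data.frame(onset_s = numeric(0), peak_time_s = numeric(0),
                      amplitude_pA = numeric(0), rise_ms = numeric(0),
                      halfwidth_ms = numeric(0), truncated = logical(0))
  }
  k <- nrow(out)
  out$correlation <- detections$correlation[seq_len(k)]
  out$cell_id <- rep(trace$cell_id, k)
  out$condition <- rep(condition, k)
  out$event_class <- rep(event_class, k)
  out$duration_s <- rep(trace$duration, k)
  out
}

#' Apply the event acceptance filters
#'
#' Accepts events satisfying all of: correlation > `min_correlation`,
#' amplitude > `min_amplitude` pA, 20--80% rise time < `max_rise_ms`, and
#' halfwidth > rise time. The rejection reason records the first failed
#' criterion in that order; truncated or unmeasurable events are rejected
#' outright.
#'
#' @param events measured events (from [measure_events()] or a compatible
#'   data.frame with `amplitude_pA`, `rise_ms`, `halfwidth_ms`,
#'   `correlation` columns)
#' @param min_correlation,min_amplitude,max_rise_ms filter thresholds
#' @return the events with logical `accepted` and character `reject_reason`
#'   columns, class `psc_events`
#' @export
filter_events <- function(events, min_correlation = 0.6, min_amplitude = 3,
                          max_rise_ms = 5) {
  ev <- as.data.frame(events)
  n <- nrow(ev)
  truncated <- if ("truncated" %in% names(ev)) ev$truncated else rep(FALSE, n)
  truncated <- truncated | !is.finite(ev$rise_ms) | !is.finite(ev$halfwidth_ms) |
    !is.finite(ev$amplitude_pA)
  reason <- rep(NA_character_, n)
  reason[truncated] <- "truncated"
  todo <- is.na(reason) & !(ev$correlation > min_correlation)
  reason[todo] <- "correlation"
  todo <- is.na(reason) & !(ev$amplitude_pA > min_amplitude)
  reason[todo] <- "amplitude"
  todo <- is.na(reason) & !(ev$rise_ms < max_rise_ms)
  reason[todo] <- "rise_time"
  todo <- is.na(reason) & !(ev$halfwidth_ms > ev$rise_ms)
  reason[todo] <- "halfwidth"
  ev$accepted <- is.na(reason)
  ev$reject_reason <- reason
  class(ev) <- c("psc_events", "data.frame")
  ev
}

#' Accepted events of a table
#' @param events a `psc_events` table
#' @return the accepted rows
#' @export
accepted_events <- function(events) {
  if (!"accepted" %in% names(events)) return(events)
  events[events$accepted, , drop = FALSE]
}

#' Interevent intervals for one cell
#'
#' Successive differences of the accepted onsets of one cell, in seconds.
#'
#' @param events a `psc_events` table
#' @param cell_id the cell; default: `events` must contain a single cell
#' @return numeric vector of IEIs (s); empty, with a warning, for fewer than
#'   two accepted events
#' @export
interevent_intervals <- function(events, cell_id = NULL) {
  ev <- accepted_events(events)
  if (!is.null(cell_id)) ev <- ev[ev$cell_id == cell_id, , drop = FALSE]
  if (length(unique(ev$cell_id)) > 1) {
    stop("multiple cells present; pass cell_id", call. = FALSE)
  }
  on <- sort(ev$onset_s)
  if (length(on) < 2) {
    warning("fewer than 2 accepted events; no interevent intervals",
            call. = FALSE)
    return(numeric(0))
  }
  diff(on)
}

#' Pooled interevent intervals across cells
#'
#' IEIs are computed within each cell and pooled; intervals never span cells.
#'
#' @param events a `psc_events` table
#' @return numeric vector of IEIs (s)
#' @export
pooled_ieis <- function(events) {
  ev <- accepted_events(events)
  unlist(lapply(split(ev$onset_s, ev$cell_id), function(on) {
    on <- sort(on)
    if (length(on) < 2) numeric(0) else diff(on)
  }), use.names = FALSE)
}

#' Write / read an event table as CSV
#'
#' @param events a `psc_events` table
#' @param path CSV file path
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(ev) <- c("psc_events", "data.frame")
  ev
}
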