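# Biexponential (difference-of-exponentials) PSC kernel utilities.
# All kernel math is done in milliseconds; the simulator converts to samples.

#' Peak time of the biexponential kernel
#'
#' For the kernel \eqn{g(t) = e^{-t/\tau_d} - e^{-t/\tau_r}} the peak occurs at
#' \eqn{t_{peak} = \tau_r \tau_d / (\tau_d - \tau_r) \cdot \ln(\tau_d/\tau_r)}.
#'
#' @param tau_r rise time constant (ms), must be < `tau_d`
#' @param tau_d decay time constant (ms)
#' @return peak time in ms
#' @export
biexp_peak_time <- function(tau_r, tau_d) {
  check_kernel_constants(tau_r, tau_d)
  (tau_r * tau_d) / (tau_d - tau_r) * log(tau_d / tau_r)
}

check_kernel_constants <- function(tau_r, tau_d) {
  if (any(!is.finite(tau_r)) || any(!is.finite(tau_d)) ||
      any(tau_r <= 0) || any(tau_d <= 0)) {
    stop("kernel time constants must be positive and finite", call. = FALSE)
  }
  if (any(tau_r >= tau_d)) {
    stop("invalid template: rise constant must be smaller than decay constant",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate the peak-normalized biexponential kernel
#'
#' Returns \eqn{g(t)/g(t_{peak})}, zero for `t < 0`, so the kernel peaks at
#' exactly 1. This normalization is what guarantees that a rendered event's
#' peak excursion equals its nominal amplitude.
#'
#' @param t times (ms) at which to evaluate
#' @inheritParams biexp_peak_time
#' @return kernel values in \[0, 1\]
#' @export
biexp_kernel <- function(t, tau_r, tau_d) {
  check_kernel_constants(tau_r, tau_d)
  tp <- biexp_peak_time(tau_r, tau_d)
  norm <- exp(-tp / tau_d) - exp(-tp / tau_r)
  g <- ifelse(t < 0, 0, (exp(-t / tau_d) - exp(-t / tau_r)) / norm)
  g
}

# Time at which the rising phase of the normalized kernel crosses `level`
# (level in (0, 1)); root-found on the continuous kernel, so not quantized.
biexp_rise_crossing <- function(level, tau_r, tau_d) {
  tp <- biexp_peak_time(tau_r, tau_d)
  stats::uniroot(function(t) biexp_kernel(t, tau_r, tau_d) - level,
                 lower = 0, upper = tp, tol = 1e-12)$root
}

#' Continuous 20--80% rise time of the biexponential kernel
#'
#' @inheritParams biexp_peak_time
#' @return 20--80% rise time in ms
#' @export
biexp_rise_20_80 <- function(tau_r, tau_d) {
  biexp_rise_crossing(0.8, tau_r, tau_d) - biexp_rise_crossing(0.2, tau_r, tau_d)
}

#' Continuous halfwidth (FWHM) of the biexponential kernel
#'
#' @inheritParams biexp_peak_time
#' @return full width at half maximum in ms
#' @export
biexp_halfwidth <- function(tau_r, tau_d) {
  tp <- biexp_peak_time(tau_r, tau_d)
  t_up <- biexp_rise_crossing(0.5, tau_r, tau_d)
  upper <- tp + 20 * tau_d
  t_down <- stats::uniroot(function(t) biexp_kernel(t, tau_r, tau_d) - 0.5,
                           lower = tp, upper = upper, tol = 1e-12)$root
  t_down - t_up
}

#' Solve for the rise constant giving a target 20--80% rise time
#'
#' The simulator parameterizes event kinetics by the observable 20--80% rise
#' time; this inverts [biexp_rise_20_80()] numerically for fixed `tau_d`.
#'
#' @param rise_ms target 20--80% rise time (ms)
#' @param tau_d decay time constant (ms)
#' @return rise time constant `tau_r` (ms)
#' @export
tau_r_for_rise <- function(rise_ms, tau_d) {
  if (rise_ms <= 0) stop("rise time must be positive", call. = FALSE)
  lo <- tau_d * 1e-5
  hi <- tau_d * 0.999
  f <- function(tr) biexp_rise_20_80(tr, tau_d) - rise_ms
  if (f(hi) < 0) {
    stop(sprintf("target rise time %.3g ms unattainable with decay %.3g ms",
                 rise_ms, tau_d), call. = FALSE)
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
}

# halfwidth as a function of tau_r, cached per decay constant (spline over a
# log grid); used where halfwidths are needed for thousands of events
biexp_halfwidth_fast <- function(tau_r, tau_d) {
  key <- sprintf("hw_%.9g", tau_d)
  fn <- get0(key, envir = .tau_r_interp_cache)
  if (is.null(fn)) {
    grid <- tau_d * exp(seq(log(1e-4), log(0.995), length.out = 120))
    hw <- vapply(grid, biexp_halfwidth, numeric(1), tau_d = tau_d)
    fn <- stats::splinefun(grid, hw, method = "hyman")
    assign(key, fn, envir = .tau_r_interp_cache)
  }
  fn(tau_r)
}

# monotone-spline inverse of biexp_rise_20_80 in tau_r, cached per decay
# constant; accurate to ~1e-6 ms over the attainable rise range and much
# faster than root-finding per event
.tau_r_interp_cache <- new.env(parent = emptyenv())

psckit_tau_r <- function(rise_ms, tau_d) {
  key <- sprintf("%.9g", tau_d)
  fn <- get0(key, envir = .tau_r_interp_cache)
  if (is.null(fn)) {
    grid <- tau_d * exp(seq(log(1e-4), log(0.995), length.out = 160))
    rg <- vapply(grid, biexp_rise_20_80, numeric(1), tau_d = tau_d)
    fn <- stats::splinefun(rg, grid, method = "hyman")
    assign(key, fn, envir = .tau_r_interp_cache)
  }
  fn(rise_ms)
}

# Deterministic fan-out of one master seed into per-stage / per-cell seeds.
# Linear congruential mixing kept below 2^31 so arithmetic stays exact in
# doubles; string keys are folded to integers first.
fanout_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (key in list(...)) {
    k <- if (is.character(key)) {
      sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% m
    } else {
      as.numeric(key) %% m
    }
    x <- (x * 1103 + k + 12345) %% m
  }
  as.integer(x)
}
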