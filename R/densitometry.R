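# Relative optical density (ROD) quantification of immunofluorescence.
#
# Grey values (8-bit, 0-255) measured in hippocampal subfields are converted
# to relative optical densities after background subtraction:
#   ROD = log10(256 / (255 - grey))
# and averaged up the sampling hierarchy (cryotome section -> vibratome
# section -> mouse) so that the group statistics are computed on one value
# per mouse.

#' Convert a grey value to relative optical density
#'
#' The background (from an immunonegative reference region of the same
#' section) is subtracted from the grey value before conversion. A
#' background-subtracted value of 255 would saturate the formula (division by
#' zero) and raises an error; negative values (background brighter than the
#' region) are clamped to zero with a warning by default, or rejected.
#'
#' @param grey grey value(s) in \[0, 255\]
#' @param background background grey value(s), same scale
#' @param negative handling of negative background-subtracted values:
#'   `"clamp"` (to zero, with a warning) or `"reject"` (error)
#' @return ROD value(s); strictly increasing in `grey`
#' @export
rod_from_grey <- function(grey, background = 0, negative = c("clamp", "reject")) {
  negative <- match.arg(negative)
  net <- grey - background
  if (any(net >= 255)) {
    stop("saturation: background-subtracted grey value >= 255", call. = FALSE)
  }
  if (any(net < 0)) {
    if (negative == "reject") {
      stop("negative background-subtracted grey value", call. = FALSE)
    }
    warning(sprintf("%d negative background-subtracted grey value(s) clamped to 0",
                    sum(net < 0)), call. = FALSE)
    net <- pmax(net, 0)
  }
  log10(256 / (255 - net))
}

#' Hierarchical ROD averaging
#'
#' Implements the nested averaging of the sampling design: ROD values from
#' the cryotome sections of one vibratome section are averaged first, the
#' vibratome-section means of one mouse are averaged next, and the group
#' statistics (mean, SEM) are computed over mice. Unbalanced designs average
#' over whatever children are present.
#'
#' @param measurements data.frame with columns `mouse_id`, `vibratome_id`,
#'   `cryotome_id`, `grey`, `background` (and optionally `region`,
#'   `condition` used for subsetting)
#' @param condition,region optional filters
#' @param negative passed to [rod_from_grey()]
#' @return list with `mice` (per-mouse mean ROD), `mean`, `sem`, `n`
#' @export
hierarchical_mean <- function(measurements, condition = NULL, region = NULL,
                              negative = "clamp") {
  m <- as.data.frame(measurements)
  if (!is.null(condition)) m <- m[m$condition == condition, , drop = FALSE]
  if (!is.null(region)) m <- m[m$region == region, , drop = FALSE]
  if (nrow(m) == 0) stop("no measurements selected", call. = FALSE)
  keys <- c("mouse_id", "vibratome_id", "cryotome_id")
  if (!all(keys %in% names(m))) {
    stop("hierarchy keys mouse_id/vibratome_id/cryotome_id required",
         call. = FALSE)
  }
  if (any(is.na(m[keys]) | m[keys] == "")) {
    stop("orphan measurement: incomplete hierarchy keys", call. = FALSE)
  }
  m$rod <- rod_from_grey(m$grey, m$background, negative = negative)
  vib <- stats::aggregate(rod ~ mouse_id + vibratome_id, data = m, FUN = mean)
  mice <- stats::aggregate(rod ~ mouse_id, data = vib, FUN = mean)
  vals <- stats::setNames(mice$rod, mice$mouse_id)
  n <- length(vals)
  list(mice = vals,
       mean = mean(vals),
       sem = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
       n = n)
}

#' Treated mean as a percentage of the control mean
#'
#' @param treated_mean,control_mean group mean RODs; `control_mean` > 0
#' @return integer percent, rounded half-up
#' @export
relative_percent <- function(treated_mean, control_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0", call. = FALSE)
  floor(100 * treated_mean / control_mean + 0.5)
}

#' Two-sample Student's t-test on per-mouse means
#'
#' Equal-variance two-sided Student's t. Degenerate zero-variance inputs are
#' handled explicitly: identical groups give p = 1, perfectly separated
#' constant groups give p = 0.
#'
#' @param a_mouse_means,b_mouse_means numeric vectors (>= 2 values each)
#' @param alpha significance level for the flag (default .05)
#' @return list with `t`, `df`, `p`, `significant`
#' @export
group_t_test <- function(a_mouse_means, b_mouse_means, alpha = 0.05) {
  a <- a_mouse_means; b <- b_mouse_means
  if (length(a) < 2 || length(b) < 2) {
    stop("at least 2 values per group are required", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    t <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    return(list(t = t, df = length(a) + length(b) - 2, p = p,
                significant = p < alpha))
  }
  res <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, significant = res$p.value < alpha)
}

#' Region-by-region densitometry comparison table
#'
#' Mirrors the layout of a per-region immunoreactivity table: control and
#' treated group mean +/- SEM (over mice), the treated mean as a percent of
#' control, and the Student's t p-value.
#'
#' @param measurements data.frame as in [hierarchical_mean()], containing
#'   both conditions
#' @param control,treated condition labels
#' @param negative passed to [rod_from_grey()]
#' @return data.frame with one row per region
#' @export
rod_group_table <- function(measurements, control = "aCSF",
                            treated = "treated", negative = "clamp") {
  regions <- unique(measurements$region)
  do.call(rbind, lapply(regions, function(rg) {
    hc <- hierarchical_mean(measurements, condition = control, region = rg,
                            negative = negative)
    ht <- hierarchical_mean(measurements, condition = treated, region = rg,
                            negative = negative)
    tt <- group_t_test(hc$mice, ht$mice)
    data.frame(region = rg,
               control_mean = hc$mean, control_sem = hc$sem, n_control = hc$n,
               treated_mean = ht$mean, treated_sem = ht$sem, n_treated = ht$n,
               percent = relative_percent(ht$mean, hc$mean),
               p = tt$p)
  }))
}
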