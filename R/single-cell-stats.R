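#' Per-cell elongation rate from a length timeseries
#'
#' The elongation rate is the ordinary-least-squares slope of
#' `ln(length_um)` against `time_min`; exponential growth appears as a
#' straight line on this scale, so the slope estimates the instantaneous
#' relative growth rate (1/min).
#'
#' @param time_min Numeric vector of observation times (min).
#' @param length_um Positive cell lengths (µm), same length as `time_min`.
#' @return A list with `rate_per_min`, `r_squared` (`NA` when the lengths
#'   are constant) and `n_frames`. Fewer than 3 frames is an error; use
#'   [elongation_rates()] for bulk estimation with automatic exclusion.
#' @examples
#' t <- 0:5
#' elongation_rate(t, 2 * exp(0.02 * t))
#' @export
elongation_rate <- function(time_min, length_um) {
  if (length(time_min) != length(length_um))
    stop("`time_min` and `length_um` must have equal length.", call. = FALSE)
  if (length(time_min) < 3L)
    stop("at least 3 frames are required to estimate an elongation rate.",
         call. = FALSE)
  if (any(length_um <= 0)) stop("lengths must be > 0.", call. = FALSE)
  y <- log(length_um)
  tm <- time_min - mean(time_min)
  ym <- y - mean(y)
  sxx <- sum(tm^2)
  if (sxx == 0) stop("observation times are all identical.", call. = FALSE)
  slope <- sum(tm * ym) / sxx
  sst <- sum(ym^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum((ym - slope * tm)^2) / sst
  list(rate_per_min = slope, r_squared = r2, n_frames = length(time_min))
}

#' Elongation rates for every tracked cell
#'
#' Joins a tracking result with its observation table and fits
#' [elongation_rate()] per track. Tracks spanning a break time (by default
#' the treatment window bounds) are split at the break so that each
#' estimate reflects a single treatment phase; each segment is stamped
#' with its mid-time. Segments with fewer than `min_frames` points are
#' flagged invalid (`valid = FALSE`) and excluded from downstream averages.
#'
#' @param observations Observation data.frame ([simulate_trench()] dialect).
#' @param tracked Tracking result from [track_trenches()] (or the
#'   `assignments` element of [observable_forest()] wrapped in a list) —
#'   anything with an `assignments` data.frame linking
#'   `trench_id`/`frame`/`rank` to `cell_id`.
#' @param breaks Numeric vector of times (min) at which tracks are split;
#'   `NULL` for no splitting.
#' @param min_frames Minimum points per segment.
#' @param shrink_split_tol A track whose length drops by more than this
#'   relative tolerance between consecutive frames is split there: such a
#'   drop marks a division whose second daughter left unobserved (the
#'   track continues through one daughter), i.e. a new cell cycle, not
#'   shrinkage. Without the split the embedded halving biases the fitted
#'   slope downward.
#' @return data.frame with `trench_id`, `cell_id`, `segment`, `t_mid`,
#'   `rate_per_min`, `r_squared`, `n_frames`, `valid`.
#' @export
elongation_rates <- function(observations, tracked, breaks = c(90, 270),
                             min_frames = 3L, shrink_split_tol = 0.15) {
  asg <- tracked$assignments
  key_obs <- paste(observations$trench_id, observations$frame,
                   observations$rank)
  key_asg <- paste(asg$trench_id, asg$frame, asg$rank)
  idx <- match(key_obs, key_asg)
  if (anyNA(idx))
    stop("assignments do not cover all observation rows.", call. = FALSE)
  df <- data.frame(trench_id = observations$trench_id,
                   cell_id = asg$cell_id[idx],
                   time_min = observations$time_min,
                   length_um = observations$length_um)
  brk <- sort(unique(breaks))
  df$segment <- if (length(brk))
    findInterval(df$time_min, brk, left.open = FALSE) + 1L else 1L
  df <- df[order(df$trench_id, df$cell_id, df$time_min), , drop = FALSE]
  # split collapsed tracks at sudden length drops (hidden division)
  same_cell <- c(FALSE, df$trench_id[-1] == df$trench_id[-nrow(df)] &
                   df$cell_id[-1] == df$cell_id[-nrow(df)])
  drop_here <- same_cell &
    c(FALSE, log(df$length_um[-1] / df$length_um[-nrow(df)]) <
        -log(1 + shrink_split_tol))
  cycle <- stats::ave(as.integer(drop_here),
                      paste(df$trench_id, df$cell_id), FUN = cumsum)
  parts <- split(df, list(df$trench_id, df$cell_id, df$segment, cycle),
                 drop = TRUE)
  out <- lapply(parts, function(d) {
    n <- nrow(d)
    if (n < max(min_frames, 3L)) {
      est <- list(rate_per_min = NA_real_, r_squared = NA_real_,
                  n_frames = n)
      valid <- FALSE
    } else {
      est <- elongation_rate(d$time_min, d$length_um)
      valid <- is.finite(est$rate_per_min)
    }
    data.frame(trench_id = d$trench_id[1L], cell_id = d$cell_id[1L],
               segment = d$segment[1L],
               t_mid = mean(range(d$time_min)),
               rate_per_min = est$rate_per_min,
               r_squared = est$r_squared, n_frames = est$n_frames,
               valid = valid)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$trench_id, res$cell_id, res$segment), , drop = FALSE]
}

#' Sliding-window population growth-rate timeseries
#'
#' Mean and standard deviation of per-cell elongation rates against time,
#' computed in sliding windows over the estimates' mid-times. Windows with
#' no valid estimate yield `NA`, never zero.
#'
#' @param estimates Output of [elongation_rates()].
#' @param window_width Window width (min).
#' @param step Distance between window centres (min); defaults to half the
#'   width.
#' @param t_range Optional `c(min, max)` time range; defaults to the range
#'   of the estimates.
#' @return data.frame with `time_min` (window centre), `mean_rate`,
#'   `sd_rate`, `n_cells`.
#' @export
growth_timeseries <- function(estimates, window_width = 30, step = NULL,
                              t_range = NULL) {
  est <- estimates[estimates$valid, , drop = FALSE]
  if (is.null(step)) step <- window_width / 2
  if (is.null(t_range)) t_range <- range(est$t_mid)
  centres <- seq(t_range[1L], t_range[2L], by = step)
  rows <- lapply(centres, function(ct) {
    sel <- est$t_mid >= ct - window_width / 2 &
      est$t_mid < ct + window_width / 2
    r <- est$rate_per_min[sel]
    data.frame(time_min = ct,
               mean_rate = if (length(r)) mean(r) else NA_real_,
               sd_rate = if (length(r) > 1L) stats::sd(r) else NA_real_,
               n_cells = length(r))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Mean elongation rate inside a time window
#'
#' Replicate-level summary of the sliding-window series: the mean of valid
#' per-cell rates whose mid-times fall in `window` (e.g. `c(250, 300)` for
#' a late-treatment/recovery comparison across replicates).
#'
#' @param estimates Output of [elongation_rates()].
#' @param window `c(start, end)` in minutes.
#' @return Mean rate (1/min), `NA` if the window is empty.
#' @export
window_mean_rate <- function(estimates, window) {
  est <- estimates[estimates$valid, , drop = FALSE]
  sel <- est$t_mid >= window[1L] & est$t_mid < window[2L]
  if (!any(sel)) return(NA_real_)
  mean(est$rate_per_min[sel])
}

#' Lysis frequency of lineages in a time window
#'
#' The summary plotted per replicate in single-cell lysis analyses:
#' `frequency = n_events / (n_lineages * window_hours)`, counting every
#' lineage alive at any point in the window in the denominator and every
#' lysis event inside the window in the numerator. Note this is a
#' per-lineage normalisation, not a per-cell-hour exposure; use
#' [lysis_rate()] to estimate the underlying per-cell lysis rate.
#'
#' @param records Lineage records ([track_trench()] schema).
#' @param window `c(start, end)` in minutes.
#' @param frame_interval Minutes per frame (to convert frames to time).
#' @param condition Optional label stored in the output.
#' @return A list with `condition`, `window_min`, `n_lineages`, `n_events`,
#'   `frequency` (events per lineage per hour).
#' @examples
#' rec <- data.frame(cell_id = 1:3, trench_id = 1, parent_id = NA,
#'                   birth_frame = 0, last_frame = c(50, 120, 180),
#'                   fate = c("divided", "lysed", "censored"))
#' lysis_frequency(rec, window = c(0, 180))
#' @export
lysis_frequency <- function(records, window, frame_interval = 1,
                            condition = NA_character_) {
  birth_min <- records$birth_frame * frame_interval
  death_min <- (records$last_frame + 1) * frame_interval
  alive <- birth_min < window[2L] & death_min > window[1L]
  n_lineages <- sum(alive)
  if (n_lineages == 0L)
    stop("no lineages alive in the requested window.", call. = FALSE)
  lysed <- records$fate == "lysed" &
    death_min > window[1L] & death_min <= window[2L]
  n_events <- sum(lysed)
  hours <- (window[2L] - window[1L]) / 60
  list(condition = condition, window_min = window,
       n_lineages = n_lineages, n_events = n_events,
       frequency = n_events / (n_lineages * hours))
}

#' Per-cell lysis rate with exact Poisson confidence interval
#'
#' Estimates the lysis hazard in events per cell per hour from the true
#' exposure: the summed time each lineage spends inside the window. The
#' exact (Garwood) 95% interval comes from [stats::poisson.test()].
#'
#' @inheritParams lysis_frequency
#' @return A list with `rate` (events/cell/h), `ci` (95% CI), `n_events`,
#'   `exposure_cell_hours`.
#' @export
lysis_rate <- function(records, window, frame_interval = 1) {
  birth_min <- records$birth_frame * frame_interval
  death_min <- (records$last_frame + 1) * frame_interval
  overlap <- pmax(0, pmin(death_min, window[2L]) -
                    pmax(birth_min, window[1L]))
  exposure_h <- sum(overlap) / 60
  if (exposure_h <= 0)
    stop("no cell exposure in the requested window.", call. = FALSE)
  lysed <- records$fate == "lysed" &
    death_min > window[1L] & death_min <= window[2L]
  n_events <- sum(lysed)
  pt <- stats::poisson.test(n_events, T = exposure_h)
  list(rate = n_events / exposure_h, ci = as.numeric(pt$conf.int),
       n_events = n_events, exposure_cell_hours = exposure_h)
}

#' Compare two groups of replicate-level summaries
#'
#' Welch two-sample t-test on replicate means. The replicate — not the
#' cell — is the unit of inference, avoiding pseudoreplication from the
#' thousands of correlated single-cell measurements within a replicate.
#'
#' @param values_a,values_b Numeric vectors of replicate-level values
#'   (>= 2 each).
#' @return A list with `difference` (mean a − mean b), `conf_int`,
#'   `t_statistic`, `df`, `p_value`.
#' @examples
#' compare_replicates(c(0.028, 0.029, 0.027), c(0.024, 0.023, 0.025))
#' @export
compare_replicates <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("at least 2 replicate values per group are required.",
         call. = FALSE)
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(difference = mean(values_a) - mean(values_b),
       conf_int = as.numeric(tt$conf.int),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
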