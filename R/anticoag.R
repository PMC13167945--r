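#' Rosendaal time in therapeutic range
#'
#' Linear-interpolation TTR: the INR is assumed to change linearly between
#' consecutive measurements, each inter-visit segment's time is allocated to
#' in-range/out-of-range exactly from the boundary-crossing points, and
#' TTR is 100 x (in-range time) / (counted time). The target interval is
#' closed — an interpolated INR exactly on a range limit counts as in
#' range. Segments whose day gap exceeds `max_gap` are excluded from both
#' numerator and denominator (interpolation over long gaps is meaningless).
#' With fewer than two usable measurements the TTR is undefined (`NA`).
#'
#' @param days strictly increasing measurement days.
#' @param inrs INR measurements (same length as `days`).
#' @param target therapeutic range `c(low, high)` (see
#'   [assign_target_range()]).
#' @param max_gap maximum interpolated day gap (default 56).
#' @return TTR percentage in `[0, 100]`, or `NA_real_`.
#' @export
#' @examples
#' rosendaal_ttr(c(0, 10), c(2.0, 3.0), c(2.0, 2.5)) # crosses 2.5 at day 5
rosendaal_ttr <- function(days, inrs, target, max_gap = 56) {
  stopifnot(length(days) == length(inrs))
  if (length(days) < 2L) return(NA_real_)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  lo <- target[[1L]]
  hi <- target[[2L]]
  total <- 0
  inrange <- 0
  for (k in seq_len(length(days) - 1L)) {
    gap <- days[k + 1L] - days[k]
    if (gap > max_gap) next
    total <- total + gap
    inrange <- inrange + gap * segment_fraction_in_range(inrs[k],
                                                         inrs[k + 1L],
                                                         lo, hi)
  }
  if (total <= 0) return(NA_real_)
  100 * inrange / total
}

# Fraction of a unit-time linear segment from INR `a` to `b` spent inside
# the closed interval [lo, hi]; exact from the crossing points.
segment_fraction_in_range <- function(a, b, lo, hi) {
  if (a == b) return(as.numeric(a >= lo & a <= hi))
  # u in [0,1] with inr(u) = a + (b - a) u; in-range u-set is an interval
  u_at <- function(level) (level - a) / (b - a)
  u1 <- u_at(lo)
  u2 <- u_at(hi)
  lo_u <- min(u1, u2)
  hi_u <- max(u1, u2)
  max(0, min(hi_u, 1) - max(lo_u, 0))
}

#' Proportions of INR measurements in, above and below range
#'
#' Measurement-wise proportions (not time-weighted), reported to one
#' decimal with half-up rounding; the closed target interval counts
#' boundary values as in range.
#'
#' @param inrs pooled INR measurements.
#' @param target `c(low, high)`.
#' @return list with `counts` (in/above/below), `pct` and `n`.
#' @export
#' @examples
#' inr_proportions(c(2.2, 2.4, 3.1, 1.8), c(2.0, 2.5))
inr_proportions <- function(inrs, target) {
  if (length(inrs) == 0L) stop("no INR measurements", call. = FALSE)
  lo <- target[[1L]]
  hi <- target[[2L]]
  counts <- c(in_range = sum(inrs >= lo & inrs <= hi),
              above = sum(inrs > hi),
              below = sum(inrs < lo))
  list(counts = counts,
       pct = round_half_up(100 * counts / length(inrs), 1),
       n = length(inrs))
}

#' Per-patient TTR over a cohort
#'
#' @param cohort a `warf_cohort`.
#' @param max_gap passed to [rosendaal_ttr()].
#' @return data.frame with columns `patient_id`, `ttr`, `n_measurements`.
#' @export
cohort_ttr <- function(cohort, max_gap = 56) {
  rows <- lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id,
               ttr = rosendaal_ttr(p$visits$day, p$visits$inr, p$target,
                                   max_gap = max_gap),
               n_measurements = nrow(p$visits))
  })
  do.call(rbind, rows)
}

#' Interval-stratified anticoagulation summary
#'
#' Start-anchored windows (default 0--30, 0--60, 0--90 days): measurements
#' with `day <= bound` contribute to the measurement-wise proportions, and
#' interpolation segments straddling the bound are clipped at it (the
#' clipped endpoint takes the interpolated INR). Per window the cohort TTR
#' is aggregated per patient and summarized as median and IQR; proportions
#' pool all in-window measurements.
#'
#' @param cohort a `warf_cohort`.
#' @param windows upper day bounds of the start-anchored windows.
#' @param max_gap passed to [rosendaal_ttr()].
#' @return data.frame with one row per window: `window`, `median_ttr`,
#'   `ttr_q1`, `ttr_q3`, `n_patients`, `pct_in`, `pct_above`, `pct_below`,
#'   `n_measurements`.
#' @export
windowed_summary <- function(cohort, windows = c(30, 60, 90), max_gap = 56) {
  rows <- lapply(windows, function(w) {
    ttrs <- numeric(0)
    pooled <- numeric(0)
    targets_lo <- numeric(0)
    for (p in cohort) {
      cl <- clip_series(p$visits$day, p$visits$inr, w)
      if (length(cl$days) >= 1L) {
        meas <- cl$days <= w & cl$measured # only true measurements pooled
        pr <- inr_proportions_safe(cl$inrs[meas], p$target)
        pooled <- c(pooled, pr)
      }
      ttrs <- c(ttrs, rosendaal_ttr2(cl, p$target, max_gap))
    }
    ttrs <- ttrs[!is.na(ttrs)]
    if (length(ttrs)) {
      q <- stats::quantile(ttrs, c(0.25, 0.5, 0.75))
    } else {
      q <- c(NA_real_, NA_real_, NA_real_)
    }
    data.frame(window = sprintf("0-%g", w),
               median_ttr = unname(q[2L]), ttr_q1 = unname(q[1L]),
               ttr_q3 = unname(q[3L]), n_patients = length(ttrs),
               pct_in = round_half_up(100 * mean(pooled == 1L), 1),
               pct_above = round_half_up(100 * mean(pooled == 2L), 1),
               pct_below = round_half_up(100 * mean(pooled == 3L), 1),
               n_measurements = length(pooled))
  })
  out <- do.call(rbind, rows)
  out$pct_in[out$n_measurements == 0] <- NA_real_
  out$pct_above[out$n_measurements == 0] <- NA_real_
  out$pct_below[out$n_measurements == 0] <- NA_real_
  out
}

# Clip a measurement series at day bound `w`; a segment straddling the
# bound contributes a synthetic endpoint with the interpolated INR.
clip_series <- function(days, inrs, w) {
  keep <- days <= w
  d <- days[keep]
  x <- inrs[keep]
  measured <- rep(TRUE, length(d))
  i <- sum(keep)
  if (i >= 1L && i < length(days) && d[i] < w) {
    d2 <- days[i + 1L]
    x2 <- inrs[i + 1L]
    xi <- x[i] + (x2 - x[i]) * (w - d[i]) / (d2 - d[i])
    d <- c(d, w)
    x <- c(x, xi)
    measured <- c(measured, FALSE)
  }
  list(days = d, inrs = x, measured = measured)
}

rosendaal_ttr2 <- function(cl, target, max_gap) {
  if (length(cl$days) < 2L) return(NA_real_)
  rosendaal_ttr(cl$days, cl$inrs, target, max_gap)
}

# classify each measurement 1 = in range, 2 = above, 3 = below
inr_proportions_safe <- function(inrs, target) {
  if (!length(inrs)) return(integer(0))
  ifelse(inrs >= target[[1L]] & inrs <= target[[2L]], 1L,
         ifelse(inrs > target[[2L]], 2L, 3L))
}
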