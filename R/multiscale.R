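#' Cumulative histogram of quiet-sleep periods
#'
#' For every duration `d` on a descending grid (60 min down to 1 min by
#' default), computes the percentage of recording time spent in quiet-sleep
#' runs lasting at least `d`. Reading the curve from long to short periods,
#' it is non-decreasing and reaches the total share of quiet sleep held in
#' runs of one minute or more; the displacement and absence shares complete
#' the recording beyond the 1-min point. An occasional interruption of a run
#' longer than the left edge of the grid does not affect the estimate, since
#' such runs contribute their full length at every grid point.
#'
#' @param labels A `state_labels` object (or character vector) produced with
#'   the same `min_qs_s` the curve is meant to display.
#' @param grid_min Descending integer grid of durations in minutes
#'   (default `60:1`).
#' @return An object of class `qs_curve`: list with `duration_min`,
#'   `cum_pct`, and the completion shares `qs_pct`, `ds_pct`, `di_pct`,
#'   `abs_pct`.
#' @export
qs_cumulative_curve <- function(labels, grid_min = 60:1) {
  lab <- label_values(labels)
  if (length(lab) == 0L) stop("empty labels")
  if (length(grid_min) < 1L || any(grid_min <= 0)) {
    stop("`grid_min` must be positive durations in minutes")
  }
  grid_min <- sort(unique(round(grid_min)), decreasing = TRUE)
  n <- length(lab)
  runs <- state_runs(lab)
  qs_len <- runs$duration_s[runs$state == "QS"]
  cum <- vapply(grid_min, function(d) {
    100 * sum(qs_len[qs_len >= d * 60]) / n
  }, numeric(1))
  idx <- summarize_states(lab)
  structure(list(duration_min = grid_min, cum_pct = cum,
                 qs_pct = idx$qs_pct, ds_pct = idx$ds_pct,
                 di_pct = idx$di_pct, abs_pct = idx$abs_pct),
            class = "qs_curve")
}

#' @export
print.qs_curve <- function(x, ...) {
  cat(sprintf(paste0("<qs_curve> grid %d..%d min; cum %% at ends: ",
                     "%.2f (long) -> %.2f (short); DI %.2f%%, ABS %.2f%%\n"),
              max(x$duration_min), min(x$duration_min),
              x$cum_pct[1L], x$cum_pct[length(x$cum_pct)],
              x$di_pct, x$abs_pct))
  invisible(x)
}

#' Plot a quiet-sleep cumulative curve
#'
#' Mirrors the usual presentation: the x axis runs from long to short
#' quiet-sleep durations and the displacement / absence shares are appended
#' after the 1-min point to complete 100% of the recording.
#'
#' @param x A `qs_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qs_curve <- function(x, ...) {
  k <- length(x$duration_min)
  xs <- c(x$duration_min, 0, -max(2, 0.05 * max(x$duration_min)))
  ys <- c(x$cum_pct, x$cum_pct[k] + x$di_pct, x$cum_pct[k] + x$di_pct + x$abs_pct)
  graphics::plot(xs, ys, type = "s", xlim = rev(range(xs)),
                 xlab = "QS period duration (min)",
                 ylab = "cumulative % of recording", ylim = c(0, 100), ...)
  graphics::abline(h = 100, lty = 3, col = "grey")
  invisible(x)
}

#' Maximum-slope point of the cumulative curve
#'
#' Returns the grid duration at which the increment of the cumulative curve
#' toward the next-shorter duration is largest. This step-up marks the
#' characteristic period of repeated sleep disturbances: quiet-sleep runs
#' shorter than it dominate the fragmentation. Ties are broken toward the
#' longer duration; a flat curve returns `NA`.
#'
#' @param curve A `qs_curve` on at least two grid points.
#' @return Duration in minutes (single numeric), or `NA_real_` for a flat
#'   curve.
#' @export
max_slope_point <- function(curve) {
  stopifnot(inherits(curve, "qs_curve"))
  k <- length(curve$duration_min)
  if (k < 2L) stop("curve needs at least 2 grid points")
  inc <- diff(curve$cum_pct)            # increment toward shorter durations
  if (all(inc <= 0)) return(NA_real_)
  curve$duration_min[which.max(inc)]
}

#' Displacement-duration distributions across thresholds
#'
#' For each candidate threshold, collects the maximal runs of per-second
#' power strictly above it and tabulates the run durations as a probability
#' mass function. Used to characterize the typical displacement length
#' (e.g. the ~5 s bursts of apneic movement) when choosing the power window
#' and displacement threshold.
#'
#' @param power A `power_series` or numeric vector of per-second power of a
#'   normalized envelope.
#' @param thresholds Candidate thresholds on the normalized power scale
#'   (default `c(0.01, 0.05, 0.1, 0.2, 0.3, 0.35, 0.5)`).
#' @return Named list (one element per threshold) of data frames with
#'   columns `duration_s`, `count`, `prob`. A threshold never exceeded
#'   yields a zero-row data frame.
#' @export
di_duration_pdf <- function(power,
                            thresholds = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.35, 0.5)) {
  v <- power_values(power)
  out <- lapply(thresholds, function(th) {
    r <- rle(v > th)
    dur <- r$lengths[r$values]
    if (length(dur) == 0L) {
      return(data.frame(duration_s = integer(), count = integer(),
                        prob = numeric()))
    }
    tab <- table(dur)
    data.frame(duration_s = as.integer(names(tab)),
               count = as.integer(tab),
               prob = as.numeric(tab) / sum(tab))
  })
  names(out) <- vapply(thresholds, format, character(1))
  out
}
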