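#' Per-second power of the normalized motion envelope
#'
#' Evaluates the power of the motion signal on non-overlapping 1-s windows:
#' each value is the mean of the squared envelope samples of that second.
#' A trailing partial window is dropped. The resulting series is what the
#' segmentation thresholds are compared against.
#'
#' @param signal A [motion_signal()]; it should be max-normalized (see
#'   [normalize_max()]) so that the thresholds have their documented scale.
#' @param hop_s Window/hop length in seconds (default 1; windows do not
#'   overlap).
#'
#' @return An object of class `power_series`: list with `values` (one power
#'   value per window), `hop_s` and `origin` (index of the first full second,
#'   0-based).
#' @export
window_power <- function(signal, hop_s = 1) {
  stopifnot(inherits(signal, "motion_signal"))
  if (!signal$normalized) {
    warning("computing window power of a non-normalized envelope; ",
            "thresholds assume a max-normalized signal")
  }
  m <- round(signal$fs * hop_s)
  if (m < 1) stop("fs * hop_s must be at least 1 sample")
  n_win <- length(signal$values) %/% m
  if (n_win < 1) stop("signal shorter than one window")
  x <- signal$values[seq_len(n_win * m)]
  vals <- colMeans(matrix(x * x, nrow = m))
  structure(list(values = vals, hop_s = hop_s, origin = 0L),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series> %d windows of %g s; range [%.3g, %.3g]\n",
              length(x$values), x$hop_s, min(x$values), max(x$values)))
  invisible(x)
}

power_values <- function(power) {
  if (inherits(power, "power_series")) power$values
  else if (is.numeric(power)) as.numeric(power)
  else stop("`power` must be a power_series or a numeric vector")
}

#' Coarse three-state thresholding
#'
#' Classifies each second as absence from bed (`ABS`, power strictly below
#' `th_abs`), displacement (`DI`, power strictly above `th_di`) or
#' mid-power presence (`MID`, later refined into quiet/disrupted sleep).
#' Values exactly at a threshold go to `MID`.
#'
#' @param power A `power_series` (from [window_power()]) or numeric vector of
#'   per-second powers.
#' @param th_abs Absence threshold (default 0.001 on the normalized scale).
#' @param th_di Displacement threshold (default 0.05).
#'
#' @return Character vector over `{"ABS", "MID", "DI"}`.
#' @export
classify_coarse <- function(power, th_abs = 0.001, th_di = 0.05) {
  v <- power_values(power)
  if (!is.numeric(th_abs) || !is.numeric(th_di) ||
      length(th_abs) != 1L || length(th_di) != 1L) {
    stop("`th_abs` and `th_di` must be single numbers")
  }
  if (th_abs < 0 || th_abs >= th_di) stop("need 0 <= th_abs < th_di")
  out <- rep("MID", length(v))
  out[v < th_abs] <- "ABS"
  out[v > th_di] <- "DI"
  out
}

#' Refine mid-power runs into quiet vs disrupted sleep
#'
#' Every maximal run of `MID` seconds lasting at least `min_qs_s` seconds is
#' relabeled quiet sleep (`QS`); shorter runs become disrupted sleep (`DS`).
#' Runs touching the start or end of the recording are judged by their
#' observed length. A run of exactly `min_qs_s` counts as QS.
#'
#' @param coarse Character vector over `{"ABS", "MID", "DI"}` from
#'   [classify_coarse()].
#' @param min_qs_s Minimum quiet-sleep duration in seconds (default 900,
#'   i.e. 15 min).
#' @param th_abs,th_di Thresholds used to produce `coarse`; recorded in the
#'   result for provenance.
#'
#' @return An object of class `state_labels`: list with `labels` (per-second
#'   states over `{"ABS","QS","DS","DI"}`), `th_abs`, `th_di`, `min_qs_s`.
#' @export
refine_qs_ds <- function(coarse, min_qs_s = 900, th_abs = NA_real_,
                         th_di = NA_real_) {
  if (!is.character(coarse) || length(coarse) == 0L) {
    stop("`coarse` must be a non-empty character vector")
  }
  bad <- setdiff(unique(coarse), c("ABS", "MID", "DI"))
  if (length(bad)) stop("unknown coarse states: ", paste(bad, collapse = ", "))
  if (min_qs_s < 1) stop("`min_qs_s` must be at least 1 second")
  r <- rle(coarse)
  mid <- r$values == "MID"
  r$values[mid] <- ifelse(r$lengths[mid] >= min_qs_s, "QS", "DS")
  state_labels(inverse.rle(r), th_abs = th_abs, th_di = th_di,
               min_qs_s = min_qs_s)
}

#' Per-second state sequence with its segmentation parameters
#'
#' @param labels Character vector over `{"ABS","QS","DS","DI"}`, one entry per
#'   second (0-based half-open seconds `[t, t+1)`).
#' @param th_abs,th_di,min_qs_s Parameters that produced the labels.
#' @return An object of class `state_labels`.
#' @export
state_labels <- function(labels, th_abs = NA_real_, th_di = NA_real_,
                         min_qs_s = NA_real_) {
  if (!is.character(labels) || length(labels) == 0L) {
    stop("`labels` must be a non-empty character vector")
  }
  bad <- setdiff(unique(labels), c("ABS", "QS", "DS", "DI"))
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  if (!is.na(th_abs) && !is.na(th_di) && th_abs >= th_di) {
    stop("need th_abs < th_di")
  }
  structure(list(labels = labels, th_abs = th_abs, th_di = th_di,
                 min_qs_s = min_qs_s),
            class = "state_labels")
}

#' @export
print.state_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("ABS", "QS", "DS", "DI")))
  cat(sprintf("<state_labels> %d s (th_abs = %g, th_di = %g, min_qs = %g s)\n",
              length(x$labels), x$th_abs, x$th_di, x$min_qs_s))
  print(tab)
  invisible(x)
}

label_values <- function(labels) {
  if (inherits(labels, "state_labels")) labels$labels
  else if (is.character(labels)) labels
  else stop("`labels` must be a state_labels object or character vector")
}

#' Maximal runs of a state sequence
#'
#' @param labels A `state_labels` object or character vector.
#' @return Data frame with columns `state`, `start_s` (0-based) and
#'   `duration_s`; the runs tile the recording without overlap.
#' @export
state_runs <- function(labels) {
  lab <- label_values(labels)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start_s = ends - r$lengths,
             duration_s = r$lengths,
             stringsAsFactors = FALSE)
}

#' Full segmentation of a normalized envelope
#'
#' Convenience wrapper running [window_power()] (unless already given a power
#' series), [classify_coarse()] and [refine_qs_ds()].
#'
#' @param x A normalized [motion_signal()] or a `power_series`.
#' @inheritParams classify_coarse
#' @inheritParams refine_qs_ds
#' @return A `state_labels` object.
#' @export
classify_states <- function(x, th_abs = 0.001, th_di = 0.05, min_qs_s = 900) {
  power <- if (inherits(x, "motion_signal")) window_power(x) else x
  coarse <- classify_coarse(power, th_abs = th_abs, th_di = th_di)
  refine_qs_ds(coarse, min_qs_s = min_qs_s, th_abs = th_abs, th_di = th_di)
}

#' Sleep-quality indexes of a labeled recording
#'
#' Computes the percentage of recording time per state, the combined
#' disrupted-plus-displacement share (the index correlated against the
#' apnea-hypopnea index), and the displacement events (maximal `DI` runs)
#' with their durations.
#'
#' @param labels A `state_labels` object or character vector over
#'   `{"ABS","QS","DS","DI"}`.
#' @return An object of class `sleep_indexes`: list with `qs_pct`, `ds_pct`,
#'   `di_pct`, `abs_pct`, `dsdi_pct`, `n_di_events`, `di_durations_s` and
#'   `n_seconds`.
#' @export
summarize_states <- function(labels) {
  lab <- label_values(labels)
  n <- length(lab)
  counts <- table(factor(lab, levels = c("ABS", "QS", "DS", "DI")))
  pct <- 100 * as.numeric(counts) / n
  runs <- state_runs(lab)
  di <- runs[runs$state == "DI", , drop = FALSE]
  structure(list(abs_pct = pct[[1L]], qs_pct = pct[[2L]], ds_pct = pct[[3L]],
                 di_pct = pct[[4L]], dsdi_pct = pct[[3L]] + pct[[4L]],
                 n_di_events = nrow(di), di_durations_s = di$duration_s,
                 n_seconds = n),
            class = "sleep_indexes")
}

#' @export
print.sleep_indexes <- function(x, ...) {
  cat(sprintf(paste0("<sleep_indexes> QS %.2f%% | DS %.2f%% | DI %.2f%% | ",
                     "ABS %.2f%% (DS+DI %.2f%%), %d displacement event(s)\n"),
              x$qs_pct, x$ds_pct, x$di_pct, x$abs_pct, x$dsdi_pct,
              x$n_di_events))
  invisible(x)
}

#' ROC-based calibration of the absence threshold
#'
#' Given short reference power series recorded with the bed empty and
#' occupied, scans the midpoints between consecutive pooled power values and
#' returns the cut maximizing Youden's J statistic for discriminating empty
#' (below threshold) from occupied (above threshold) seconds. With perfectly
#' separated inputs this is the midpoint of the gap. If the two
#' distributions are indistinguishable (best J is not positive) the pooled
#' median is returned with a warning.
#'
#' @param power_empty,power_occupied `power_series` objects or numeric
#'   vectors of per-second power with the bed empty / occupied.
#' @return A single numeric threshold; attributes `youden_j`, `sensitivity`
#'   and `specificity` report the operating point.
#' @export
calibrate_abs_threshold <- function(power_empty, power_occupied) {
  e <- power_values(power_empty)
  o <- power_values(power_occupied)
  if (length(e) == 0L || length(o) == 0L) {
    stop("both reference series must be non-empty")
  }
  pooled <- sort(unique(c(e, o)))
  if (length(pooled) < 2L) {
    warning("reference distributions are identical; returning pooled median")
    return(stats::median(c(e, o)))
  }
  cand <- (pooled[-1L] + pooled[-length(pooled)]) / 2
  j <- vapply(cand, function(th) {
    mean(o > th) - mean(e > th)
  }, numeric(1))
  best <- which.max(j)
  if (j[best] <= 0) {
    warning("empty and occupied power are indistinguishable (J <= 0); ",
            "returning pooled median")
    return(stats::median(c(e, o)))
  }
  th <- cand[best]
  attr(th, "youden_j") <- j[best]
  attr(th, "sensitivity") <- mean(o > th)
  attr(th, "specificity") <- mean(e <= th)
  th
}
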