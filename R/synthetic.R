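#' Synthetic bed-sensor recording protocol
#'
#' Describes one simulated night on the multichannel pressure sensor. The
#' generated signal is the sum of three components mirroring the noise
#' taxonomy the segmentation exploits: an external noise floor present at
#' all times (traffic-like sensor noise), a breathing oscillation present
#' only while the subject occupies the bed, and high-amplitude noise bursts
#' for body movements. Movement bursts come in three flavors: spontaneous
#' movements (the roughly once-per-1.5-h repositionings of typical adult
#' sleep), apnea-like burst clusters (frequent short events, modal duration
#' about 5 s), and sub-displacement "restless" activity whose power sits
#' between the absence and displacement thresholds. Occasional bursts reach
#' the sensor saturation level, which anchors the per-recording maximum the
#' envelope is normalized by.
#'
#' Amplitudes are expressed in units of the saturation level (1 = strongest
#' measurable movement). With the defaults, a normalized envelope yields
#' per-second powers of roughly 1e-4 during absence, 5e-3 during quiet
#' breathing, 0.02 during restless activity and 0.1-1 during displacement
#' bursts, so the published thresholds (0.001 and 0.05) are meaningful
#' separators with at least a twofold margin on either side even after
#' per-channel gain jitter and the spread of the per-recording maximum.
#'
#' @param duration_s Recording length in seconds (default 8 h).
#' @param fs Sampling rate in Hz (default 50).
#' @param n_channels Number of pressure channels (default 8).
#' @param breathing_amp Breathing sinusoid amplitude (default 0.12).
#' @param breathing_freq_hz Breathing frequency (default 0.25 Hz).
#' @param external_noise_sd Noise-floor standard deviation (default 0.01).
#' @param movement_interval_s Mean gap between spontaneous movements
#'   (default 5400 s = 1.5 h).
#' @param movement_gap_cv Coefficient of variation of the inter-movement
#'   gaps; 1 gives exponential gaps, smaller values near-regular gaps
#'   (gamma distributed).
#' @param movement_duration_meanlog,movement_duration_sdlog Log-normal
#'   parameters of burst durations in seconds; defaults give a modal
#'   duration of about 5 s.
#' @param movement_amp_meanlog,movement_amp_sdlog Log-normal parameters of
#'   burst amplitudes (fraction of saturation).
#' @param saturation_prob Probability that a movement saturates the sensor.
#' @param saturation_level Saturation amplitude (reference 1).
#' @param ensure_saturation If `TRUE` (default) at least one movement per
#'   recording is promoted to saturation so the normalization reference is
#'   comparable across recordings.
#' @param clip_level Hard clip applied to the raw samples (sensor range).
#' @param apnea_enabled,apnea_rate_per_h Enable apnea-like burst clusters at
#'   the given mean event rate (events per hour).
#' @param apnea_gap_cv Coefficient of variation of inter-event gaps within
#'   the cluster process.
#' @param restless_rate_per_h Rate of sub-displacement restless bursts
#'   (default 0).
#' @param restless_amp Amplitude of restless bursts (default 0.15, i.e.
#'   normalized power about 0.02: above the absence threshold, below the
#'   displacement threshold even after per-channel gain jitter).
#' @param restless_duration_meanlog,restless_duration_sdlog Log-normal
#'   duration parameters of restless bursts.
#' @param absence List of `c(start_s, duration_s)` intervals during which
#'   the bed is empty.
#' @param seed Optional default seed used by [simulate_recording()].
#' @return An object of class `sleep_protocol` (a validated list).
#' @export
synthetic_protocol <- function(duration_s = 8 * 3600,
                               fs = 50,
                               n_channels = 8,
                               breathing_amp = 0.12,
                               breathing_freq_hz = 0.25,
                               external_noise_sd = 0.01,
                               movement_interval_s = 5400,
                               movement_gap_cv = 1,
                               movement_duration_meanlog = log(5) + 0.35^2,
                               movement_duration_sdlog = 0.35,
                               movement_amp_meanlog = log(0.45),
                               movement_amp_sdlog = 0.15,
                               saturation_prob = 0.1,
                               saturation_level = 1,
                               ensure_saturation = TRUE,
                               clip_level = 3,
                               apnea_enabled = FALSE,
                               apnea_rate_per_h = 0,
                               apnea_gap_cv = 0.6,
                               restless_rate_per_h = 0,
                               restless_amp = 0.15,
                               restless_duration_meanlog = log(12),
                               restless_duration_sdlog = 0.3,
                               absence = list(),
                               seed = NA_integer_) {
  p <- structure(as.list(environment()), class = "sleep_protocol")
  validate_protocol(p)
  p
}

#' Validate a synthetic protocol
#'
#' Collects every violated constraint and raises one error listing them all.
#'
#' @param protocol A `sleep_protocol`.
#' @return The protocol, invisibly, if valid.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "sleep_protocol"))
  p <- protocol
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(p$duration_s >= 60, "duration_s must be at least 60 s")
  chk(p$fs > 0, "fs must be positive")
  chk(p$fs >= 2 * p$breathing_freq_hz,
      "fs must be at least twice the breathing frequency")
  chk(p$n_channels >= 1, "need at least one channel")
  chk(p$breathing_amp >= 0, "breathing_amp must be nonnegative")
  chk(p$external_noise_sd >= 0, "external_noise_sd must be nonnegative")
  chk(p$movement_interval_s > 0, "movement_interval_s must be positive")
  chk(p$movement_gap_cv > 0, "movement_gap_cv must be positive")
  chk(p$saturation_prob >= 0 && p$saturation_prob <= 1,
      "saturation_prob must lie in [0, 1]")
  chk(p$saturation_level > 0, "saturation_level must be positive")
  chk(!p$apnea_enabled || p$apnea_rate_per_h > 0,
      "apnea_rate_per_h must be positive when apnea_enabled")
  chk(p$restless_rate_per_h >= 0, "restless_rate_per_h must be nonnegative")
  for (seg in p$absence) {
    chk(length(seg) == 2L && seg[1] >= 0 && seg[2] > 0 &&
          seg[1] + seg[2] <= p$duration_s,
        sprintf("absence segment (%s) must lie within the recording",
                paste(seg, collapse = ", ")))
  }
  if (length(bad)) {
    stop("invalid protocol:\n  - ", paste(bad, collapse = "\n  - "))
  }
  invisible(protocol)
}

#' @export
print.sleep_protocol <- function(x, ...) {
  cat(sprintf(paste0("<sleep_protocol> %.1f h @ %g Hz, %d channel(s); ",
                     "spontaneous movements every %.0f min%s%s%s\n"),
              x$duration_s / 3600, x$fs, x$n_channels,
              x$movement_interval_s / 60,
              if (x$apnea_enabled)
                sprintf("; apnea bursts %.0f/h", x$apnea_rate_per_h) else "",
              if (x$restless_rate_per_h > 0)
                sprintf("; restless bursts %.0f/h", x$restless_rate_per_h) else "",
              if (length(x$absence))
                sprintf("; %d absence interval(s)", length(x$absence)) else ""))
  invisible(x)
}

# Gamma-distributed waiting times with given mean and coefficient of
# variation (cv = 1 reduces to the exponential), accumulated until the
# horizon is passed.
draw_event_starts <- function(mean_gap, cv, horizon) {
  n_guess <- max(10, ceiling(horizon / mean_gap * 3) + 10)
  shape <- 1 / cv^2
  gaps <- stats::rgamma(n_guess, shape = shape, scale = mean_gap / shape)
  starts <- cumsum(gaps)
  while (length(starts) && starts[length(starts)] < horizon) {
    gaps <- stats::rgamma(n_guess, shape = shape, scale = mean_gap / shape)
    starts <- c(starts, starts[length(starts)] + cumsum(gaps))
  }
  starts[starts < horizon]
}

draw_events <- function(type, mean_gap, cv, protocol, occupied_sec) {
  D <- protocol$duration_s
  starts <- floor(draw_event_starts(mean_gap, cv, D))
  if (!length(starts)) {
    return(data.frame(type = character(), start_s = integer(),
                      duration_s = integer(), amplitude = numeric()))
  }
  if (type == "restless") {
    dur <- pmax(1, round(stats::rlnorm(length(starts),
                                       protocol$restless_duration_meanlog,
                                       protocol$restless_duration_sdlog)))
    amp <- protocol$restless_amp * stats::runif(length(starts), 0.9, 1.1)
  } else {
    dur <- pmax(1, round(stats::rlnorm(length(starts),
                                       protocol$movement_duration_meanlog,
                                       protocol$movement_duration_sdlog)))
    sat <- stats::runif(length(starts)) < protocol$saturation_prob
    amp <- stats::rlnorm(length(starts), protocol$movement_amp_meanlog,
                         protocol$movement_amp_sdlog)
    amp <- pmin(amp, protocol$saturation_level)
    amp[sat] <- protocol$saturation_level
  }
  dur <- pmin(dur, D - starts)
  keep <- dur >= 1
  # events must fall entirely within occupied time
  keep <- keep & vapply(seq_along(starts), function(i) {
    all(occupied_sec[(starts[i] + 1):(starts[i] + dur[i])])
  }, logical(1))
  data.frame(type = rep(type, sum(keep)), start_s = as.integer(starts[keep]),
             duration_s = as.integer(dur[keep]), amplitude = amp[keep],
             stringsAsFactors = FALSE)
}

#' Simulate a multichannel bed-sensor recording with ground truth
#'
#' Generates the raw channel matrix described by a [synthetic_protocol()]
#' together with the intended per-second coarse state of every second
#' (`ABS` while the bed is empty, `DI` during movement or apnea bursts,
#' `MID` otherwise; restless bursts are deliberately `MID`: they model
#' activity that must not count as displacement). Output is reproducible:
#' the same protocol and seed give bit-identical recordings.
#'
#' @param protocol A `sleep_protocol`.
#' @param seed Integer seed (defaults to the protocol's `seed` field).
#' @return List with elements `channels` (a [channel_matrix()]) and `truth`
#'   (class `ground_truth`: list with per-second `states` and the `events`
#'   log).
#' @export
simulate_recording <- function(protocol, seed = protocol$seed) {
  validate_protocol(protocol)
  if (!is.na(seed)) set.seed(as.integer(seed))
  p <- protocol
  D <- as.integer(p$duration_s)
  n <- D * p$fs
  C <- p$n_channels

  occupied_sec <- rep(TRUE, D)
  for (seg in p$absence) {
    occupied_sec[(floor(seg[1]) + 1):(floor(seg[1] + seg[2]))] <- FALSE
  }

  ev_move <- draw_events("movement", p$movement_interval_s, p$movement_gap_cv,
                         p, occupied_sec)
  ev_apnea <- if (p$apnea_enabled) {
    draw_events("apnea", 3600 / p$apnea_rate_per_h, p$apnea_gap_cv,
                p, occupied_sec)
  } else ev_move[0, ]
  ev_rest <- if (p$restless_rate_per_h > 0) {
    draw_events("restless", 3600 / p$restless_rate_per_h, 1, p, occupied_sec)
  } else ev_move[0, ]

  # every night contains at least one repositioning; max-normalization of
  # the envelope presupposes one, so the generator guarantees it
  if (nrow(ev_move) + nrow(ev_apnea) == 0L && any(occupied_sec)) {
    start <- sample(which(occupied_sec), 1L) - 1L
    dur <- max(1, round(stats::rlnorm(1, p$movement_duration_meanlog,
                                      p$movement_duration_sdlog)))
    dur <- min(dur, D - start)
    ev_move <- data.frame(type = "movement", start_s = as.integer(start),
                          duration_s = as.integer(dur),
                          amplitude = p$saturation_level,
                          stringsAsFactors = FALSE)
  }

  if (p$ensure_saturation) {
    n_di <- nrow(ev_move) + nrow(ev_apnea)
    if (n_di > 0 &&
        max(c(ev_move$amplitude, ev_apnea$amplitude)) < p$saturation_level) {
      if (nrow(ev_move) && (!nrow(ev_apnea) ||
                            max(ev_move$amplitude) >= max(ev_apnea$amplitude))) {
        ev_move$amplitude[which.max(ev_move$amplitude)] <- p$saturation_level
      } else {
        ev_apnea$amplitude[which.max(ev_apnea$amplitude)] <- p$saturation_level
      }
    }
  }
  events <- rbind(ev_move, ev_apnea, ev_rest)
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL

  occupied_sample <- rep(occupied_sec, each = p$fs)
  t <- seq_len(n) / p$fs
  vals <- matrix(stats::rnorm(C * n, sd = p$external_noise_sd), nrow = C)
  for (ch in seq_len(C)) {
    gain <- stats::runif(1, 0.7, 1.3)
    phase <- stats::runif(1, 0, 2 * pi)
    vals[ch, ] <- vals[ch, ] + occupied_sample * p$breathing_amp * gain *
      sin(2 * pi * p$breathing_freq_hz * t + phase)
  }
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      idx <- (events$start_s[i] * p$fs + 1):((events$start_s[i] +
                                                events$duration_s[i]) * p$fs)
      for (ch in seq_len(C)) {
        gain <- stats::runif(1, 0.7, 1.3)
        vals[ch, idx] <- vals[ch, idx] +
          stats::rnorm(length(idx), sd = events$amplitude[i] * gain)
      }
    }
  }
  vals <- pmin(pmax(vals, -p$clip_level), p$clip_level)

  states <- ifelse(occupied_sec, "MID", "ABS")
  di_ev <- events[events$type != "restless", , drop = FALSE]
  for (i in seq_len(nrow(di_ev))) {
    states[(di_ev$start_s[i] + 1):(di_ev$start_s[i] + di_ev$duration_s[i])] <- "DI"
  }

  list(channels = channel_matrix(vals, fs = p$fs),
       truth = structure(list(states = states, events = events,
                              duration_s = D),
                         class = "ground_truth"))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d s; %d event(s): %s\n", x$duration_s,
              nrow(x$events),
              paste(sprintf("%s=%d", names(table(x$events$type)),
                            as.integer(table(x$events$type))), collapse = ", ")))
  invisible(x)
}

#' Preset: typical healthy night
#'
#' Sparse spontaneous repositionings only (mean interval 1.5 h), no apnea
#' clusters, no absence.
#'
#' @param ... Overrides passed to [synthetic_protocol()].
#' @return A `sleep_protocol`.
#' @export
preset_healthy <- function(...) {
  synthetic_protocol(...)
}

#' Preset: apneic night of a given severity
#'
#' Adds apnea-like movement-burst clusters on top of the healthy preset at a
#' rate that places the implied events per hour inside the requested
#' severity band: 8/h for mild (band 5-15), 20/h for moderate (15-30), 35/h
#' for severe (at least 30).
#'
#' @param severity `"Mi"`, `"Mo"` or `"S"`.
#' @param ... Overrides passed to [synthetic_protocol()].
#' @return A `sleep_protocol`.
#' @export
preset_apnea <- function(severity = c("Mi", "Mo", "S"), ...) {
  severity <- match.arg(severity)
  rate <- c(Mi = 8, Mo = 20, S = 35)[[severity]]
  synthetic_protocol(apnea_enabled = TRUE, apnea_rate_per_h = rate, ...)
}

#' Preset: insomnia-like night
#'
#' Frequent short quiet intervals (spontaneous movements every 30 min),
#' restless sub-displacement activity, and two out-of-bed absence intervals.
#'
#' @param ... Overrides passed to [synthetic_protocol()].
#' @return A `sleep_protocol`.
#' @export
preset_insomnia <- function(...) {
  args <- list(...)
  dur <- if (!is.null(args$duration_s)) args$duration_s else 8 * 3600
  if (is.null(args$movement_interval_s)) args$movement_interval_s <- 1800
  if (is.null(args$restless_rate_per_h)) args$restless_rate_per_h <- 10
  if (is.null(args$absence)) {
    args$absence <- list(c(round(0.35 * dur), 600), c(round(0.70 * dur), 900))
  }
  do.call(synthetic_protocol, args)
}

#' Noise-free sleep indexes from ground truth
#'
#' Applies the quiet/disrupted refinement rule directly to the intended
#' coarse states of a simulation, giving the oracle the full pipeline is
#' compared against.
#'
#' @param truth A `ground_truth` from [simulate_recording()].
#' @param min_qs_s Minimum quiet-sleep duration in seconds (default 900).
#' @return A `sleep_indexes` object.
#' @export
ground_truth_indexes <- function(truth, min_qs_s = 900) {
  stopifnot(inherits(truth, "ground_truth"))
  summarize_states(refine_qs_ds(truth$states, min_qs_s = min_qs_s))
}
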