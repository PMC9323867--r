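#' Read a multichannel recording from delimited text
#'
#' Columns are channels (the header row carries the channel ids), rows are
#' samples. Non-numeric cells are reported with their line and column.
#'
#' @param path Path to a CSV file.
#' @param fs Sampling rate in Hz (not stored in the file).
#' @return A [channel_matrix()].
#' @export
read_channel_matrix <- function(path, fs) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  if (nrow(d) == 0L || ncol(d) == 0L) stop("parse error: ", path, " is empty")
  for (j in seq_along(d)) {
    v <- suppressWarnings(as.numeric(d[[j]]))
    bad <- which(is.na(v) & !is.na(d[[j]]))
    if (length(bad)) {
      stop(sprintf("parse error in %s: non-numeric value %s at line %d, column %s",
                   path, dQuote(d[[j]][bad[1L]]), bad[1L] + 1L, names(d)[j]))
    }
    if (anyNA(v)) {
      stop(sprintf("parse error in %s: missing value at line %d, column %s",
                   path, which(is.na(v))[1L] + 1L, names(d)[j]))
    }
    d[[j]] <- v
  }
  channel_matrix(t(as.matrix(d)), fs = fs, channel_ids = names(d))
}

#' Write a multichannel recording to CSV
#'
#' @param channels A [channel_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_matrix <- function(channels, path) {
  stopifnot(inherits(channels, "channel_matrix"))
  d <- as.data.frame(t(channels$values))
  names(d) <- channels$channel_ids
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a motion envelope as single-column CSV
#'
#' The file carries a one-line metadata comment
#' `# fs_hz=...; normalized=...; norm_max=...` followed by a `value` column.
#'
#' @param signal A [motion_signal()].
#' @param path File path.
#' @return `write_motion_signal()` returns `path` invisibly;
#'   `read_motion_signal()` returns a [motion_signal()].
#' @export
write_motion_signal <- function(signal, path) {
  stopifnot(inherits(signal, "motion_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.17g; normalized=%s; norm_max=%.17g",
                     signal$fs, tolower(signal$normalized), signal$norm_max),
             con)
  writeLines("value", con)
  writeLines(format(signal$values, digits = 15, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' @rdname write_motion_signal
#' @export
read_motion_signal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing metadata header in ", path)
  meta <- strsplit(sub("^#\\s*", "", header), ";\\s*")[[1L]]
  kv <- do.call(rbind, strsplit(meta, "="))
  get <- function(k) kv[kv[, 1L] == k, 2L]
  d <- utils::read.csv(path, comment.char = "#")
  motion_signal(d$value, fs = as.numeric(get("fs_hz")),
                normalized = identical(get("normalized"), "true"),
                norm_max = as.numeric(get("norm_max")))
}

#' Write / read per-second state labels
#'
#' Two-column CSV (`second_index`, `state`), 0-based seconds.
#'
#' @param labels A `state_labels` object.
#' @param path File path.
#' @return `write_state_labels()` returns `path` invisibly;
#'   `read_state_labels()` returns a `state_labels` object (without the
#'   generating thresholds, which the file does not carry).
#' @export
write_state_labels <- function(labels, path) {
  stopifnot(inherits(labels, "state_labels"))
  utils::write.csv(data.frame(second_index = seq_along(labels$labels) - 1L,
                              state = labels$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_labels
#' @export
read_state_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("second_index", "state") %in% names(d))) {
    stop("expected columns second_index, state in ", path)
  }
  d <- d[order(d$second_index), ]
  if (!identical(as.integer(d$second_index), seq_len(nrow(d)) - 1L)) {
    stop("second_index must cover 0..n-1 without gaps in ", path)
  }
  state_labels(d$state)
}

#' Default analysis configuration
#'
#' @return Named list of the tunable parameters: `fs_hz` (raw sampling
#'   rate), `window_s` (envelope window), `method` (`"std"` or `"pca"`),
#'   `th_abs`, `th_di` (power thresholds on the normalized scale),
#'   `min_qs_min` (minimum quiet-sleep period, minutes), `dfa_n_scales`,
#'   `dfa_min_min`, `dfa_max_min` (DFA scale grid, minutes).
#' @export
default_config <- function() {
  list(fs_hz = 50, window_s = 4, method = "std",
       th_abs = 0.001, th_di = 0.05, min_qs_min = 15,
       dfa_n_scales = 15, dfa_min_min = 1, dfa_max_min = 60)
}

#' Read a YAML/JSON configuration file
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path Path to a YAML (or JSON) config file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading JSON configs requires the jsonlite package")
    }
    jsonlite::fromJSON(path)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  }
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(base, cfg)
}

#' Run the full analysis pipeline on one recording
#'
#' Conditioning (envelope extraction and max-normalization), per-second
#' power, coarse thresholding, quiet/disrupted refinement, state summary,
#' quiet-sleep cumulative curve and detrended fluctuation analysis of the
#' per-second power series. Deterministic given its inputs; errors are
#' re-raised with the name of the failing stage.
#'
#' @param input A [channel_matrix()], a [motion_signal()], or a path to a
#'   channel CSV (read at `config$fs_hz`).
#' @param config Configuration list; missing entries fall back to
#'   [default_config()].
#' @return An object of class `analysis_report`: list with `indexes`
#'   (a `sleep_indexes`), `curve` (a `qs_curve`), `max_slope_min`, `dfa`
#'   (a `dfa_result`, or `NULL` for recordings too short for the scale
#'   grid), `labels` and `params`.
#' @export
run_analyze <- function(input, config = list()) {
  params <- utils::modifyList(default_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  channels <- NULL
  signal <- NULL
  if (is.character(input)) {
    channels <- stage("read", read_channel_matrix(input, fs = params$fs_hz))
  } else if (inherits(input, "channel_matrix")) {
    channels <- input
  } else if (inherits(input, "motion_signal")) {
    signal <- input
  } else {
    stop("`input` must be a channel_matrix, motion_signal or file path")
  }
  if (is.null(signal)) {
    signal <- stage("condition", {
      env <- if (identical(params$method, "pca")) {
        pca_motion(channels, window_s = params$window_s)
      } else {
        sliding_std_envelope(channels, window_s = params$window_s)
      }
      normalize_max(env)
    })
  } else if (!signal$normalized) {
    signal <- stage("condition", normalize_max(signal))
  }
  power <- stage("power", window_power(signal))
  labels <- stage("classify", {
    coarse <- classify_coarse(power, th_abs = params$th_abs,
                              th_di = params$th_di)
    refine_qs_ds(coarse, min_qs_s = params$min_qs_min * 60,
                 th_abs = params$th_abs, th_di = params$th_di)
  })
  indexes <- stage("summarize", summarize_states(labels))
  curve <- stage("curve", qs_cumulative_curve(labels))
  slope <- stage("curve", max_slope_point(curve))
  dfa <- stage("dfa", {
    scales <- suppressWarnings(
      default_scales(1, n_scales = params$dfa_n_scales,
                     min_min = params$dfa_min_min,
                     max_min = params$dfa_max_min,
                     n_samples = length(power$values)))
    if (length(scales) >= 3L) dfa_fluctuation(power, scales = scales)
    else NULL
  })
  structure(list(indexes = indexes, curve = curve, max_slope_min = slope,
                 dfa = dfa, labels = labels, params = params),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  states: QS %.2f%% | DS %.2f%% | DI %.2f%% | ABS %.2f%%\n",
              x$indexes$qs_pct, x$indexes$ds_pct, x$indexes$di_pct,
              x$indexes$abs_pct))
  cat(sprintf("  displacement events: %d\n", x$indexes$n_di_events))
  cat(sprintf("  max-slope point: %s min\n",
              ifelse(is.na(x$max_slope_min), "none", x$max_slope_min)))
  if (!is.null(x$dfa)) cat(sprintf("  Hurst exponent: %.3f\n", x$dfa$H))
  cat(sprintf("  params: th_abs = %g, th_di = %g, min_qs = %g min\n",
              x$params$th_abs, x$params$th_di, x$params$min_qs_min))
  invisible(x)
}
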