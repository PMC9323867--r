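#' Multichannel pressure bed sensor recording
#'
#' A `channel_matrix` holds the raw multichannel pressure trace of one
#' recording: a channels-by-samples numeric matrix together with its sampling
#' rate. All channels must have equal length and the sampling rate must be
#' positive.
#'
#' @param values Numeric matrix, channels in rows and samples in columns, or a
#'   numeric vector for a single channel.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Optional character vector of channel labels; defaults to
#'   `ch1, ch2, ...`.
#'
#' @return An object of class `channel_matrix` with fields `values`, `fs` and
#'   `channel_ids`.
#' @export
#' @examples
#' cm <- channel_matrix(matrix(rnorm(200), nrow = 2), fs = 10)
#' cm
channel_matrix <- function(values, fs, channel_ids = NULL) {
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, nrow = 1)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (channels x samples)")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must contain at least one channel and one sample")
  }
  if (anyNA(values)) stop("`values` must not contain missing values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(values)))
  if (length(channel_ids) != nrow(values)) {
    stop("`channel_ids` must have one label per channel")
  }
  rownames(values) <- channel_ids
  structure(list(values = values, fs = fs, channel_ids = channel_ids),
            class = "channel_matrix")
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("<channel_matrix> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$fs, ncol(x$values) / x$fs))
  invisible(x)
}

#' Motion envelope of a recording
#'
#' A `motion_signal` is the nonnegative activity envelope derived from a
#' pressure recording (see [sliding_std_envelope()] and [pca_motion()]); its
#' per-second power drives the state segmentation.
#'
#' @param values Nonnegative numeric vector of envelope samples.
#' @param fs Sampling rate in Hz.
#' @param normalized Logical; `TRUE` once the envelope has been divided by its
#'   recording maximum.
#' @param norm_max The pre-normalization maximum (NA until normalized).
#'
#' @return An object of class `motion_signal`.
#' @export
motion_signal <- function(values, fs, normalized = FALSE, norm_max = NA_real_) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector")
  }
  if (anyNA(values)) stop("`values` must not contain missing values")
  if (any(values < 0)) stop("envelope values must be nonnegative")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (isTRUE(normalized) && abs(max(values) - 1) > 1e-8) {
    stop("a normalized envelope must have maximum 1")
  }
  structure(list(values = as.numeric(values), fs = fs,
                 normalized = isTRUE(normalized), norm_max = norm_max),
            class = "motion_signal")
}

#' @export
print.motion_signal <- function(x, ...) {
  cat(sprintf("<motion_signal> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              if (x$normalized) sprintf(", max-normalized (norm_max = %g)", x$norm_max)
              else ""))
  invisible(x)
}

# Raised-cosine (Hann) weights, w_k = 0.5 * (1 - cos(2*pi*k/(L-1))).
# The endpoint weights are zero, so L must be >= 3 for a non-degenerate window.
hann_weights <- function(L) {
  k <- seq_len(L) - 1L
  0.5 * (1 - cos(2 * pi * k / (L - 1)))
}

# Linear (open) convolution via FFT, zero-padded to a 2-3-5-smooth length so
# the transform stays O(n log n) for any recording length.
conv_open <- function(x, y) {
  n_out <- length(x) + length(y) - 1L
  m <- stats::nextn(n_out, c(2, 3, 5))
  fx <- stats::fft(c(x, rep(0, m - length(x))))
  fy <- stats::fft(c(y, rep(0, m - length(y))))
  Re(stats::fft(fx * fy, inverse = TRUE))[seq_len(n_out)] / m
}

# Centered sliding weighted sums of `x` with kernel `w` (symmetric), truncated
# at the boundaries. Returns the three sums needed for a weighted std:
# sum(w), sum(w*x), sum(w*x^2) around every sample.
sliding_weighted_sums <- function(x, w) {
  n <- length(x)
  L <- length(w)
  h <- L %/% 2L
  idx <- (L - h):(L - h + n - 1L)
  conv <- function(v) conv_open(v, w)[idx]
  list(W = conv(rep(1, n)), S1 = conv(x), S2 = conv(x * x))
}

# Weighted population std around every sample; weights renormalized at the
# truncated boundary windows.
sliding_weighted_std <- function(x, w) {
  # centering the whole channel first is mathematically a no-op for a windowed
  # std but avoids cancellation when the baseline pressure is large
  x <- x - mean(x)
  s <- sliding_weighted_sums(x, w)
  m <- s$S1 / s$W
  v <- pmax(s$S2 / s$W - m * m, 0)
  sqrt(v)
}

resolve_window_weights <- function(window_s, fs, window) {
  L <- round(window_s * fs)
  if (L < 2) stop("window must span at least 2 samples (window_s * fs >= 2)")
  w <- switch(match.arg(window, c("hann", "rect")),
              hann = hann_weights(L),
              rect = rep(1, L))
  if (sum(w) <= 0) {
    stop("degenerate window: raised-cosine weights vanish for ", L,
         " samples; use a longer window")
  }
  w
}

#' Sliding raised-cosine standard-deviation envelope
#'
#' Extracts the motion signal of a recording as the average over channels of
#' the channel-wise standard deviation computed in a sliding raised-cosine
#' (Hann) window, 4 s by default. Windows are truncated at the recording
#' boundaries with weights renormalized, so the envelope has one value per
#' input sample.
#'
#' @param channels A [channel_matrix()].
#' @param window_s Window length in seconds (default 4).
#' @param window Window shape: `"hann"` (raised cosine, default) or `"rect"`.
#'
#' @return A [motion_signal()] at the sampling rate of the input
#'   (not yet normalized).
#' @seealso [pca_motion()] for the principal-component variant,
#'   [normalize_max()] for the final per-recording normalization.
#' @export
#' @examples
#' cm <- channel_matrix(matrix(rnorm(4000), nrow = 2), fs = 10)
#' env <- sliding_std_envelope(cm)
sliding_std_envelope <- function(channels, window_s = 4, window = "hann") {
  stopifnot(inherits(channels, "channel_matrix"))
  n <- ncol(channels$values)
  w <- resolve_window_weights(window_s, channels$fs, window)
  if (length(w) > n) stop("window longer than the recording")
  per_channel <- apply(channels$values, 1L, sliding_weighted_std, w = w)
  env <- if (is.matrix(per_channel)) rowMeans(per_channel) else per_channel
  motion_signal(pmax(env, 0), fs = channels$fs)
}

#' PCA-based motion envelope
#'
#' Variant of the motion-signal extraction used for multichannel recordings:
#' channels are mean-centered, the scores on the first principal component of
#' the whole-recording covariance are computed, and the envelope is the
#' sliding raised-cosine standard deviation of those scores. The result is
#' invariant to a global sign flip of the channels.
#'
#' @inheritParams sliding_std_envelope
#' @return A [motion_signal()]; the proportion of variance explained by the
#'   first component is attached as attribute `pc1_var_explained`.
#' @export
pca_motion <- function(channels, window_s = 4, window = "hann") {
  stopifnot(inherits(channels, "channel_matrix"))
  if (nrow(channels$values) < 2L) stop("PCA extraction needs at least 2 channels")
  x <- t(channels$values)                 # samples x channels
  x <- sweep(x, 2L, colMeans(x))
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) stop("all channels are constant; PCA is undefined")
  sv <- svd(x, nu = 1L, nv = 1L)
  scores <- as.numeric(x %*% sv$v[, 1L])
  var_explained <- sv$d[1L]^2 / sum(sv$d^2)
  w <- resolve_window_weights(window_s, channels$fs, window)
  if (length(w) > nrow(x)) stop("window longer than the recording")
  env <- sliding_weighted_std(scores, w)
  out <- motion_signal(pmax(env, 0), fs = channels$fs)
  attr(out, "pc1_var_explained") <- var_explained
  out
}

#' Normalize an envelope by its recording maximum
#'
#' Divides the motion envelope by its maximum so that the segmentation
#' thresholds are expressed on a common 0-1 scale across recordings. The
#' operation is idempotent and invariant to positive rescaling of the input.
#'
#' @param signal A [motion_signal()].
#' @return The normalized [motion_signal()], with the pre-normalization
#'   maximum stored in `norm_max`.
#' @export
normalize_max <- function(signal) {
  stopifnot(inherits(signal, "motion_signal"))
  if (signal$normalized) return(signal)
  m <- max(signal$values)
  if (m <= 0) stop("cannot normalize an all-zero envelope")
  out <- motion_signal(signal$values / m, fs = signal$fs,
                       normalized = TRUE, norm_max = m)
  attr(out, "pc1_var_explained") <- attr(signal, "pc1_var_explained")
  out
}
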