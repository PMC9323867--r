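#' Integrated (profile) series for detrended fluctuation analysis
#'
#' First DFA step: subtract the series mean and take the cumulative sum.
#' The profile always ends at zero (up to floating point) because the
#' centered increments telescope.
#'
#' @param x Numeric vector (length >= 4), or a `power_series` /
#'   [motion_signal()] whose values are used.
#' @return Numeric profile of the same length.
#' @export
dfa_profile <- function(x) {
  v <- if (inherits(x, "power_series")) x$values
       else if (inherits(x, "motion_signal")) x$values
       else as.numeric(x)
  if (length(v) < 4L) stop("series too short for DFA (need length >= 4)")
  if (anyNA(v)) stop("series must not contain missing values")
  if (stats::sd(v) == 0) {
    warning("constant series: DFA profile is identically zero")
    return(rep(0, length(v)))
  }
  cumsum(v - mean(v))
}

#' Detrended fluctuation analysis
#'
#' Integrates the series ([dfa_profile()]), partitions the profile into
#' non-overlapping epochs of each scale (the tail remainder is excluded),
#' removes a least-squares polynomial trend (order 1 by default, i.e. DFA-1)
#' from every epoch, and reports the root-mean-square fluctuation per scale
#' over the covered points,
#' `RMS(s) = sqrt(mean((y - y_fit)^2))`.
#' The Hurst exponent is the slope of `log RMS` versus `log scale`
#' (see [hurst_exponent()]): H = 0.5 for an uncorrelated series, H > 0.5
#' for long-range correlated fluctuations, H < 0.5 for anti-correlated ones.
#'
#' @param x Numeric series (or `power_series` / `motion_signal`); typically
#'   the 1 Hz per-second power of the normalized motion envelope.
#' @param scales Integer epoch lengths in samples, strictly increasing; each
#'   scale must be at least `poly_order + 2` and at most half the series
#'   length. Defaults to [default_scales()] at 1 Hz truncated to the series.
#' @param poly_order Order of the detrending polynomial (default 1).
#'
#' @return An object of class `dfa_result`: list with `scales`, `rms`, `H`,
#'   `fit_r2` and `n` (series length).
#' @export
#' @examples
#' set.seed(1)
#' r <- dfa_fluctuation(rnorm(2000), scales = round(exp(seq(log(8), log(256),
#'                                                          length.out = 10))))
#' r$H  # close to 0.5 for white noise
dfa_fluctuation <- function(x, scales = NULL, poly_order = 1) {
  prof <- dfa_profile(x)
  n <- length(prof)
  if (is.null(scales)) {
    scales <- default_scales(1, n_samples = n)
  }
  scales <- as.integer(round(scales))
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("`scales` must be strictly increasing")
  }
  if (any(scales < poly_order + 2)) {
    stop("every scale must be at least poly_order + 2 samples")
  }
  if (max(scales) > n %/% 2L) {
    stop("largest scale exceeds half the series length")
  }
  rms <- vapply(scales, function(s) {
    m <- n %/% s
    seg <- matrix(prof[seq_len(m * s)], nrow = s)
    X <- stats::poly(seq_len(s), degree = poly_order, raw = TRUE)
    qx <- qr(cbind(1, X))
    resid <- qr.resid(qx, seg)
    sqrt(sum(resid^2) / (m * s))
  }, numeric(1))
  res <- structure(list(scales = scales, rms = rms, H = NA_real_,
                        fit_r2 = NA_real_, n = n),
                   class = "dfa_result")
  if (sum(rms > 0) >= 3L) {
    fit <- hurst_exponent(res, details = TRUE)
    res$H <- fit$H
    res$fit_r2 <- fit$r2
  } else {
    warning("fewer than 3 scales with positive fluctuation; ",
            "Hurst exponent not estimated")
  }
  res
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> %d scales [%d..%d samples], H = %.3f (R2 = %.3f)\n",
              length(x$scales), min(x$scales), max(x$scales), x$H, x$fit_r2))
  invisible(x)
}

#' Hurst exponent from a DFA result
#'
#' Ordinary least-squares slope of `log(rms)` against `log(scale)`. Scales
#' with zero fluctuation are excluded with a warning; at least three scales
#' with positive fluctuation are required.
#'
#' @param result A `dfa_result` (the stored `H` is ignored; the fit is
#'   recomputed from `scales` and `rms`).
#' @param details If `TRUE` return a list with `H` and `r2` instead of the
#'   bare slope.
#' @return The Hurst exponent (single numeric), or a list when
#'   `details = TRUE`.
#' @export
hurst_exponent <- function(result, details = FALSE) {
  stopifnot(inherits(result, "dfa_result"))
  keep <- result$rms > 0
  if (any(!keep)) {
    warning(sum(!keep), " scale(s) with zero fluctuation excluded from the fit")
  }
  if (sum(keep) < 3L) stop("need at least 3 scales with positive fluctuation")
  lx <- log(result$scales[keep])
  ly <- log(result$rms[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  h <- fit$coefficients[[2L]]
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  if (details) list(H = h, r2 = r2) else h
}

#' Default DFA scales: 1 to 60 minutes
#'
#' Fifteen logarithmically spaced epoch lengths spanning 1 to 60 minutes at
#' the given sampling rate, rounded to whole samples with duplicates
#' removed. When the series length is supplied, scales longer than half of
#' it are dropped with a warning, so that short recordings still yield a
#' usable (truncated) scale set.
#'
#' @param fs Sampling rate of the analyzed series in Hz (1 for the
#'   per-second power series).
#' @param n_scales Number of scales (default 15).
#' @param min_min,max_min Scale range in minutes (defaults 1 and 60).
#' @param n_samples Optional series length used to truncate the scales.
#' @return Integer vector of strictly increasing epoch lengths in samples.
#' @export
default_scales <- function(fs, n_scales = 15, min_min = 1, max_min = 60,
                           n_samples = NULL) {
  if (fs <= 0) stop("`fs` must be positive")
  if (min_min <= 0 || max_min <= min_min) stop("need 0 < min_min < max_min")
  s <- exp(seq(log(min_min * 60 * fs), log(max_min * 60 * fs),
               length.out = n_scales))
  s <- sort(unique(as.integer(round(s))))
  if (!is.null(n_samples)) {
    keep <- s <= n_samples %/% 2L
    if (!all(keep)) {
      warning("recording shorter than twice the largest scale; ",
              sum(!keep), " scale(s) truncated")
      s <- s[keep]
    }
  }
  s
}
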