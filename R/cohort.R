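#' Sleep efficiency
#'
#' `SE = ST / TIB`: total sleep time divided by time in bed, a fraction in
#' `[0, 1]`.
#'
#' @param st_h Sleep time in hours.
#' @param tib_h Time in bed in hours.
#' @return Sleep efficiency (vectorized).
#' @export
sleep_efficiency <- function(st_h, tib_h) {
  if (any(tib_h <= 0)) stop("`tib_h` must be positive")
  if (any(st_h < 0) || any(st_h > tib_h)) {
    stop("`st_h` must lie in [0, tib_h]")
  }
  st_h / tib_h
}

#' Apnea-hypopnea index
#'
#' `AHI = TNE / TR`: total number of abnormal respiratory events divided by
#' the recording duration in hours, i.e. events per hour.
#'
#' @param tne Total number of events (nonnegative).
#' @param tr_h Recording duration in hours.
#' @return Events per hour (vectorized).
#' @export
ahi <- function(tne, tr_h) {
  if (any(tr_h <= 0)) stop("`tr_h` must be positive")
  if (any(tne < 0)) stop("`tne` must be nonnegative")
  tne / tr_h
}

#' Apnea severity category
#'
#' Half-open severity bands: Normal `AHI < 5`, Mild `5 <= AHI < 15`,
#' Moderate `15 <= AHI < 30`, Severe `AHI >= 30`.
#'
#' @param ahi Apnea-hypopnea index (events per hour, nonnegative).
#' @return Factor with levels `N`, `Mi`, `Mo`, `S` (vectorized).
#' @export
ahi_category <- function(ahi) {
  if (any(ahi < 0, na.rm = TRUE)) stop("`ahi` must be nonnegative")
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("N", "Mi", "Mo", "S"))
}

#' Good vs bad sleep-efficiency group
#'
#' `GSE` for sleep efficiency strictly above 0.80, `BSE` otherwise (a
#' recording at exactly 80% counts as bad efficiency).
#'
#' @param se Sleep efficiency in `[0, 1]`.
#' @return Factor with levels `GSE`, `BSE` (vectorized).
#' @export
efficiency_group <- function(se) {
  if (any(se < 0 | se > 1, na.rm = TRUE)) stop("`se` must lie in [0, 1]")
  factor(ifelse(se > 0.80, "GSE", "BSE"), levels = c("GSE", "BSE"))
}

#' Pearson correlation with validity checks
#'
#' Standard product-moment correlation; returns `NA` with a warning when
#' either argument has zero variance.
#'
#' @param x,y Paired numeric vectors of equal length, `n >= 3`.
#' @return Correlation coefficient in `[-1, 1]`, or `NA_real_`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Leave-one-out stability of a correlation
#'
#' Recomputes the Pearson correlation leaving out one pair at a time and
#' summarizes the fold values by their mean and population standard
#' deviation.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @return List with `mean`, `sd` (population), `fold_r` (per-fold
#'   correlations) and `n`.
#' @export
loocv_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  fold_r <- vapply(seq_len(n), function(i) pearson_r(x[-i], y[-i]), numeric(1))
  m <- mean(fold_r)
  list(mean = m, sd = sqrt(mean((fold_r - m)^2)), fold_r = fold_r, n = n)
}

#' Bland-Altman agreement statistics
#'
#' Differences `a - b`, their mean and standard deviation, and the 95%
#' limits of agreement `mean +/- 1.96 sd`.
#'
#' @param a,b Paired numeric vectors of equal length, `n >= 3`.
#' @return Object of class `bland_altman`: list with `mean_diff`, `sd_diff`,
#'   `lower`, `upper`, `outside_count`, `diffs`, `means` and `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  structure(list(mean_diff = m, sd_diff = s, lower = lower, upper = upper,
                 outside_count = sum(d < lower | d > upper),
                 diffs = d, means = (a + b) / 2, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman> mean diff %.3f, sd %.3f, 95%% limits ",
                     "[%.3f, %.3f], %d/%d outside\n"),
              x$mean_diff, x$sd_diff, x$lower, x$upper, x$outside_count, x$n))
  invisible(x)
}

# Distribution of the rank-sum statistic U for group a over all
# choose(n_a + n_b, n_a) assignments of the pooled (possibly tied) ranks.
mw_enumerate_u <- function(ranks_pooled, n_a) {
  combs <- utils::combn(length(ranks_pooled), n_a)
  colSums(matrix(ranks_pooled[combs], nrow = n_a)) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test with midranks for ties. For small samples
#' (`n_a + n_b <= exact_limit`) the p-value is exact, obtained by
#' enumerating the U distribution over all assignments of the pooled ranks;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exact_limit Largest combined sample size for exact enumeration
#'   (default 12).
#' @return List with `U` (statistic for sample `a`), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b, exact_limit = 12) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n_a + n_b <= exact_limit) {
    dist <- mw_enumerate_u(rk, n_a)
    p <- 2 * min(mean(dist <= u), mean(dist >= u))
    p <- min(1, p)
    return(list(U = u, p = p, method = "exact"))
  }
  n <- n_a + n_b
  ties <- table(pooled)
  mu <- n_a * n_b / 2
  sig2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  list(U = u, p = 2 * stats::pnorm(-abs(z)), method = "normal")
}

#' Flag recordings whose clinical metrics undermine motion-based scoring
#'
#' A recording is uncertain when (i) it combines high sleep efficiency with
#' a high apnea-hypopnea index (the movement-based indexes cannot agree with
#' both), or (ii) hypopneas - respiratory events that generate no motion -
#' make up at least `hypo_min` of its abnormal breathing events.
#'
#' @param records Data frame with columns `se` and `ahi` (NA allowed).
#' @param hypopnea_frac Optional numeric vector (same length) with the
#'   fraction of events that are hypopneas; NA when unknown.
#' @param se_min,ahi_min Cutoffs of the high-SE/high-AHI rule (defaults 0.90
#'   and 30).
#' @param hypo_min Hypopnea-dominance cutoff (default 0.80).
#' @return Logical vector of flags.
#' @export
uncertain_flags <- function(records, hypopnea_frac = NULL,
                            se_min = 0.90, ahi_min = 30, hypo_min = 0.80) {
  stopifnot(is.data.frame(records), all(c("se", "ahi") %in% names(records)))
  f1 <- !is.na(records$se) & !is.na(records$ahi) &
    records$se >= se_min & records$ahi >= ahi_min
  f2 <- rep(FALSE, nrow(records))
  if (!is.null(hypopnea_frac)) {
    if (length(hypopnea_frac) != nrow(records)) {
      stop("`hypopnea_frac` must have one value per record")
    }
    f2 <- !is.na(hypopnea_frac) & hypopnea_frac >= hypo_min
  }
  f1 | f2
}

#' Packaged cohort tables
#'
#' Loads the packaged clinical table (44 recordings across the apnea and
#' shift-work datasets: sleep time, sleep efficiency, event counts,
#' apnea-hypopnea index, day/night timetable, uncertainty flags) merged with
#' the per-recording sleep-quality percentages detected by the motion
#' pipeline, and attaches the derived columns used throughout the
#' evaluation: `dsdi_pct`, `severity` and `efficiency_group`.
#'
#' @return Data frame with one row per recording (44 rows).
#' @export
load_fixture_tables <- function() {
  p1 <- system.file("extdata", "table1.csv", package = "sleepmotion",
                    mustWork = TRUE)
  p2 <- system.file("extdata", "table2.csv", package = "sleepmotion",
                    mustWork = TRUE)
  t1 <- utils::read.csv(p1, stringsAsFactors = FALSE)
  t2 <- utils::read.csv(p2, stringsAsFactors = FALSE)
  d <- merge(t1, t2[, c("rec", "qs_pct", "ds_pct", "di_pct")], by = "rec")
  d <- d[order(d$rec), ]
  rownames(d) <- NULL
  # integrity checks on the transcription
  ok <- nrow(d) == 44L &&
    sum(d$dataset == "apnea") == 22L &&
    sum(d$dataset == "shift_work") == 22L &&
    sum(d$uncertain) == 4L &&
    all(abs(d$qs_pct + d$ds_pct + d$di_pct - 100) <= 0.02 + 1e-9) &&
    all(d$se >= 0 & d$se <= 1)
  if (!ok) stop("packaged cohort tables failed their integrity checks")
  d$dsdi_pct <- d$ds_pct + d$di_pct
  d$severity <- ahi_category(d$ahi)
  d$efficiency_group <- efficiency_group(d$se)
  d
}
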