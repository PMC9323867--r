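test_that("cumulative curve sums quiet-sleep run lengths per duration", {
  # 60-min recording: QS runs of 40 and 18 min plus 2 min of displacement
  lab <- c(rep("QS", 40 * 60), rep("DI", 60), rep("QS", 18 * 60), rep("DI", 60))
  curve <- qs_cumulative_curve(state_labels(lab))
  at <- function(d) curve$cum_pct[curve$duration_min == d]
  expect_equal(at(30), 100 * 40 / 60, tolerance = 1e-9)
  expect_equal(at(15), 100 * 58 / 60, tolerance = 1e-9)
  expect_equal(at(1), 100 * 58 / 60, tolerance = 1e-9)
  expect_equal(curve$di_pct, 100 * 2 / 60, tolerance = 1e-9)
})

test_that("one uninterrupted quiet night saturates the curve", {
  curve <- qs_cumulative_curve(state_labels(rep("QS", 8 * 3600)))
  expect_true(all(curve$cum_pct == 100))
  # an all-disrupted recording stays at zero
  curve0 <- qs_cumulative_curve(state_labels(rep("DS", 3600)))
  expect_true(all(curve0$cum_pct == 0))
})

test_that("curve is monotone and permutation-invariant", {
  set.seed(12)
  for (i in 1:10) {
    # quiet-sleep runs separated by short non-quiet runs, so every run is
    # maximal; permuting the quiet runs must not change the curve
    qs_len <- sample(c(30:120, 900:2500), 12)
    sep <- sample(c("DS", "DI"), 12, replace = TRUE)
    sep_len <- sample(5:40, 12, replace = TRUE)
    build <- function(ord) {
      unlist(lapply(seq_along(ord), function(k) {
        c(rep("QS", qs_len[ord[k]]), rep(sep[k], sep_len[k]))
      }))
    }
    lab <- build(seq_along(qs_len))
    curve <- qs_cumulative_curve(state_labels(lab))
    expect_true(all(diff(curve$cum_pct) >= 0))  # toward shorter durations
    qs_share <- 100 * sum(qs_len[qs_len >= 60]) / length(lab)
    expect_equal(curve$cum_pct[length(curve$cum_pct)], qs_share,
                 tolerance = 1e-9)
    lab_p <- build(sample(length(qs_len)))
    expect_equal(qs_cumulative_curve(state_labels(lab_p))$cum_pct,
                 curve$cum_pct)
  }
})

test_that("max-slope point picks the largest step toward shorter periods", {
  # single QS run of 19.5 min: jump between the 20- and 19-min grid points
  lab <- c(rep("QS", 1170), rep("DI", 30))
  curve <- qs_cumulative_curve(state_labels(lab))
  expect_equal(max_slope_point(curve), 20)
  # two equal jumps: one 29.5-min run vs three 9.83-min runs (1770 s of QS
  # entering the curve at the 30- and the 10-min step respectively);
  # tie broken toward the longer duration
  lab2 <- c(rep("QS", 1770), rep("DI", 10),
            rep(c(rep("QS", 590), "DI"), 3), rep("DS", 240))
  curve2 <- qs_cumulative_curve(state_labels(lab2))
  expect_equal(max_slope_point(curve2), 30)
  # staircase agrees with the brute-force argmax of first differences
  set.seed(13)
  for (i in 1:10) {
    runs <- sample(c(90:3700), 8)
    lab3 <- unlist(lapply(runs, function(l) c(rep("QS", l), "DI")))
    curve3 <- qs_cumulative_curve(state_labels(lab3))
    inc <- diff(curve3$cum_pct)
    expected <- curve3$duration_min[which.max(inc)]
    expect_equal(max_slope_point(curve3), expected)
  }
  # flat curve returns the none-marker
  expect_true(is.na(max_slope_point(qs_cumulative_curve(
    state_labels(rep("DS", 7200))))))
})

test_that("displacement-duration distributions count threshold exceedances", {
  p <- c(rep(0.01, 10), rep(0.2, 2), rep(0.01, 5), rep(0.2, 2),
         rep(0.01, 5), rep(0.2, 5), rep(0.01, 10))
  pdfs <- di_duration_pdf(p, thresholds = c(0.05, 0.5))
  d05 <- pdfs[["0.05"]]
  expect_equal(d05$duration_s, c(2L, 5L))
  expect_equal(d05$prob, c(2 / 3, 1 / 3))
  # never exceeded -> empty distribution
  expect_equal(nrow(pdfs[["0.5"]]), 0)
})

test_that("raising the threshold never increases total event seconds", {
  set.seed(14)
  p <- runif(5000)^2
  ths <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.35, 0.5)
  pdfs <- di_duration_pdf(p, thresholds = ths)
  secs <- sapply(pdfs, function(d) sum(d$duration_s * d$count))
  expect_true(all(diff(secs) <= 0))
  # masses are a probability distribution whenever events exist
  for (d in pdfs) {
    if (nrow(d)) expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
})
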