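norm_sig <- function(values, fs = 1) {
  motion_signal(values / max(values), fs = fs, normalized = TRUE,
                norm_max = max(values))
}

test_that("window power averages squared samples per second", {
  # 2-s signal at 4 Hz: first second zeros, second second ones
  sig <- motion_signal(c(0, 0, 0, 0, 1, 1, 1, 1), fs = 4, normalized = TRUE,
                       norm_max = 1)
  expect_equal(window_power(sig)$values, c(0, 1))
  # constant envelope c -> power c^2 everywhere
  sig_c <- motion_signal(rep(1, 40), fs = 4, normalized = TRUE, norm_max = 1)
  expect_equal(window_power(sig_c)$values, rep(1, 10))
  # trailing partial window dropped
  sig_p <- motion_signal(rep(1, 11), fs = 4, normalized = TRUE, norm_max = 1)
  expect_length(window_power(sig_p)$values, 2)
  expect_error(suppressWarnings(
    window_power(motion_signal(c(1, 1), fs = 4, normalized = FALSE))),
    "shorter")
  expect_warning(window_power(motion_signal(rep(2, 8), fs = 4)),
                 "non-normalized")
})

test_that("coarse thresholding uses strict inequalities with ties to MID", {
  p <- c(0, 0.0005, 0.001, 0.01, 0.05, 0.06, 1)
  lab <- classify_coarse(p, th_abs = 0.001, th_di = 0.05)
  expect_identical(lab, c("ABS", "ABS", "MID", "MID", "MID", "DI", "DI"))
  expect_error(classify_coarse(p, th_abs = 0.05, th_di = 0.05), "th_abs < th_di")
})

test_that("quiet/disrupted refinement applies the minimum-QS rule", {
  # 20-min mid run between two displacement seconds -> QS
  coarse <- c("DI", rep("MID", 1200), "DI")
  lab <- refine_qs_ds(coarse, min_qs_s = 900)
  expect_identical(unique(lab$labels[2:1201]), "QS")
  # 5-min mid run -> DS
  coarse <- c("DI", rep("MID", 300), "DI")
  expect_identical(unique(refine_qs_ds(coarse, 900)$labels[2:301]), "DS")
  # run of exactly minQS counts as QS
  coarse <- c("DI", rep("MID", 900), "DI")
  expect_identical(unique(refine_qs_ds(coarse, 900)$labels[2:901]), "QS")
  # boundary runs judged by observed length
  coarse <- c(rep("MID", 899), "DI")
  expect_identical(unique(refine_qs_ds(coarse, 900)$labels[1:899]), "DS")
})

test_that("refinement is idempotent and depends only on run lengths", {
  set.seed(5)
  coarse <- sample(c("MID", "DI", "ABS"), 3000, replace = TRUE,
                   prob = c(0.9, 0.05, 0.05))
  lab1 <- refine_qs_ds(coarse, 300)
  # re-deriving coarse states from the refined labels and refining again
  # changes nothing
  coarse2 <- ifelse(lab1$labels %in% c("QS", "DS"), "MID", lab1$labels)
  expect_identical(refine_qs_ds(coarse2, 300)$labels, lab1$labels)
  # maximal mid-power runs interleaved with displacement runs: permuting
  # the runs (keeping the interleaving, so runs stay maximal) preserves
  # the percentages and the event-duration multiset
  set.seed(6)
  mid_len <- sample(c(5:50, 250:400), 15)
  di_len <- sample(1:20, 15, replace = TRUE)
  build <- function(ord_mid, ord_di) {
    unlist(lapply(seq_along(ord_mid), function(k) {
      c(rep("MID", mid_len[ord_mid[k]]), rep("DI", di_len[ord_di[k]]))
    }))
  }
  s1 <- summarize_states(refine_qs_ds(build(1:15, 1:15), 300))
  s2 <- summarize_states(refine_qs_ds(build(sample(15), sample(15)), 300))
  expect_equal(s1$qs_pct, s2$qs_pct)
  expect_equal(s1$di_pct, s2$di_pct)
  expect_equal(sort(s1$di_durations_s), sort(s2$di_durations_s))
})

test_that("state summary counts percentages and displacement events", {
  lab <- c(rep("QS", 3000), rep("DS", 500), rep("DI", 500))
  s <- summarize_states(lab)
  expect_equal(c(s$qs_pct, s$ds_pct, s$di_pct, s$abs_pct),
               c(75, 12.5, 12.5, 0))
  expect_equal(s$dsdi_pct, 25)
  expect_equal(s$n_di_events, 1)
  expect_equal(s$di_durations_s, 500)
  s_all <- summarize_states(rep("QS", 100))
  expect_equal(s_all$qs_pct, 100)
  expect_equal(s_all$dsdi_pct, 0)
})

test_that("state percentages always sum to exactly 100", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(50:2000, 1)
    lab <- sample(c("ABS", "QS", "DS", "DI"), n, replace = TRUE)
    s <- summarize_states(lab)
    expect_equal(s$qs_pct + s$ds_pct + s$di_pct + s$abs_pct, 100,
                 tolerance = 1e-9)
  }
})

test_that("raising thresholds moves seconds monotonically", {
  set.seed(8)
  p <- runif(2000)^3
  th_seq <- c(0.05, 0.1, 0.3)
  mid_abs <- sapply(th_seq, function(th) {
    sum(classify_coarse(p, 0.001, th) != "DI")
  })
  expect_true(all(diff(mid_abs) >= 0))
  # raising min_qs never increases the quiet-sleep share
  coarse <- classify_coarse(p, 0.001, 0.3)
  qs <- sapply(c(60, 300, 900), function(m) {
    summarize_states(refine_qs_ds(coarse, m))$qs_pct
  })
  expect_true(all(diff(qs) <= 0))
})

test_that("absence-threshold calibration matches exhaustive J maximization", {
  # perfectly separable: threshold in the gap with J = 1
  e <- c(1e-4, 2e-4, 5e-4)
  o <- c(2e-3, 4e-3, 9e-3)
  th <- calibrate_abs_threshold(e, o)
  expect_gt(th, 5e-4)
  expect_lt(th, 2e-3)
  expect_equal(attr(th, "youden_j"), 1)
  # overlapping small samples equal the brute-force oracle
  set.seed(9)
  for (i in 1:10) {
    e <- rexp(sample(4:10, 1), rate = 2000)
    o <- rexp(sample(4:10, 1), rate = 400)
    expect_equal(as.numeric(calibrate_abs_threshold(e, o)),
                 brute_youden_threshold(e, o))
  }
  # indistinguishable distributions fall back to the pooled median
  x <- c(1, 2, 3, 4)
  expect_warning(th0 <- calibrate_abs_threshold(x, x), "indistinguishable")
  expect_equal(th0, stats::median(c(x, x)))
})

test_that("classify_states wires power, thresholds and refinement together", {
  set.seed(10)
  v <- c(rep(0.02, 1000), rep(0.9, 5), rep(0.02, 300), rep(0.9, 5),
         rep(0.02, 1000))
  sig <- norm_sig(rep(sqrt(v), each = 2), fs = 2)
  lab <- classify_states(sig, th_abs = 1e-4, th_di = 0.05, min_qs_s = 900)
  s <- summarize_states(lab)
  expect_equal(s$n_di_events, 2)
  expect_equal(s$ds_pct * length(lab$labels) / 100, 300, tolerance = 1e-9)
})
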