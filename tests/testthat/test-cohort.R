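test_that("sleep efficiency and event index follow their definitions", {
  expect_equal(sleep_efficiency(8, 10), 0.8)
  expect_equal(sleep_efficiency(6.5, 6.5), 1)
  expect_equal(sleep_efficiency(0, 8), 0)
  expect_error(sleep_efficiency(9, 8), "st_h")
  # printed cohort rows round-trip at table precision
  expect_equal(round(ahi(145, 9.66), 2), 15.01)
  expect_lt(abs(ahi(319, 6.79) - 46.97), 0.02)
  expect_equal(ahi(0, 8), 0)
  expect_error(ahi(10, 0), "positive")
})

test_that("severity bands are half-open exactly as defined", {
  expect_equal(as.character(ahi_category(c(3.49, 15.01, 5, 30, 0, 14.99, 29.9))),
               c("N", "Mo", "Mi", "S", "N", "Mi", "Mo"))
})

test_that("efficiency grouping is strict at 80%", {
  expect_equal(as.character(efficiency_group(c(0.81, 0.80, 0.79))),
               c("GSE", "BSE", "BSE"))
})

test_that("pearson correlation is exact on affine relations and guarded", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  set.seed(20)
  a <- rnorm(30); b <- rnorm(30)
  r0 <- pearson_r(a, b)
  expect_equal(pearson_r(3 * a - 7, b / 2 + 1), r0, tolerance = 1e-12)
  expect_warning(rna <- pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(rna))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("leave-one-out folds match brute-force enumeration", {
  expect_equal(loocv_correlation(1:6, 2 * (1:6) + 3)$mean, 1)
  expect_equal(loocv_correlation(1:6, 2 * (1:6) + 3)$sd, 0)
  set.seed(21)
  x <- rnorm(5); y <- rnorm(5)
  res <- loocv_correlation(x, y)
  brute <- sapply(1:5, function(i) cor(x[-i], y[-i]))
  expect_equal(res$fold_r, brute)
  expect_equal(res$mean, mean(brute))
  expect_equal(res$sd, sqrt(mean((brute - mean(brute))^2)))
})

test_that("Bland-Altman limits bracket the differences", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$lower, 0)
  ba_c <- bland_altman(x + 2.5, x)
  expect_equal(ba_c$mean_diff, 2.5)
  expect_equal(ba_c$sd_diff, 0)
  set.seed(22)
  a <- rnorm(10); b <- rnorm(10)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$outside_count, sum(d < ba$lower | d > ba$upper))
})

test_that("Mann-Whitney exact p equals full permutation enumeration", {
  # identical samples: maximal two-sided p
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # complete separation of 3 vs 3: U = 9, exact p = 2/20
  res <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_true(res$U %in% c(0, 9))
  expect_equal(res$p, 0.1)
  expect_identical(res$method, "exact")
  set.seed(23)
  for (i in 1:15) {
    a <- sample(1:8, sample(3:5, 1), replace = TRUE)
    b <- sample(1:8, sample(3:5, 1), replace = TRUE)
    expect_equal(mann_whitney(a, b)$p, perm_mw_p(a, b))
  }
})

test_that("large-sample Mann-Whitney agrees with the standard implementation", {
  set.seed(24)
  a <- rnorm(15); b <- rnorm(12, mean = 0.8)
  res <- mann_whitney(a, b)
  expect_identical(res$method, "normal")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(res$U, unname(ref$statistic))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("uncertainty rules flag anomalous metric combinations", {
  rec <- data.frame(se = c(0.95, 0.77, 0.58, 0.5), ahi = c(40.99, 15.01, 12.87, NA))
  expect_equal(uncertain_flags(rec), c(TRUE, FALSE, FALSE, FALSE))
  # hypopnea-dominated recordings flagged when the fraction is known
  hf <- c(NA, NA, 0.85, 0.9)
  expect_equal(uncertain_flags(rec, hypopnea_frac = hf),
               c(TRUE, FALSE, TRUE, TRUE))
  # a record with no AHI is never flagged by the SE/AHI rule
  expect_false(uncertain_flags(data.frame(se = 0.99, ahi = NA)))
})

test_that("packaged cohort tables load with the documented structure", {
  d <- load_fixture_tables()
  expect_equal(nrow(d), 44)
  expect_equal(sum(d$dataset == "apnea"), 22)
  expect_equal(sum(d$uncertain), 4)
  expect_equal(d$rec[d$uncertain], c(1, 3, 13, 15))
  r6 <- d[d$rec == 6, ]
  expect_equal(r6$se, 0.66)
  expect_equal(r6$ahi, 50.63)
  expect_equal(c(r6$qs_pct, r6$ds_pct, r6$di_pct), c(10.15, 72.20, 17.65))
  expect_equal(r6$dsdi_pct, 89.85)
  expect_true(all(abs(d$qs_pct + d$ds_pct + d$di_pct - 100) <= 0.02))
  # grouping counts
  nu <- d[!d$uncertain, ]
  expect_equal(as.integer(table(nu$efficiency_group)), c(19, 21))
  ap <- nu[nu$dataset == "apnea", ]
  expect_equal(sum(ap$severity %in% c("N", "Mi")), 10)
  expect_equal(sum(ap$severity %in% c("Mo", "S")), 8)
})
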