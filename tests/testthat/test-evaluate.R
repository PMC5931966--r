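test_that("bland_altman computes bias and symmetric limits of agreement", {
  ba <- bland_altman(c(60, 70, 80), c(50, 50, 50))
  expect_equal(ba$bias, 20)
  expect_equal(ba$sd, 10)
  expect_equal(ba$loa_low, 0.4)
  expect_equal(ba$loa_high, 39.6)
  expect_equal(ba$n, 3L)
  # identical inputs collapse to zero
  ba0 <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  # symmetry property across random paired samples
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    ba <- bland_altman(runif(n, 0, 100), runif(n, 0, 100))
    expect_equal(ba$loa_low + ba$loa_high, 2 * ba$bias, tolerance = 1e-12)
    expect_gte(ba$loa_high, ba$loa_low)
  }
  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("clopper_pearson matches the exact closed forms and its properties", {
  ci <- clopper_pearson(24, 24)
  expect_equal(ci[["low"]], 100 * 0.025^(1 / 24), tolerance = 1e-9)
  expect_equal(ci[["high"]], 100)
  expect_equal(clopper_pearson(0, 10)[["low"]], 0)
  expect_equal(clopper_pearson(7, 7)[["high"]], 100)
  # contains k/n; widens as n decreases at fixed k/n
  for (n in c(8, 16, 64)) {
    k <- n / 2
    ci <- clopper_pearson(k, n)
    expect_lt(ci[["low"]], 50); expect_gt(ci[["high"]], 50)
  }
  w <- function(n) diff(clopper_pearson(n / 2, n))
  expect_gt(w(8), w(16))
  expect_gt(w(16), w(64))
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(-1, 4), "k <= n")
})

test_that("diagnostic_performance reproduces hand-computed confusion metrics", {
  # counts 30/13/11/0 (chosen to match sens 100, spec 45.8, ppv 69.8)
  truth <- c(rep(60, 30), rep(30, 24))
  measured <- c(rep(70, 30), rep(55, 13), rep(20, 11))
  dp <- diagnostic_performance(measured, truth, 50)
  expect_equal(c(dp$tp, dp$fp, dp$tn, dp$fn), c(30, 13, 11, 0))
  expect_equal(dp$tp + dp$fp + dp$tn + dp$fn, dp$n)
  expect_equal(dp$sensitivity$value, 100)
  expect_equal(round(dp$specificity$value, 1), 45.8)
  expect_equal(round(dp$ppv$value, 1), 69.8)
  expect_equal(dp$npv$value, 100)
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- dp[[m]]
    expect_true(v$ci[["low"]] <= v$value && v$value <= v$ci[["high"]])
  }
  # perfect agreement
  dperf <- diagnostic_performance(c(80, 20), c(80, 20), 50)
  for (m in c("sensitivity", "specificity", "ppv", "npv"))
    expect_equal(dperf[[m]]$value, 100)
  # all negative: ppv undefined, not NaN
  dneg <- diagnostic_performance(c(10, 20), c(10, 20), 50)
  expect_true(dneg$ppv$undefined)
  expect_true(is.na(dneg$ppv$value))
  expect_equal(dneg$specificity$value, 100)
  # relabeling symmetry: flipping both classifications about the threshold
  # swaps sensitivity and specificity
  set.seed(5)
  meas <- runif(30, 0, 100); tru <- runif(30, 0, 100)
  a <- diagnostic_performance(meas, tru, 50)
  b <- diagnostic_performance(100 - meas + 1e-9, 100 - tru + 1e-9, 50)
  expect_equal(a$sensitivity$value, b$specificity$value, tolerance = 1e-9)
  expect_equal(a$specificity$value, b$sensitivity$value, tolerance = 1e-9)
})

test_that("plaque_change implements the RCV/RDS/RAS reduction formulas", {
  ch <- plaque_change(plaque_quant(35.1, 34.7, 50.1),
                      plaque_quant(19.3, 18.4, 27.2))
  expect_equal(round(ch$rcv, 1), 45.0)
  expect_equal(round(ch$rds, 1), 47.0)
  expect_equal(round(ch$ras, 1), 45.7)
  # no-op de-blooming run reduces nothing
  same <- plaque_quant(10, 40, 60)
  ch0 <- plaque_change(same, same)
  expect_equal(c(ch0$rcv, ch0$rds, ch0$ras), c(0, 0, 0))
  # zero before-values are flagged, not divided
  chz <- plaque_change(plaque_quant(0, 0, 0), plaque_quant(0, 0, 0))
  expect_true(all(chz$undefined))
  expect_true(is.na(chz$rcv))
})

test_that("iq_summary tallies scores and the diagnostic proportion", {
  s1 <- rep(1:4, times = c(100, 174, 74, 27))
  q1 <- iq_summary(s1)
  expect_equal(q1$percent_diagnostic, 92.8)
  expect_equal(unname(q1$counts), c(100, 174, 74, 27))
  expect_equal(q1$n, 375L)
  expect_equal(sum(q1$counts), q1$n)
  s2 <- rep(1:4, times = c(119, 198, 54, 4))
  q2 <- iq_summary(s2)
  expect_equal(q2$percent_diagnostic, 98.9)
  expect_equal(unname(q2$percents[1]), 31.7)
  q3 <- iq_summary(rep(1L, 10))
  expect_equal(q3$percent_diagnostic, 100)
  expect_equal(unname(q3$percents[1]), 100)
  expect_error(iq_summary(integer(0)), "non-empty")
  expect_error(iq_summary(c(1, 5)), "1..4")
})

test_that("group_compare reports means, SDs and a t-test p-value", {
  set.seed(8)
  g <- group_compare(rnorm(20, 50, 5), rnorm(20, 60, 5))
  expect_lt(g$p_value, 0.01)
  expect_lt(g$mean_x, g$mean_y)
  expect_error(group_compare(1, 1:5), ">= 2")
})
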