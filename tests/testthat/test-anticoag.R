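test_that("Rosendaal TTR matches hand-interpolated crossings", {
  # all in range
  expect_equal(rosendaal_ttr(c(0, 7, 14), c(2.1, 2.3, 2.2), c(2.0, 2.5)),
               100)
  # 2.0 -> 3.0 over 10 days, range 2.0-2.5: crosses 2.5 at day 5
  expect_equal(rosendaal_ttr(c(0, 10), c(2.0, 3.0), c(2.0, 2.5)), 50)
  # 1.5 -> 2.5 over 4 days, range 2.0-3.0: crosses 2.0 at day 2
  expect_equal(rosendaal_ttr(c(0, 4), c(1.5, 2.5), c(2.0, 3.0)), 50)
  # single measurement undefined
  expect_true(is.na(rosendaal_ttr(5, 2.2, c(2, 3))))
  # long gaps excluded from numerator and denominator
  expect_equal(rosendaal_ttr(c(0, 7, 100), c(2.2, 2.3, 5), c(2, 3)), 100)
  expect_true(is.na(rosendaal_ttr(c(0, 100), c(2.2, 2.3), c(2, 3))))
})

test_that("range boundaries count as in range (closed interval)", {
  # constant series exactly on the limits
  expect_equal(rosendaal_ttr(c(0, 10), c(2.5, 2.5), c(2.0, 2.5)), 100)
  expect_equal(rosendaal_ttr(c(0, 10), c(2.0, 2.0), c(2.0, 2.5)), 100)
  expect_equal(inr_proportions(c(2.0, 2.5), c(2.0, 2.5))$pct[["in_range"]],
               100)
})

test_that("TTR is invariant under uniform time shifts", {
  set.seed(31)
  days <- cumsum(c(0, sample(1:10, 5)))
  inrs <- runif(6, 1.5, 3.5)
  base <- rosendaal_ttr(days, inrs, c(2, 3))
  for (shift in c(-3, 11, 100)) {
    expect_equal(rosendaal_ttr(days + shift, inrs, c(2, 3)), base)
  }
})

test_that("exact TTR agrees with a dense numerical oracle", {
  set.seed(47)
  for (i in 1:200) {
    n <- sample(3:9, 1)
    days <- cumsum(c(0, sample(1:14, n - 1, replace = TRUE)))
    inrs <- round(runif(n, 1.0, 4.0), 2)
    target <- sort(round(runif(2, 1.5, 3.2), 1))
    if (target[1] == target[2]) target[2] <- target[2] + 0.5
    exact <- rosendaal_ttr(days, inrs, target)
    oracle <- ttr_oracle(days, inrs, target)
    expect_lt(abs(exact - oracle), 0.1, label = paste("series", i))
  }
})

test_that("INR proportions reproduce count-derived percentages", {
  mk <- function(n_in, n_above, n_below) {
    c(rep(2.2, n_in), rep(3.5, n_above), rep(1.2, n_below))
  }
  pr <- inr_proportions(mk(749, 145, 1210 - 749 - 145), c(2.0, 2.5))
  expect_equal(pr$pct[["in_range"]], 61.9)
  expect_equal(pr$pct[["above"]], 12.0)
  expect_equal(pr$n, 1210L)
  all_in <- inr_proportions(rep(2.2, 5), c(2, 2.5))
  expect_equal(unname(all_in$pct), c(100, 0, 0))
  expect_error(inr_proportions(numeric(0), c(2, 3)), "no INR")
})

test_that("windowed summaries clip straddling segments at the bound", {
  # measurements only within 0-30: identical rows for all windows
  rec <- patient_record("w", 60, 165, 70, indication = "other",
                        visits = data.frame(day = c(0, 10, 25),
                                            inr = c(2.2, 2.5, 2.8),
                                            dose = rep(2.5, 3)))
  ws <- windowed_summary(warfdose:::as_cohort(list(rec)))
  expect_equal(ws$median_ttr[1], ws$median_ttr[2])
  expect_equal(ws$median_ttr[2], ws$median_ttr[3])
  expect_equal(ws$pct_in, rep(ws$pct_in[1], 3))

  # segment straddling day 30: clipped TTR must match a numerical oracle
  rec2 <- patient_record("w2", 60, 165, 70, indication = "other",
                         visits = data.frame(day = c(0, 20, 40),
                                             inr = c(1.8, 2.4, 3.6),
                                             dose = rep(2.5, 3)))
  ws2 <- windowed_summary(warfdose:::as_cohort(list(rec2)), windows = 30)
  inr_at_30 <- 2.4 + (3.6 - 2.4) * (30 - 20) / (40 - 20)
  oracle <- ttr_oracle(c(0, 20, 30), c(1.8, 2.4, inr_at_30), c(2, 3))
  expect_lt(abs(ws2$median_ttr - oracle), 0.1)
  # clipped synthetic endpoint is interpolated, not measured: 2 measurements
  expect_equal(ws2$n_measurements, 2L)

  # empty window: missing TTR, zero counts
  late <- patient_record("w3", 60, 165, 70, indication = "other",
                         visits = data.frame(day = c(40, 50),
                                             inr = c(2.2, 2.4),
                                             dose = c(2.5, 2.5)))
  ws3 <- windowed_summary(warfdose:::as_cohort(list(late)), windows = 30)
  expect_true(is.na(ws3$median_ttr))
  expect_equal(ws3$n_measurements, 0L)
  expect_true(is.na(ws3$pct_in))
})

test_that("cohort TTR returns one row per patient", {
  coh <- fixture_cohort()
  tt <- cohort_ttr(coh)
  expect_equal(nrow(tt), length(coh))
  expect_true(all(tt$ttr >= 0 & tt$ttr <= 100, na.rm = TRUE))
})
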