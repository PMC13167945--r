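test_that("classification respects the inclusive tolerance band", {
  expect_equal(as.character(classify(2.0, 2.0)), "within")
  expect_equal(as.character(classify(2.4, 2.0, tol = 0.20)), "within")
  expect_equal(as.character(classify(1.6, 2.0, tol = 0.20)), "within")
  expect_equal(as.character(classify(2.7, 2.0, tol = 0.20)), "over")
  expect_equal(as.character(classify(1.5, 2.0, tol = 0.20)), "under")
  expect_error(classify(1, 0), "positive")
  # scale equivariance
  set.seed(12)
  p <- runif(50, 0.5, 6)
  r <- runif(50, 0.5, 6)
  for (k in c(0.1, 1, 7.3)) {
    expect_identical(classify(k * p, k * r), classify(p, r))
  }
})

test_that("accuracy summaries reproduce count-derived percentages", {
  mk <- function(w, o, u) {
    factor(rep(c("within", "over", "under"), c(w, o, u)),
           levels = c("within", "over", "under"))
  }
  s <- accuracy_summary(mk(1160, 485, 96))
  expect_equal(unname(s$pct), c(66.6, 27.9, 5.5))
  expect_equal(s$n, 1741L)
  s2 <- accuracy_summary(mk(470, 184, 3))
  expect_equal(unname(s2$pct), c(71.5, 28.0, 0.5))
  s3 <- accuracy_summary(mk(10, 0, 0))
  expect_equal(unname(s3$pct), c(100, 0, 0))
  # partition: percentages sum to 100 before rounding
  set.seed(3)
  for (i in 1:10) {
    counts <- rpois(3, 50) + 1
    s <- accuracy_summary(mk(counts[1], counts[2], counts[3]))
    expect_equal(sum(s$counts) / s$n, 1)
  }
  expect_error(accuracy_summary(factor(character())), "no outcomes")
})

test_that("stable-dose detection follows the window rules", {
  mk <- function(days, doses, inrs, ind = "mechanical_valve") {
    patient_record("s", 60, 165, 70, indication = ind,
                   visits = data.frame(day = days, inr = inrs, dose = doses))
  }
  # days 7,14,21 at one dose, in-range INRs
  r <- mk(c(7, 14, 21), rep(2.5, 3), c(2.1, 2.2, 2.3))
  sd <- detect_stable_dose(r)
  expect_equal(sd$dose, 2.5)
  expect_equal(sd$window, c(start = 7, end = 21))
  # dose change breaks the run
  expect_null(detect_stable_dose(mk(c(7, 10, 21), c(2.5, 3, 3),
                                    c(2.1, 2.2, 2.3))))
  # an out-of-range INR inside the window disqualifies it
  expect_null(detect_stable_dose(mk(c(7, 14, 21), rep(2.5, 3),
                                    c(2.1, 2.9, 2.3))))
  # window must begin at/after day 7 under the default rule
  expect_null(detect_stable_dose(mk(c(0, 5, 14), rep(2.5, 3),
                                    c(2.1, 2.2, 2.3))))
  # ...but visits before day 7 are trimmed, not fatal
  r2 <- mk(c(3, 7, 14, 22), rep(2.5, 4), c(2.1, 2.2, 2.3, 2.2))
  expect_equal(detect_stable_dose(r2)$window, c(start = 7, end = 22))
  # the alternative reading accepts windows starting early
  alt <- detect_stable_dose(mk(c(0, 5, 14), rep(2.5, 3), c(2.1, 2.2, 2.3)),
                            window_rule = "starts_within_7d")
  expect_equal(alt$window, c(start = 0, end = 14))
})

test_that("stable-dose detection agrees with a brute-force window scan", {
  brute <- function(record, min_days = 14) {
    v <- record$visits
    lo <- record$target[["low"]]; hi <- record$target[["high"]]
    for (i in seq_len(nrow(v))) {
      for (j in seq_len(nrow(v))) {
        if (j <= i) next
        idx <- i:j
        if (v$day[i] < 7) next
        if (length(unique(v$dose[idx])) != 1L) next
        if (v$day[j] - v$day[i] < min_days) next
        if (all(v$inr[idx] >= lo & v$inr[idx] <= hi)) return(TRUE)
      }
    }
    FALSE
  }
  set.seed(19)
  for (i in 1:200) {
    n <- sample(3:7, 1)
    rec <- patient_record(
      "b", 60, 165, 70, indication = "other",
      visits = data.frame(day = sort(sample(0:40, n)),
                          inr = round(runif(n, 1.6, 3.4), 1),
                          dose = sample(c(2.5, 2.75), n, replace = TRUE)))
    expect_equal(!is.null(detect_stable_dose(rec)), brute(rec),
                 info = paste("case", i))
  }
})

test_that("stable-dose accuracy classifies against the stable dose", {
  coh <- generate_cohort(40, seed = 71)
  art <- tiny_artifact()
  # a perfect predictor: overwrite predictions via a stub artifact is not
  # possible, so check the classification arithmetic directly instead
  res <- stable_dose_accuracy(art, coh)
  if (!is.null(res$summary)) {
    expect_equal(sum(res$summary$counts), res$summary$n)
    expect_true(all(res$outcomes$reference > 0))
  }
  # perfect and inflated predictors via hand-built outcomes
  stable <- 2.5
  perfect <- prediction_outcomes(rep(stable, 5), rep(stable, 5))
  expect_equal(unname(accuracy_summary(perfect)$pct), c(100, 0, 0))
  inflated <- prediction_outcomes(rep(1.25 * stable, 5), rep(stable, 5))
  expect_equal(unname(accuracy_summary(inflated)$pct), c(0, 100, 0))
})

test_that("per-visit accuracy bins by decision index and drops empty bins", {
  out <- data.frame(
    visit = c(1L, 1L, 2L, 2L, 12L),
    klass = factor(c("within", "over", "within", "within", "within"),
                   levels = c("within", "over", "under")))
  pv <- per_visit_accuracy(out, max_index = 10)
  expect_equal(pv$visit, c("1", "2", ">10"))
  expect_equal(pv$accuracy, c(50, 100, 100))
  expect_equal(pv$n, c(2L, 2L, 1L))
})

test_that("sensitivity subgroups follow the decision table and are total", {
  sg <- function(c9, vk) sensitivity_subgroup(genotype(c9, vk))
  expect_equal(sg("*1/*1", "GG"), "normal")
  expect_equal(sg("*1/*1", "GA"), "normal")
  expect_equal(sg("*1/*1", "AA"), "sensitive")
  expect_equal(sg("*1/*3", "GA"), "sensitive")
  expect_equal(sg("*1/*3", "AA"), "highly_sensitive")
  expect_equal(sg("*2/*3", "AA"), "highly_sensitive")
  for (c9 in c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3")) {
    for (vk in c("GG", "GA", "AA")) {
      expect_true(sg(c9, vk) %in%
                    c("normal", "sensitive", "highly_sensitive"))
    }
  }
  expect_equal(sensitivity_subgroup(genotype(known = FALSE)), "unclassified")
})

test_that("genotype ablation is minimal, idempotent and model-visible", {
  coh <- fixture_cohort()
  abl <- ablate_genotype(coh)
  expect_identical(abl, ablate_genotype(abl))
  for (i in seq_along(coh)) {
    expect_false(abl[[i]]$fixed$genotype$known)
    same <- coh[[i]]
    same$fixed$genotype$known <- FALSE
    expect_identical(abl[[i]], same)
  }
  # a model with nonzero genotype weights predicts differently after ablation
  art <- tiny_artifact()
  rec <- Filter(function(p) p$fixed$genotype$vkorc1 != "GA", coh)[[1]]
  p1 <- predict_dose(art, rec, 3)
  p2 <- predict_dose(art, ablate_genotype(list(rec))[[1]], 3)
  expect_gt(abs(p1 - p2), 0)
})

test_that("error summaries report moments under the stated sign convention", {
  out <- prediction_outcomes(c(1, 2, 3), c(2, 2, 2))
  es <- error_summary(out)
  expect_equal(es$mean, 0)
  expect_equal(es$sd, 1)
  expect_equal(es$skewness, 0)
  expect_match(es$sign_convention, "predicted - reference")
  # all-zero errors degenerate cleanly
  es0 <- error_summary(prediction_outcomes(c(2, 2), c(2, 2)))
  expect_equal(es0$sd, 0)
  expect_equal(es0$skewness, 0)
  # over-prediction shows up as positive mean error
  eso <- error_summary(prediction_outcomes(c(3, 3.5), c(2, 2)))
  expect_gt(eso$mean, 0)
})
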