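# The network is hand-authored (forward + backpropagation through time), so
# the gradient itself is under test: analytic gradients must match central
# finite differences on every parameter block.

test_that("backpropagation matches finite differences", {
  coh <- fixture_cohort()
  samples <- cohort_samples(coh)
  lens <- vapply(samples, function(s) nrow(s$steps), integer(1))
  stats <- sample_stats(samples)
  batch <- collate(samples[c(which(lens == 2)[1], which(lens == 4)[1],
                             which(lens == 5)[1])], stats)
  cfg <- dose_model_config(hidden_size = 4, num_layers = 2,
                           bidirectional = TRUE, ffn_hidden = 3, seed = 11)
  params <- warfdose:::nn_init(cfg)
  loss <- function(p) {
    out <- warfdose:::nn_forward(p, batch, cfg)
    mean((out$pred - batch$y)^2)
  }
  out <- warfdose:::nn_forward(params, batch, cfg)
  grads <- warfdose:::nn_backward(params, out$cache,
                                  2 * (out$pred - batch$y) / length(batch$y),
                                  cfg)
  blocks <- list(c("ffn", "W1"), c("ffn", "b1"), c("head", "W"),
                 list("lstm", 1L, 1L, "W"), list("lstm", 1L, 2L, "U"),
                 list("lstm", 2L, 1L, "U"), list("lstm", 2L, 2L, "b"))
  get_p <- function(lst, path) { for (k in path) lst <- lst[[k]]; lst }
  set_p <- function(lst, path, v) {
    if (length(path) == 1) { lst[[path[[1]]]] <- v; return(lst) }
    lst[[path[[1]]]] <- set_p(lst[[path[[1]]]], path[-1], v)
    lst
  }
  set.seed(4)
  for (path in blocks) {
    p <- get_p(params, path)
    g <- get_p(grads, path)
    for (i in sample(length(p), min(3L, length(p)))) {
      eps <- 1e-5
      pp <- p; pp[i] <- p[i] + eps
      lp <- loss(set_p(params, path, pp))
      pp[i] <- p[i] - eps
      lm <- loss(set_p(params, path, pp))
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[i]), 1e-6 + 1e-4 * abs(num))
    }
  }
})

test_that("recurrent representation width doubles when bidirectional", {
  samples <- cohort_samples(fixture_cohort())[1:3]
  stats <- sample_stats(samples)
  batch <- collate(samples, stats)
  for (bi in c(TRUE, FALSE)) {
    cfg <- dose_model_config(hidden_size = 128, num_layers = 1,
                             bidirectional = bi, ffn_hidden = 4, seed = 1)
    out <- warfdose:::nn_forward(warfdose:::nn_init(cfg), batch, cfg)
    expect_equal(ncol(out$cache$pooled), if (bi) 256L else 128L)
  }
})

test_that("padding never changes predictions", {
  samples <- cohort_samples(fixture_cohort())
  lens <- vapply(samples, function(s) nrow(s$steps), integer(1))
  stats <- sample_stats(samples)
  cfg <- dose_model_config(hidden_size = 6, num_layers = 2,
                           bidirectional = TRUE, ffn_hidden = 4, seed = 2)
  params <- warfdose:::nn_init(cfg)
  short <- samples[[which(lens == 2)[1]]]
  long <- samples[[which(lens == 5)[1]]]
  alone <- warfdose:::nn_forward(params, collate(list(short), stats), cfg)
  padded <- warfdose:::nn_forward(params, collate(list(short, long), stats),
                                  cfg)
  expect_equal(padded$pred[1], alone$pred, tolerance = 1e-12)
})

test_that("a unidirectional model is direction sensitive", {
  samples <- cohort_samples(fixture_cohort())
  lens <- vapply(samples, function(s) nrow(s$steps), integer(1))
  s <- samples[[which(lens == 5)[1]]]
  stats <- sample_stats(samples)
  cfg <- dose_model_config(hidden_size = 6, num_layers = 1,
                           bidirectional = FALSE, ffn_hidden = 4, seed = 3)
  params <- warfdose:::nn_init(cfg)
  fwd <- warfdose:::nn_forward(params, collate(list(s), stats), cfg)
  srev <- s
  srev$steps <- s$steps[nrow(s$steps):1, ]
  rev <- warfdose:::nn_forward(params, collate(list(srev), stats), cfg)
  expect_gt(abs(fwd$pred - rev$pred), 1e-8)
})

test_that("zeroed recurrent branch makes histories indistinguishable", {
  samples <- cohort_samples(fixture_cohort())
  # two samples from the same patient: same fixed covariates, different
  # histories
  pid <- samples[[1]]$meta$patient_id
  same <- Filter(function(s) s$meta$patient_id == pid, samples)[1:2]
  stats <- sample_stats(samples)
  cfg <- dose_model_config(hidden_size = 4, num_layers = 1,
                           bidirectional = TRUE, ffn_hidden = 4, seed = 4)
  params <- warfdose:::nn_init(cfg)
  for (d in 1:2) {
    params$lstm[[1]][[d]]$W[] <- 0
    params$lstm[[1]][[d]]$U[] <- 0
    params$lstm[[1]][[d]]$b[] <- 0
  }
  out <- warfdose:::nn_forward(params, collate(same, stats), cfg)
  expect_equal(out$pred[1], out$pred[2], tolerance = 1e-12)
})

test_that("predict_dose equals forward-after-collate and clamps", {
  art <- tiny_artifact()
  rec <- fixture_cohort()[[2]]
  s <- build_samples(rec)[[2]]
  batch <- collate(list(s), art$stats)
  direct <- warfdose:::nn_forward(art$params, batch, art$config)
  expect_equal(predict_dose(art, rec, at_visit = 3),
               max(0, min(denormalize(direct$pred, art$stats, "dose"),
                          art$config$max_dose)))
  expect_error(predict_dose(art, rec, at_visit = 1), "decision visit")
  # clamping at zero: force a hugely negative head bias
  low <- art
  low$params$head$b[] <- -1e6
  expect_equal(predict_dose(low, rec, at_visit = 3), 0)
})

test_that("INR and dose variants differ only in label wiring", {
  art_inr <- tiny_artifact("inr")
  rec <- fixture_cohort()[[1]]
  p <- predict_inr(art_inr, rec, at_visit = 2)
  expect_true(is.finite(p) && p >= 0)
  expect_error(predict_inr(tiny_artifact("dose"), rec, 2), "inr")
  # same code path: samples differ only in masked feature and label
  sd <- build_samples(rec, "dose")[[1]]
  si <- build_samples(rec, "inr")[[1]]
  expect_identical(sd$steps, si$steps)
  expect_identical(sd$fixed, si$fixed)
})

test_that("artifacts round-trip through save/load bit for bit", {
  art <- tiny_artifact()
  art$log <- data.frame(epoch = 1:2, train_loss = c(1, 0.5),
                        val_loss = c(1.1, 0.6), best = c(FALSE, TRUE))
  dir <- withr::local_tempdir()
  save_artifact(art, dir)
  back <- load_artifact(dir)
  rec <- fixture_cohort()[[3]]
  for (v in 2:4) {
    expect_identical(predict_dose(back, rec, v), predict_dose(art, rec, v))
  }
  expect_equal(back$config, art$config)
})
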