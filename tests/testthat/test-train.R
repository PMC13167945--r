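test_that("mse loss matches hand arithmetic and is symmetric in pairs", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(2, 4), c(1, 2)), 2.5)
  expect_equal(mse_loss(c(4, 2), c(2, 1)), 2.5) # permuting pairs
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_error(mse_loss(1:3, 1:2), "mismatch")
})

test_that("fit statistics satisfy their definitions and inequalities", {
  fs <- fit_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fs[c("mse", "mae", "rmse")], data.frame(mse = 0, mae = 0,
                                                       rmse = 0))
  expect_equal(fs$r2, 1)
  expect_equal(fs$accuracy, 100)
  # constant prediction at the mean: r2 = 0
  expect_equal(fit_stats(rep(2, 3), c(1, 2, 3))$r2, 0)
  fs2 <- fit_stats(c(2, 2, 2), c(1, 2, 3))
  expect_equal(fs2$mse, 2 / 3)
  expect_equal(fs2$rmse, sqrt(2 / 3))
  expect_equal(fs2$mae, 2 / 3)
  # zero-variance references: r2 undefined
  expect_true(is.na(fit_stats(c(1, 2), c(2, 2))$r2))
  # rmse^2 = mse and mae <= rmse on random evaluations
  set.seed(8)
  for (i in 1:20) {
    y <- runif(50, 1, 5)
    p <- y + rnorm(50, sd = 0.5)
    fs <- fit_stats(p, y)
    expect_equal(fs$rmse^2, fs$mse)
    expect_lte(fs$mae, fs$rmse)
    expect_lte(fs$r2, 1)
  }
})

test_that("early stopping halts exactly per the protocol", {
  # constant validation loss from epoch 1: stop after 1 + patience epochs
  expect_equal(stopping_epoch(rep(1, 100))$stop_epoch, 11L)
  # strictly improving: runs the full budget and keeps the last epoch best
  improving <- stopping_epoch(seq(1, 0.01, length.out = 100))
  expect_equal(improving$stop_epoch, 100L)
  expect_equal(improving$best_epoch, 100L)
  # improvements below min_delta do not count as progress
  expect_equal(stopping_epoch(1 - cumsum(rep(1e-6, 100)))$stop_epoch, 11L)
  # recovery resets the patience counter
  v <- c(1, rep(0.99999, 9), 0.5, rep(0.49999, 10))
  expect_equal(stopping_epoch(v)$stop_epoch, 21L)
  expect_equal(stopping_epoch(v)$best_epoch, 11L)
})

test_that("training respects the epoch budget and restores the best epoch", {
  coh <- generate_cohort(16, seed = 55)
  sp <- make_split(coh, seed = 1, k = 5)
  d <- split_samples(coh, sp, 1L, "dose")
  cfg <- dose_model_config(hidden_size = 3, num_layers = 1, ffn_hidden = 3,
                           max_epochs = 6, seed = 9)
  art <- train_one(cfg, d$train, d$val)
  expect_lte(nrow(art$log), 6L)
  best_val <- art$log$val_loss[art$log$best]
  expect_lte(best_val, min(art$log$val_loss) + 1e-12)
  expect_lte(best_val, art$log$val_loss[nrow(art$log)])
  # determinism: identical config gives identical predictions
  art2 <- train_one(cfg, d$train, d$val)
  rec <- coh[[which(vapply(coh, function(p) p$patient_id, "") ==
                      sp$test[1])]]
  expect_identical(predict_dose(art, rec, 2), predict_dose(art2, rec, 2))
})

test_that("repeated training selects by accuracy with an rmse tiebreak", {
  tbl <- data.frame(accuracy = c(80, 78), rmse = c(0.5, 0.4))
  expect_equal(select_best(tbl), 1L)
  tie <- data.frame(accuracy = c(80, 80), rmse = c(0.5, 0.4))
  expect_equal(select_best(tie), 2L)
  coh <- generate_cohort(16, seed = 56)
  sp <- make_split(coh, seed = 2, k = 5)
  cfg <- dose_model_config(hidden_size = 3, num_layers = 1, ffn_hidden = 3,
                           max_epochs = 2, seed = 4)
  tr <- train_repeated(cfg, coh, sp, reps = 1)
  expect_equal(tr$best, 1L)
  expect_identical(tr$best_artifact, tr$artifacts[[1]])
  expect_equal(nrow(tr$stats), 1L)
})

test_that("single-point sweep grids return the forced winner", {
  coh <- generate_cohort(14, seed = 57)
  sp <- make_split(coh, seed = 3, k = 5)
  plan <- sweep_plan(hidden_size = 4L, batch_size = 8L, num_layers = 1L,
                     learning_rate = 0.01, reps = 1L, max_epochs = 1L)
  base <- dose_model_config(hidden_size = 4, ffn_hidden = 3, seed = 6)
  sw <- run_sweep(plan, coh, sp, base)
  expect_equal(sw$config$hidden_size, 4L)
  expect_equal(sw$config$batch_size, 8L)
  expect_equal(sw$config$num_layers, 1L)
  expect_equal(sw$config$learning_rate, 0.01)
  expect_equal(nrow(sw$table), 4L) # one row per axis
  expect_true(all(sw$table$winner))
})

test_that("the persistence baseline repeats the previous dose", {
  rec <- tiny_record(doses = c(2.5, 3.0, 3.5), inrs = c(1.5, 2.1, 2.2),
                     days = c(0, 5, 12))
  s <- build_samples(rec)
  expect_equal(persistence_baseline(s), c(2.5, 3.0))
})
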