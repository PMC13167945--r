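#' Mean squared error loss
#'
#' @param y_pred,y equal-length numeric vectors.
#' @return `sum((y_pred - y)^2) / n`.
#' @export
mse_loss <- function(y_pred, y) {
  if (length(y_pred) == 0L) stop("empty vectors", call. = FALSE)
  if (length(y_pred) != length(y)) stop("length mismatch", call. = FALSE)
  mean((y_pred - y)^2)
}

#' Fit statistics on denormalized predictions
#'
#' MSE, MAE, RMSE, coefficient of determination, and tolerance-band
#' accuracy (percent of predictions within `tol` of the reference,
#' relative). `r2` is reported as `NA` when the references have zero
#' variance or fewer than two observations.
#'
#' @param y_pred,y predictions and references in label units (mg/day or
#'   INR).
#' @param tol relative tolerance for the accuracy column (0.20 for dose).
#' @return one-row data.frame with columns `mse`, `mae`, `rmse`, `r2`,
#'   `accuracy`, `n`.
#' @export
fit_stats <- function(y_pred, y, tol = 0.20) {
  if (length(y_pred) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) == 0L) stop("empty vectors", call. = FALSE)
  mse <- mean((y_pred - y)^2)
  mae <- mean(abs(y_pred - y))
  sstot <- sum((y - mean(y))^2)
  r2 <- if (length(y) < 2L || sstot <= 0) NA_real_ else {
    1 - sum((y_pred - y)^2) / sstot
  }
  data.frame(mse = mse, mae = mae, rmse = sqrt(mse), r2 = r2,
             accuracy = 100 * mean(abs(y_pred - y) <= tol * y),
             n = length(y))
}

#' Early-stopping rule
#'
#' Pure form of the training controller: training runs for at most
#' `max_epochs` epochs and stops once the validation loss has failed to
#' improve on the best value so far by at least `min_delta` for `patience`
#' consecutive epochs. Given a hypothetical validation-loss sequence this
#' returns the epoch at which training halts (constant losses halt after
#' `1 + patience` epochs; strictly improving losses run to `max_epochs`).
#'
#' @param val_losses numeric vector of per-epoch validation losses (at least
#'   `max_epochs` long, or shorter to mean "losses continue this pattern" is
#'   not assumed — the vector length caps the run).
#' @param max_epochs,patience,min_delta protocol constants.
#' @return list with `stop_epoch` and `best_epoch`.
#' @export
stopping_epoch <- function(val_losses, max_epochs = 100L, patience = 10L,
                           min_delta = 1e-4) {
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  last <- min(length(val_losses), max_epochs)
  for (epoch in seq_len(last)) {
    v <- val_losses[epoch]
    if (v < best - min_delta) {
      best <- v
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        return(list(stop_epoch = epoch, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = last, best_epoch = best_epoch)
}

# Deterministic length-bucketed minibatches: sort by sequence length, cut
# into batches, collate each once; epochs then shuffle only batch order.
make_batches <- function(samples, stats, batch_size) {
  lens <- vapply(samples, function(s) nrow(s$steps), integer(1))
  ord <- order(lens)
  samples <- samples[ord]
  starts <- seq(1L, length(samples), by = batch_size)
  lapply(starts, function(s) {
    collate(samples[s:min(s + batch_size - 1L, length(samples))], stats)
  })
}

eval_loss <- function(params, batches, config) {
  tot <- 0
  n <- 0
  for (b in batches) {
    out <- nn_forward(params, b, config, training = FALSE)
    tot <- tot + sum((out$pred - b$y)^2)
    n <- n + length(b$y)
  }
  tot / n
}

#' Train one model on a train/validation split
#'
#' Minimizes the MSE of normalized labels with Adam at the configured
#' learning rate, for at most `config$max_epochs` epochs, stopping early
#' when the validation loss fails to improve by `config$min_delta` for
#' `config$patience` consecutive epochs (see [stopping_epoch()]). The
#' parameters from the best validation epoch are restored into the returned
#' artifact; the full per-epoch log is retained. Normalization statistics
#' are computed from the training samples only (or passed via `stats`) and
#' stored in the artifact.
#'
#' @param config a [dose_model_config()].
#' @param train_samples,val_samples lists of `warf_sample`.
#' @param stats optional precomputed [sample_stats()] (training data only).
#' @param split_fingerprint optional fingerprint string recorded in the
#'   artifact.
#' @param verbose print per-epoch losses.
#' @return a `warf_artifact`.
#' @export
train_one <- function(config, train_samples, val_samples, stats = NULL,
                      split_fingerprint = NA_character_, verbose = FALSE) {
  stopifnot(length(train_samples) > 0, length(val_samples) > 0)
  label_type <- train_samples[[1L]]$label_type
  if (is.null(stats)) stats <- sample_stats(train_samples)
  train_batches <- make_batches(train_samples, stats, config$batch_size)
  val_batches <- make_batches(val_samples, stats, config$batch_size)
  params <- nn_init(config)
  opt <- adam_init(params)
  best <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  with_seed(config$seed + 10000L, {
    for (epoch in seq_len(config$max_epochs)) {
      tr_tot <- 0
      tr_n <- 0
      for (bi in sample(seq_along(train_batches))) {
        b <- train_batches[[bi]]
        out <- nn_forward(params, b, config, training = TRUE)
        if (!all(is.finite(out$pred))) {
          stop("training diverged: non-finite predictions at epoch ", epoch,
               call. = FALSE)
        }
        resid <- out$pred - b$y
        tr_tot <- tr_tot + sum(resid^2)
        tr_n <- tr_n + length(resid)
        grads <- nn_backward(params, out$cache, 2 * resid / length(resid),
                             config)
        step <- adam_step(params, grads, opt, config$learning_rate)
        params <- step$params
        opt <- step$state
      }
      vl <- eval_loss(params, val_batches, config)
      if (!is.finite(vl)) {
        stop("training diverged: non-finite validation loss", call. = FALSE)
      }
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_tot / tr_n,
                                   val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        tr_tot / tr_n, vl))
      }
      if (vl < best - config$min_delta) {
        best <- vl
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  log$best <- log$epoch == best_epoch
  new_artifact(config, best_params, stats, label_type, log,
               split_fingerprint)
}

#' Materialize the samples of one fold of a split plan
#'
#' @param cohort a `warf_cohort`.
#' @param split a [make_split()] plan.
#' @param fold fold index.
#' @param label_type `"dose"` or `"inr"`.
#' @return list with `train`, `val` and `test` sample lists.
#' @export
split_samples <- function(cohort, split, fold = 1L,
                          label_type = c("dose", "inr")) {
  label_type <- match.arg(label_type)
  f <- split$folds[[fold]]
  list(train = cohort_samples(subset_cohort(cohort, f$train), label_type),
       val = cohort_samples(subset_cohort(cohort, f$val), label_type),
       test = cohort_samples(subset_cohort(cohort, split$test), label_type))
}

split_fingerprint <- function(split, fold = 1L) {
  fnv1a_hash(paste(c(split$test, "|", split$folds[[fold]]$train),
                   collapse = ","))
}

#' Sequential hyperparameter sweep plan
#'
#' Coordinate-wise search in the order hidden size, batch size, number of
#' recurrent layers, learning rate: each axis is swept with the other axes
#' held at their incumbent values, every candidate is trained `reps` times
#' with distinct seeds, and the candidate with the highest mean tolerance-
#' band dose accuracy on the scoring set wins before the search moves to
#' the next axis.
#'
#' @param hidden_size,batch_size,num_layers,learning_rate candidate grids.
#' @param reps trainings per candidate.
#' @param max_epochs epoch cap used during the sweep.
#' @param score_on `"test"` scores candidates on the held-out test set (the
#'   protocol as described); `"validation"` scores on the fold's validation
#'   set and avoids test leakage into model choice.
#' @return object of class `warf_sweep_plan`.
#' @export
sweep_plan <- function(hidden_size = c(32L, 64L, 128L, 256L),
                       batch_size = c(16L, 32L, 64L),
                       num_layers = c(1L, 2L, 3L),
                       learning_rate = c(0.001, 0.005, 0.01, 0.025, 0.05),
                       reps = 3L, max_epochs = 30L,
                       score_on = c("test", "validation")) {
  grids <- list(hidden_size = hidden_size, batch_size = batch_size,
                num_layers = num_layers, learning_rate = learning_rate)
  if (any(vapply(grids, length, integer(1)) == 0L)) {
    stop("every sweep axis needs at least one candidate", call. = FALSE)
  }
  stopifnot(reps >= 1)
  structure(list(grids = grids, reps = as.integer(reps),
                 max_epochs = as.integer(max_epochs),
                 score_on = match.arg(score_on)),
            class = "warf_sweep_plan")
}

#' Run the sequential hyperparameter sweep
#'
#' @param plan a [sweep_plan()].
#' @param cohort a `warf_cohort`.
#' @param split a [make_split()] plan; fold `fold` provides the
#'   train/validation data and the plan's test set the default scoring set.
#' @param base_config configuration providing all non-swept settings and
#'   the base seed.
#' @param fold fold index used for training.
#' @return list with `config` (winning configuration), and `table` (one row
#'   per candidate x axis with per-rep and mean accuracies).
#' @export
run_sweep <- function(plan, cohort, split, base_config = dose_model_config(),
                      fold = 1L) {
  data <- split_samples(cohort, split, fold, "dose")
  score_samples <- if (plan$score_on == "test") data$test else data$val
  score_ref <- vapply(score_samples, `[[`, numeric(1), "label")
  incumbent <- list(hidden_size = base_config$hidden_size,
                    batch_size = base_config$batch_size,
                    num_layers = base_config$num_layers,
                    learning_rate = base_config$learning_rate)
  rows <- list()
  for (axis in names(plan$grids)) {
    scores <- numeric(length(plan$grids[[axis]]))
    for (ci in seq_along(plan$grids[[axis]])) {
      cand <- incumbent
      cand[[axis]] <- plan$grids[[axis]][ci]
      rep_acc <- numeric(plan$reps)
      for (r in seq_len(plan$reps)) {
        cfg <- dose_model_config(
          hidden_size = cand$hidden_size, batch_size = cand$batch_size,
          num_layers = cand$num_layers, learning_rate = cand$learning_rate,
          bidirectional = base_config$bidirectional,
          ffn_hidden = base_config$ffn_hidden,
          dropout = base_config$dropout, max_epochs = plan$max_epochs,
          patience = base_config$patience,
          min_delta = base_config$min_delta,
          max_dose = base_config$max_dose,
          seed = base_config$seed + 100L * r)
        art <- train_one(cfg, data$train, data$val)
        pred <- predict_samples(art, score_samples)
        rep_acc[r] <- fit_stats(pred, score_ref)$accuracy
      }
      scores[ci] <- mean(rep_acc)
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, value = plan$grids[[axis]][ci],
        mean_accuracy = scores[ci], reps = plan$reps)
    }
    incumbent[[axis]] <- plan$grids[[axis]][which.max(scores)]
  }
  table <- do.call(rbind, rows)
  table$winner <- mapply(function(a, v) incumbent[[a]] == v,
                         table$axis, table$value)
  config <- dose_model_config(
    hidden_size = incumbent$hidden_size, batch_size = incumbent$batch_size,
    num_layers = incumbent$num_layers,
    learning_rate = incumbent$learning_rate,
    bidirectional = base_config$bidirectional,
    ffn_hidden = base_config$ffn_hidden, dropout = base_config$dropout,
    max_epochs = base_config$max_epochs, patience = base_config$patience,
    min_delta = base_config$min_delta, max_dose = base_config$max_dose,
    seed = base_config$seed)
  list(config = config, table = table)
}

#' Rank repeated-training candidates
#'
#' Selection rule for the repeated final trainings: highest tolerance-band
#' dose accuracy on the external/test set wins; ties are broken by lower
#' RMSE.
#'
#' @param stats_table data.frame with columns `accuracy` and `rmse`.
#' @return index of the selected row.
#' @export
select_best <- function(stats_table) {
  stopifnot(all(c("accuracy", "rmse") %in% names(stats_table)))
  order(-stats_table$accuracy, stats_table$rmse)[1L]
}

#' Repeated final trainings with model selection
#'
#' Trains `reps` models that differ only by seed, evaluates each on the
#' test set of `split`, and selects the best by [select_best()].
#'
#' @param config a [dose_model_config()]; rep `r` uses seed
#'   `config$seed + r - 1`.
#' @param cohort a `warf_cohort`.
#' @param split a [make_split()] plan.
#' @param reps number of repeated trainings.
#' @param fold training fold.
#' @param label_type `"dose"` or `"inr"`.
#' @return list with `artifacts`, `stats` (one row per rep), `best`
#'   (selected index) and `best_artifact`.
#' @export
train_repeated <- function(config, cohort, split, reps = 10L, fold = 1L,
                           label_type = "dose") {
  stopifnot(reps >= 1)
  data <- split_samples(cohort, split, fold, label_type)
  ref <- vapply(data$test, `[[`, numeric(1), "label")
  fp <- split_fingerprint(split, fold)
  tol <- if (label_type == "dose") 0.20 else 0.30
  artifacts <- vector("list", reps)
  stats <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    artifacts[[r]] <- train_one(cfg, data$train, data$val,
                                split_fingerprint = fp)
    pred <- predict_samples(artifacts[[r]], data$test)
    st <- fit_stats(pred, ref, tol = tol)
    st$rep <- r
    st$seed <- cfg$seed
    stats[[r]] <- st
  }
  stats <- do.call(rbind, stats)
  best <- select_best(stats)
  list(artifacts = artifacts, stats = stats, best = best,
       best_artifact = artifacts[[best]])
}

#' Persistence baseline predictions
#'
#' The trivial comparator that predicts the previous visit's adjusted dose
#' (or INR) for every decision visit; any learned model must beat it.
#'
#' @param samples list of `warf_sample`.
#' @return numeric vector of predictions in label units.
#' @export
persistence_baseline <- function(samples) {
  vapply(samples, function(s) {
    if (s$label_type == "dose") {
      s$steps[nrow(s$steps), "dose_prev"]
    } else {
      s$steps[nrow(s$steps) - 1L, "inr"]
    }
  }, numeric(1))
}
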