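#' Dose-model architecture and training hyperparameters
#'
#' The network has two branches: a one-hidden-layer ReLU feedforward branch
#' over the fixed covariates and a (bi)directional LSTM branch over the
#' visit-step sequence, whose per-time hidden states are max-pooled over the
#' valid (non-padded) positions. The pooled recurrent representation
#' (`hidden_size` units, doubled when bidirectional) and the feedforward
#' representation are concatenated and mapped by a linear head to a single
#' normalized dose (or INR). Defaults follow the selected configuration of
#' the sequential hyperparameter sweep: hidden size 128, batch size 32, two
#' recurrent layers, learning rate 0.025.
#'
#' @param hidden_size LSTM hidden units per direction.
#' @param num_layers stacked recurrent layers.
#' @param bidirectional process the sequence in both directions.
#' @param batch_size minibatch size for training.
#' @param learning_rate Adam learning rate.
#' @param ffn_hidden hidden width of the fixed-covariate branch.
#' @param dropout dropout rate between recurrent layers (0 disables).
#' @param max_epochs early-stopping epoch cap.
#' @param patience epochs without meaningful validation improvement before
#'   stopping.
#' @param min_delta minimum validation-loss improvement (normalized-loss
#'   units) that counts as progress.
#' @param max_dose clamp for denormalized dose predictions, mg/day.
#' @param seed RNG seed for weight initialization and batch order.
#' @return object of class `warf_config`.
#' @export
dose_model_config <- function(hidden_size = 128L, num_layers = 2L,
                              bidirectional = TRUE, batch_size = 32L,
                              learning_rate = 0.025, ffn_hidden = 64L,
                              dropout = 0, max_epochs = 100L,
                              patience = 10L, min_delta = 1e-4,
                              max_dose = 10, seed = 1L) {
  stopifnot(hidden_size >= 1, num_layers >= 1, batch_size >= 1,
            learning_rate > 0, ffn_hidden >= 1, dropout >= 0, dropout < 1,
            max_epochs >= 1, patience >= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 bidirectional = isTRUE(bidirectional),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 ffn_hidden = as.integer(ffn_hidden), dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 max_dose = max_dose, seed = as.integer(seed)),
            class = "warf_config")
}

#' @export
print.warf_config <- function(x, ...) {
  cat(sprintf(
    "<warf_config> %s, hidden %d x %d layer(s), batch %d, lr %g, seed %d\n",
    if (x$bidirectional) "Bi-LSTM" else "LSTM", x$hidden_size, x$num_layers,
    x$batch_size, x$learning_rate, x$seed))
  invisible(x)
}

new_artifact <- function(config, params, stats, label_type, log,
                         split_fingerprint = NA_character_) {
  structure(list(config = config, params = params, stats = stats,
                 label_type = label_type, log = log,
                 split_fingerprint = split_fingerprint),
            class = "warf_artifact")
}

#' @export
print.warf_artifact <- function(x, ...) {
  cat(sprintf("<warf_artifact> %s model (%s), trained %d epoch(s)\n",
              x$label_type,
              if (x$config$bidirectional) "Bi-LSTM" else "LSTM",
              if (is.null(x$log)) 0L else nrow(x$log)))
  invisible(x)
}

#' Predict the adjusted warfarin dose at a given visit
#'
#' Builds the supervised sample for `at_visit` (history up to and including
#' that visit, with the visit's own dose masked), normalizes it with the
#' artifact's stored training statistics, runs the network in evaluation
#' mode and denormalizes. Dose predictions are clamped to
#' `[0, config$max_dose]`.
#'
#' @param artifact a trained `warf_artifact` (see [train_one()]).
#' @param record a [patient_record()].
#' @param at_visit 1-based visit index, `>= 2`.
#' @return predicted dose in mg/day (or INR for INR artifacts).
#' @export
predict_dose <- function(artifact, record, at_visit) {
  stopifnot(identical(artifact$label_type, "dose"))
  predict_at(artifact, record, at_visit)
}

#' @rdname predict_dose
#' @export
predict_inr <- function(artifact, record, at_visit) {
  stopifnot(identical(artifact$label_type, "inr"))
  predict_at(artifact, record, at_visit)
}

predict_at <- function(artifact, record, at_visit) {
  samples <- build_samples(record, label_type = artifact$label_type)
  idx <- vapply(samples, function(s) s$meta$at_visit, integer(1))
  hit <- match(at_visit, idx)
  if (is.na(hit)) {
    stop("at_visit must index a decision visit (2..",
         nrow(record$visits), ")", call. = FALSE)
  }
  predict_samples(artifact, samples[hit])
}

#' Predict for a list of prepared samples
#'
#' Vectorized inference over `warf_sample` objects; used by the evaluation
#' suite. Returns denormalized predictions in label units.
#'
#' @param artifact a trained `warf_artifact`.
#' @param samples list of `warf_sample` with the artifact's `label_type`.
#' @param batch_size inference batch size.
#' @return numeric vector of predictions.
#' @export
predict_samples <- function(artifact, samples, batch_size = 256L) {
  n <- length(samples)
  preds <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- collate(samples[idx], artifact$stats)
    out <- nn_forward(artifact$params, batch, artifact$config,
                      training = FALSE)
    p <- denormalize(out$pred, artifact$stats, batch$label_feature)
    if (batch$label_feature == "dose") {
      p <- pmin(pmax(p, 0), artifact$config$max_dose)
    } else {
      p <- pmax(p, 0)
    }
    preds[idx] <- p
  }
  preds
}

#' Save or load a trained model artifact
#'
#' The artifact directory holds the configuration (`config.yaml`), the
#' normalization statistics (`stats.csv`), the learned parameters
#' (`params.rds`), the label type and split fingerprint (`meta.yaml`) and
#' the per-epoch training log (`log.csv`). A load after save reproduces
#' predictions bit for bit.
#'
#' @param artifact a `warf_artifact`.
#' @param dir directory path (created if absent).
#' @return `save_artifact()` invisibly returns `dir`; `load_artifact()`
#'   returns the `warf_artifact`.
#' @export
save_artifact <- function(artifact, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(artifact$config), file.path(dir, "config.yaml"))
  st <- as.data.frame(artifact$stats)
  st$mean <- fmt_num(st$mean) # full precision: reloads must be bit-exact
  st$sd <- fmt_num(st$sd)
  utils::write.csv(st, file.path(dir, "stats.csv"), row.names = FALSE)
  saveRDS(artifact$params, file.path(dir, "params.rds"))
  yaml::write_yaml(list(label_type = artifact$label_type,
                        split_fingerprint = artifact$split_fingerprint),
                   file.path(dir, "meta.yaml"))
  if (!is.null(artifact$log)) {
    utils::write.csv(artifact$log, file.path(dir, "log.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(dose_model_config, cfg[names(cfg) %in%
                                             names(formals(dose_model_config))])
  stats <- utils::read.csv(file.path(dir, "stats.csv"),
                           stringsAsFactors = FALSE)
  class(stats) <- c("warf_stats", "data.frame")
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  log <- if (file.exists(file.path(dir, "log.csv"))) {
    utils::read.csv(file.path(dir, "log.csv"))
  }
  new_artifact(config, readRDS(file.path(dir, "params.rds")), stats,
               meta$label_type, log,
               meta$split_fingerprint %||% NA_character_)
}
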