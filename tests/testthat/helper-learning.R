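# The learning-recovery experiment (shared by several acceptance checks):
# simulated modeling cohort n=800 and external cohort n=200 under default
# generator settings, bidirectional and unidirectional models trained over
# three seeds at reduced size (hidden 32, <=30 epochs), plus the
# genotype-ablated external evaluation. Cached so the experiment runs once
# per test session.
learning_results <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    train_cohort <- generate_cohort(800, seed = 101)
    external <- generate_cohort(200, seed = 102, id_prefix = "ext")
    split <- make_split(train_cohort, seed = 103, k = 10)
    d <- split_samples(train_cohort, split, 1L, "dose")
    ext_samples <- cohort_samples(external, "dose")
    ext_ref <- vapply(ext_samples, `[[`, numeric(1), "label")
    ablated <- ablate_genotype(external)
    rows <- list()
    for (seed in c(201L, 202L, 203L)) {
      for (bi in c(TRUE, FALSE)) {
        cfg <- dose_model_config(hidden_size = 32, num_layers = 2,
                                 bidirectional = bi, batch_size = 64,
                                 max_epochs = 30, seed = seed)
        art <- train_one(cfg, d$train, d$val)
        acc <- fit_stats(predict_samples(art, ext_samples), ext_ref)$accuracy
        st <- stable_dose_accuracy(art, external)$summary$pct[["within"]]
        ab <- if (bi) {
          stable_dose_accuracy(art, ablated)$summary$pct[["within"]]
        } else {
          NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, arch = if (bi) "bilstm" else "lstm", accuracy = acc,
          stable = st, stable_ablated = ab, epochs = nrow(art$log))
      }
    }
    cache <<- list(
      runs = do.call(rbind, rows),
      persistence = fit_stats(persistence_baseline(ext_samples),
                              ext_ref)$accuracy,
      n_external = length(ext_samples))
    cache
  }
})
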