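# Fixtures are built in code; cohorts come from the package's own simulator
# under fixed seeds. The small cohort is cached for the whole test run.

fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(6, seed = 42)
    cache
  }
})

# A hand-written three-visit record with known numbers.
tiny_record <- function(doses = c(2.5, 3.0, 3.0),
                        inrs = c(1.5, 2.1, 2.3),
                        days = c(0, 5, 12),
                        indication = "mechanical_valve", ...) {
  patient_record("t1", age = 60, height = 165, weight = 70,
                 genotype = genotype("*1/*3", "GA"),
                 indication = indication,
                 visits = data.frame(day = days, inr = inrs, dose = doses),
                 ...)
}

# Untrained artifact over the fixture cohort; enough for wiring tests that
# need a consistent stats/params pair without paying for training.
tiny_artifact <- function(label_type = "dose", seed = 5, hidden = 4) {
  samples <- cohort_samples(fixture_cohort(), label_type)
  cfg <- dose_model_config(hidden_size = hidden, num_layers = 1,
                           bidirectional = TRUE, ffn_hidden = 4, seed = seed)
  warfdose:::new_artifact(cfg, warfdose:::nn_init(cfg),
                          sample_stats(samples), label_type, NULL)
}

# Brute-force TTR oracle: sample the piecewise-linear INR at `per_segment`
# midpoints per segment and count the in-range fraction.
ttr_oracle <- function(days, inrs, target, max_gap = 56,
                       per_segment = 10000L) {
  lo <- target[[1L]]; hi <- target[[2L]]
  total <- 0; inrange <- 0
  for (k in seq_len(length(days) - 1L)) {
    gap <- days[k + 1L] - days[k]
    if (gap > max_gap) next
    u <- (seq_len(per_segment) - 0.5) / per_segment
    x <- inrs[k] + (inrs[k + 1L] - inrs[k]) * u
    total <- total + gap
    inrange <- inrange + gap * mean(x >= lo & x <= hi)
  }
  if (total <= 0) return(NA_real_)
  100 * inrange / total
}
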