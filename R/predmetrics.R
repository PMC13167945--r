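#' Classify a prediction against its reference
#'
#' A prediction is `within` when `|predicted - reference| <= tol *
#' reference` (boundary inclusive), `over` when it exceeds the band from
#' above, `under` otherwise. The conventional tolerances are 0.20 for dose
#' predictions and 0.30 for INR predictions.
#'
#' @param predicted,reference numeric vectors (reference > 0).
#' @param tol relative tolerance (> 0).
#' @return factor with levels `within`, `over`, `under`.
#' @export
#' @examples
#' classify(c(2.4, 2.7, 1.2), rep(2, 3), tol = 0.20)
classify <- function(predicted, reference, tol = 0.20) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  within <- abs(predicted - reference) <= tol * reference
  klass <- ifelse(within, "within",
                  ifelse(predicted > reference, "over", "under"))
  factor(klass, levels = c("within", "over", "under"))
}

#' Assemble a prediction-outcome table
#'
#' @param predicted,reference numeric vectors in the same unit.
#' @param tol relative tolerance passed to [classify()].
#' @param meta optional list of per-sample metadata (as produced by
#'   [collate()]); contributes `patient_id`, `visit` and `subgroup` columns.
#' @return data.frame of class `warf_outcomes` with columns `predicted`,
#'   `reference`, `klass` and any metadata columns.
#' @export
prediction_outcomes <- function(predicted, reference, tol = 0.20,
                                meta = NULL) {
  out <- data.frame(predicted = predicted, reference = reference,
                    klass = classify(predicted, reference, tol))
  if (!is.null(meta)) {
    out$patient_id <- vapply(meta, function(m) m$patient_id, character(1))
    out$visit <- vapply(meta, function(m) m$visit, integer(1))
    out$subgroup <- vapply(meta, function(m) m$subgroup, character(1))
  }
  structure(out, class = c("warf_outcomes", "data.frame"))
}

#' Accuracy summary over prediction outcomes
#'
#' Proportions of within/over/under classifications, reported to one
#' decimal with half-up rounding (the convention of clinical reporting).
#'
#' @param outcomes a [prediction_outcomes()] table, or anything with a
#'   `klass` column/factor.
#' @return list with `counts` (named integer), `pct` (named numeric,
#'   one-decimal percentages) and `n`.
#' @export
#' @examples
#' # counts alone suffice to reproduce printed accuracy rows
#' k <- factor(rep(c("within", "over", "under"), c(1160, 485, 96)),
#'             levels = c("within", "over", "under"))
#' accuracy_summary(data.frame(klass = k))$pct
accuracy_summary <- function(outcomes) {
  klass <- if (is.data.frame(outcomes)) outcomes$klass else outcomes
  if (length(klass) == 0L) stop("no outcomes to summarize", call. = FALSE)
  klass <- factor(klass, levels = c("within", "over", "under"))
  counts <- table(klass)
  n <- sum(counts)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       pct = stats::setNames(round_half_up(100 * as.numeric(counts) / n, 1),
                             names(counts)),
       n = as.integer(n))
}

#' Detect a patient's stable dose
#'
#' Scans maximal runs of consecutive visits at an identical dose and returns
#' the earliest window spanning at least `min_days` days in which every INR
#' lies inside the patient's target range. Under the default reading
#' (`window_rule = "starts_at_or_after_day7"`) the window must begin no
#' earlier than day 7 after initiation, excluding the induction transient;
#' leading in-run visits before day 7 are trimmed. The alternative reading
#' (`"starts_within_7d"`) requires the window to begin within the first 7
#' days.
#'
#' @param record a [patient_record()].
#' @param min_days minimum window span in days (default 14).
#' @param window_rule see above.
#' @return list with `dose`, `window` (`c(start, end)` days) and
#'   `visit_idx` (indices of the in-window visits), or `NULL` when no
#'   qualifying window exists.
#' @export
detect_stable_dose <- function(record, min_days = 14,
                               window_rule = c("starts_at_or_after_day7",
                                               "starts_within_7d")) {
  window_rule <- match.arg(window_rule)
  v <- record$visits
  lo <- record$target[["low"]]
  hi <- record$target[["high"]]
  runs <- rle(v$dose)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  in_range <- v$inr >= lo & v$inr <= hi
  for (r in seq_along(runs$values)) {
    idx <- starts[r]:ends[r]
    if (window_rule == "starts_at_or_after_day7") {
      idx <- idx[v$day[idx] >= 7]
    }
    if (length(idx) < 2L) next
    # earliest qualifying start inside the run, extended to the longest
    # stretch of consecutive in-range visits
    for (i in idx) {
      if (window_rule == "starts_within_7d" && v$day[i] > 7) break
      if (!in_range[i]) next
      j <- i
      while (j < idx[length(idx)] && in_range[j + 1L]) j <- j + 1L
      if (v$day[j] - v$day[i] >= min_days) {
        return(list(dose = runs$values[r],
                    window = c(start = v$day[i], end = v$day[j]),
                    visit_idx = i:j))
      }
    }
  }
  NULL
}

#' Stable-dose prediction accuracy over a cohort
#'
#' For every patient with a detected stable dose, the dose model predicts at
#' each decision visit inside the stable window (conditioning on the history
#' up to that visit) and the prediction is classified against the stable
#' dose with the +/-20% band; results are pooled by [accuracy_summary()].
#'
#' @param artifact a trained dose `warf_artifact`.
#' @param cohort a `warf_cohort`.
#' @param tol relative tolerance.
#' @param ... passed to [detect_stable_dose()].
#' @return list with `summary` (see [accuracy_summary()]), `outcomes`, and
#'   `stable` (per-patient stable-dose table); `NULL` summary components
#'   when no patient has a stable dose.
#' @export
stable_dose_accuracy <- function(artifact, cohort, tol = 0.20, ...) {
  outs <- list()
  stable_rows <- list()
  for (p in cohort) {
    sd <- detect_stable_dose(p, ...)
    if (is.null(sd)) next
    stable_rows[[length(stable_rows) + 1L]] <- data.frame(
      patient_id = p$patient_id, dose = sd$dose,
      start = sd$window[["start"]], end = sd$window[["end"]])
    idx <- sd$visit_idx[sd$visit_idx >= 2L] # visit 1 has no history
    if (!length(idx)) next
    samples <- build_samples(p, label_type = "dose")
    at <- vapply(samples, function(s) s$meta$at_visit, integer(1))
    samples <- samples[match(idx, at)]
    pred <- predict_samples(artifact, samples)
    outs[[length(outs) + 1L]] <- prediction_outcomes(
      pred, rep(sd$dose, length(pred)), tol = tol,
      meta = lapply(samples, `[[`, "meta"))
  }
  if (!length(outs)) {
    return(list(summary = NULL, outcomes = NULL, stable = NULL,
                n_stable_patients = 0L))
  }
  outcomes <- do.call(rbind, outs)
  list(summary = accuracy_summary(outcomes), outcomes = outcomes,
       stable = do.call(rbind, stable_rows),
       n_stable_patients = length(stable_rows))
}

#' Accuracy by decision-visit index
#'
#' Within-band percentage per decision visit (1 = first dose-adjustment
#' decision); indices beyond `max_index` are pooled into a tail bin. Bins
#' with no outcomes are omitted.
#'
#' @param outcomes a [prediction_outcomes()] table carrying a `visit`
#'   column.
#' @param max_index largest unpooled visit index.
#' @return data.frame with columns `visit`, `accuracy`, `n`.
#' @export
per_visit_accuracy <- function(outcomes, max_index = 10L) {
  stopifnot("visit" %in% names(outcomes))
  bin <- ifelse(outcomes$visit > max_index, paste0(">", max_index),
                as.character(outcomes$visit))
  lev <- c(as.character(seq_len(max_index)), paste0(">", max_index))
  bin <- factor(bin, levels = lev)
  tab <- table(bin, outcomes$klass == "within")
  present <- rowSums(tab) > 0
  data.frame(
    visit = rownames(tab)[present],
    accuracy = round_half_up(
      100 * tab[present, "TRUE"] / rowSums(tab[present, , drop = FALSE]), 1),
    n = as.integer(rowSums(tab[present, , drop = FALSE])),
    row.names = NULL)
}

#' Genotype sensitivity subgroup
#'
#' CPIC-style decision table over the CYP2C9/VKORC1 genotype:
#' `highly_sensitive` for VKORC1 AA carrying at least one reduced-function
#' CYP2C9 allele; `sensitive` for VKORC1 AA with *1/*1 or VKORC1 GG/GA with
#' a reduced-function allele; `normal` for VKORC1 GG/GA with *1/*1;
#' `unclassified` when the genotype is unknown. The table is replaceable via
#' `table`.
#'
#' @param genotype a [genotype()] object.
#' @param table optional function `(vkorc1_a, cyp_variant_alleles) ->
#'   character` overriding the default mapping.
#' @return one of `"normal"`, `"sensitive"`, `"highly_sensitive"`,
#'   `"unclassified"`.
#' @export
sensitivity_subgroup <- function(genotype, table = NULL) {
  if (!isTRUE(genotype$known)) return("unclassified")
  gf <- genotype_features(genotype)
  if (!is.null(table)) {
    return(table(gf[["vkorc1_a"]], gf[["cyp_variant_alleles"]]))
  }
  aa <- gf[["vkorc1_a"]] == 2
  var <- gf[["cyp_variant_alleles"]] >= 1
  if (aa && var) "highly_sensitive"
  else if (aa || var) "sensitive"
  else "normal"
}

#' Remove genotype information from a cohort
#'
#' Returns a copy of the cohort with `genotype$known = FALSE` everywhere, so
#' downstream feature encoding falls back to the neutral (training-mean)
#' imputation. Everything else is untouched; the operation is idempotent.
#'
#' @param cohort a `warf_cohort`.
#' @return a `warf_cohort`.
#' @export
ablate_genotype <- function(cohort) {
  as_cohort(lapply(cohort, function(p) {
    p$fixed$genotype$known <- FALSE
    p
  }))
}

#' Prediction-error distribution summary
#'
#' Moments, quantiles and a binned histogram of the signed errors
#' `predicted - reference` (over-prediction is positive by this
#' convention).
#'
#' @param outcomes a [prediction_outcomes()] table (>= 2 rows).
#' @param bins number of histogram bins.
#' @return list with `mean`, `sd`, `skewness` (moment coefficient),
#'   `quantiles`, `histogram` (data.frame `mid`, `count`, `density`) and
#'   `sign_convention`.
#' @export
error_summary <- function(outcomes, bins = 30L) {
  e <- outcomes$predicted - outcomes$reference
  if (length(e) < 2L) stop("need at least two outcomes", call. = FALSE)
  s <- stats::sd(e)
  m2 <- mean((e - mean(e))^2)
  skew <- if (m2 > 0) mean((e - mean(e))^3) / m2^1.5 else 0
  h <- graphics::hist(e, breaks = bins, plot = FALSE)
  list(mean = mean(e), sd = s, skewness = skew,
       quantiles = stats::quantile(e, c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)),
       histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density),
       sign_convention = "error = predicted - reference (over-prediction positive)")
}
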