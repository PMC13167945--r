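#' Build supervised samples from a patient record
#'
#' Converts one longitudinal record into one supervised sample per decision
#' visit. For a record with visits \eqn{1..V}, visit \eqn{i \in 2..V} yields
#' a sample whose steps are visits \eqn{1..i}; each step carries the
#' previous visit's adjusted dose (`dose_prev`; the first step duplicates
#' the initiation dose rather than using 0, which would falsely signal "no
#' prior anticoagulation"), the current INR, the planned interval to the
#' next visit (`interval_next`, treated as known at decision time because it
#' is planner-chosen; for the final visit the last observed interval is
#' carried forward), and the current adjusted dose. At the decision step the
#' supervised quantity is masked: the dose for dose-prediction samples
#' (`label_type = "dose"`, label = dose at visit \eqn{i}) or the INR for
#' INR-prediction samples (`label_type = "inr"`, label = INR at visit
#' \eqn{i}). Masked positions are replaced by a sentinel after
#' normalization (see [collate()]), so a masked dose is always
#' distinguishable from a true zero.
#'
#' @param record a [patient_record()].
#' @param label_type `"dose"` or `"inr"`.
#' @return list of `warf_sample` objects; empty when the record has fewer
#'   than two visits. Samples with non-positive labels are dropped with a
#'   warning.
#' @export
build_samples <- function(record, label_type = c("dose", "inr")) {
  label_type <- match.arg(label_type)
  v <- record$visits
  V <- nrow(v)
  if (V < 2L) return(list())
  interval <- diff(v$day)               # interval[j] = day[j+1] - day[j]
  interval_next <- c(interval, interval[length(interval)])
  dose_prev <- c(v$dose[1], v$dose[-V])
  fixed <- encode_fixed(record)
  g <- record$fixed$genotype
  subgroup <- sensitivity_subgroup(g)
  out <- vector("list", V - 1L)
  keep <- logical(V - 1L)
  for (i in 2:V) {
    steps <- cbind(dose_prev = dose_prev[1:i], inr = v$inr[1:i],
                   interval_next = interval_next[1:i], dose = v$dose[1:i])
    label <- if (label_type == "dose") v$dose[i] else v$inr[i]
    if (!is.finite(label) || label <= 0) {
      warning("dropping sample with non-positive label (patient ",
              record$patient_id, ", visit ", i, ")", call. = FALSE)
      next
    }
    out[[i - 1L]] <- structure(
      list(fixed = fixed, steps = steps,
           masked_feature = if (label_type == "dose") "dose" else "inr",
           label = label, label_type = label_type,
           meta = list(patient_id = record$patient_id, at_visit = i,
                       visit = i - 1L, # 1 = first dose-adjustment decision
                       target = record$target, subgroup = subgroup)),
      class = "warf_sample")
    keep[i - 1L] <- TRUE
  }
  out[keep]
}

#' @rdname build_samples
#' @param cohort a `warf_cohort`.
#' @export
cohort_samples <- function(cohort, label_type = c("dose", "inr")) {
  label_type <- match.arg(label_type)
  unlist(lapply(cohort, build_samples, label_type = label_type),
         recursive = FALSE)
}

#' Patient-level train/validation/test split plan
#'
#' Allocates a fraction of patients to a held-out test set, then partitions
#' the remainder into `k` cross-validation folds, each serving once as the
#' validation set (about 9% of all patients when `test_frac = 0.1` and
#' `k = 10`) with the rest (about 81%) for training. Splitting is at the
#' patient level because visits within a patient are correlated.
#'
#' @param cohort a `warf_cohort`.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param test_frac fraction of patients held out for testing.
#' @param k number of cross-validation folds over the non-test patients.
#' @return object of class `warf_split`: list with `test` (patient ids),
#'   `folds` (list of `list(train, val)` id vectors) and `seed`.
#' @export
make_split <- function(cohort, seed, test_frac = 0.10, k = 10L) {
  ids <- vapply(cohort, function(p) p$patient_id, character(1))
  n <- length(ids)
  if (n < k + 2L) stop("too few patients for ", k, " folds", call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(ids)
    n_test <- max(1L, round(test_frac * n))
    test <- sort(shuffled[seq_len(n_test)])
    rest <- shuffled[-seq_len(n_test)]
    fold_id <- rep_len(seq_len(k), length(rest))
    folds <- lapply(seq_len(k), function(f) {
      list(train = sort(rest[fold_id != f]), val = sort(rest[fold_id == f]))
    })
    structure(list(test = test, folds = folds, seed = seed, k = k),
              class = "warf_split")
  })
}

subset_cohort <- function(cohort, ids) {
  keep <- vapply(cohort, function(p) p$patient_id %in% ids, logical(1))
  as_cohort(cohort[keep])
}

#' Normalization statistics from a set of training samples
#'
#' Computes feature-wise means and standard deviations over the fixed
#' covariates and the stacked visit steps of `samples`. Call this on
#' training-fold samples only — the statistics are stored inside the trained
#' artifact so evaluation data never contribute to them. Step statistics use
#' the true, pre-masking values; labels share the masked feature's stats.
#'
#' @param samples list of `warf_sample` objects (see [build_samples()]).
#' @return a [norm_stats()] table covering all fixed and step features.
#' @export
sample_stats <- function(samples) {
  stopifnot(length(samples) > 0)
  fixed <- do.call(rbind, lapply(samples, `[[`, "fixed"))
  steps <- do.call(rbind, lapply(samples, `[[`, "steps"))
  merge_stats(norm_stats(fixed), norm_stats(steps))
}

merge_stats <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  structure(out, class = c("warf_stats", "data.frame"))
}

#' Collate samples into a padded, normalized batch
#'
#' Right-pads step sequences to the batch maximum length, z-scores every
#' feature with training statistics, replaces the masked (supervised)
#' position's value with `sentinel` — a value far outside the range
#' achievable by normalized data, so it never collides with a genuine
#' normalized dose — and normalizes labels with the masked feature's
#' statistics. Unknown-genotype features normalize to 0 (training mean).
#'
#' @param samples list of `warf_sample` (all with the same `label_type`).
#' @param stats a [norm_stats()] object covering fixed and step features.
#' @param max_len truncate histories to the most recent `max_len` steps
#'   (with a warning).
#' @param sentinel normalized-scale sentinel for the masked position.
#' @return list with `fixed` (n x 8 matrix), `x` (list over time of n x 4
#'   step matrices), `mask` (n x T logical; TRUE = real step), `lens`,
#'   `y` (normalized labels), `y_raw`, and `meta` (list of sample metas).
#' @export
collate <- function(samples, stats, max_len = Inf, sentinel = -8) {
  stopifnot(length(samples) > 0)
  label_type <- unique(vapply(samples, `[[`, character(1), "label_type"))
  stopifnot(length(label_type) == 1L)
  lens <- vapply(samples, function(s) nrow(s$steps), integer(1))
  if (any(lens > max_len)) {
    warning(sum(lens > max_len), " sequence(s) truncated to the most recent ",
            max_len, " steps", call. = FALSE)
    samples <- lapply(samples, function(s) {
      n <- nrow(s$steps)
      if (n > max_len) s$steps <- s$steps[(n - max_len + 1L):n, , drop = FALSE]
      s
    })
    lens <- pmin(lens, as.integer(max_len))
  }
  n <- length(samples)
  T_max <- max(lens)
  feats <- step_feature_names()
  fixed <- do.call(rbind, lapply(samples, `[[`, "fixed"))
  for (f in colnames(fixed)) fixed[, f] <- normalize(fixed[, f], stats, f)
  masked <- samples[[1L]]$masked_feature
  x <- lapply(seq_len(T_max), function(t) {
    m <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
    for (b in seq_len(n)) {
      if (t <= lens[b]) m[b, ] <- samples[[b]]$steps[t, feats]
    }
    m
  })
  for (t in seq_len(T_max)) {
    for (f in feats) x[[t]][, f] <- normalize(x[[t]][, f], stats, f)
  }
  # sentinel at each sample's decision step (its last real step)
  for (b in seq_len(n)) x[[lens[b]]][b, masked] <- sentinel
  mask <- outer(lens, seq_len(T_max), `>=`)
  y_raw <- vapply(samples, `[[`, numeric(1), "label")
  list(fixed = fixed, x = x, mask = mask, lens = lens,
       y = normalize(y_raw, stats, masked), y_raw = y_raw,
       label_feature = masked,
       meta = lapply(samples, `[[`, "meta"))
}
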