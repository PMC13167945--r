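#' Read and write longitudinal cohort files
#'
#' Cohorts are exchanged as UTF-8 CSV with one row per visit and the fixed
#' covariates repeated on every row. Required columns: `patient_id`, `age`,
#' `height_cm`, `weight_kg`, `cyp2c9`, `vkorc1`, `genotype_known`,
#' `amiodarone`, `digoxin`, `indication`, `day`, `inr`, `dose_mg`; optional
#' per-patient `target_low`/`target_high` override the indication's INR
#' range. Booleans are written as 0/1. `write_cohort()` followed by
#' `read_cohort()` is the identity on valid cohorts; visits that are out of
#' order are re-sorted by day with a warning, and duplicated
#' `(patient_id, day)` pairs are rejected.
#'
#' @param path file path.
#' @param cohort a `warf_cohort` (list of [patient_record()]s).
#' @return `read_cohort()` returns a `warf_cohort`; `write_cohort()`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "age", "height_cm", "weight_kg", "cyp2c9", "vkorc1",
           "genotype_known", "amiodarone", "digoxin", "indication", "day",
           "inr", "dose_mg")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("inr", "dose_mg", "day", "age", "height_cm", "weight_kg")) {
    if (!is.numeric(df[[col]])) {
      stop("non-numeric values in column ", col, call. = FALSE)
    }
  }
  dup <- duplicated(df[c("patient_id", "day")])
  if (any(dup)) {
    stop("duplicate (patient_id, day): patient ", df$patient_id[dup][1],
         ", day ", df$day[dup][1], call. = FALSE)
  }
  has_target <- all(c("target_low", "target_high") %in% names(df))
  ids <- unique(df$patient_id) # preserve file order
  records <- lapply(ids, function(id) {
    rows <- df[df$patient_id == id, , drop = FALSE]
    r1 <- rows[1L, ]
    target <- NULL
    if (has_target && is.finite(r1$target_low) && is.finite(r1$target_high)) {
      target <- c(r1$target_low, r1$target_high)
    }
    patient_record(
      patient_id = id, age = r1$age, height = r1$height_cm,
      weight = r1$weight_kg,
      genotype = genotype(cyp2c9 = r1$cyp2c9, vkorc1 = r1$vkorc1,
                          known = as.logical(r1$genotype_known)),
      amiodarone = as.logical(r1$amiodarone),
      digoxin = as.logical(r1$digoxin),
      indication = r1$indication,
      visits = data.frame(day = rows$day, inr = rows$inr,
                          dose = rows$dose_mg),
      target = target)
  })
  as_cohort(records)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    g <- p$fixed$genotype
    n <- nrow(p$visits)
    # target written only when it differs from the indication default
    default <- assign_target_range(p$indication)
    overridden <- !isTRUE(all.equal(unname(default), unname(p$target)))
    data.frame(
      patient_id = rep(p$patient_id, n),
      age = fmt_num(p$fixed$age), height_cm = fmt_num(p$fixed$height),
      weight_kg = fmt_num(p$fixed$weight),
      cyp2c9 = g$cyp2c9, vkorc1 = g$vkorc1,
      genotype_known = as.integer(g$known),
      amiodarone = as.integer(p$fixed$amiodarone),
      digoxin = as.integer(p$fixed$digoxin),
      indication = p$indication,
      day = fmt_num(p$visits$day),
      inr = fmt_num(p$visits$inr),
      dose_mg = fmt_num(p$visits$dose),
      target_low = if (overridden) fmt_num(p$target[["low"]]) else "",
      target_high = if (overridden) fmt_num(p$target[["high"]]) else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
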