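#' Indication-specific therapeutic INR target ranges
#'
#' Returns the therapeutic INR interval used for time-in-range, stable-dose
#' detection and prediction labels. The defaults follow valve-surgery
#' anticoagulation practice: 2.0--2.5 after mechanical valve replacement,
#' 1.8--2.3 after bioprosthetic valve replacement and 1.5--2.5 after valve
#' repair. For `"other"` indications (where the range is set by indication
#' and comorbidity) the package default is 2.0--3.0; supply `override` to
#' set a per-patient range.
#'
#' @param indication one of `"mechanical_valve"`, `"bioprosthetic_valve"`,
#'   `"valve_repair"`, `"other"`.
#' @param override optional length-2 numeric `c(low, high)` that wins over
#'   the indication default.
#' @return named numeric vector `c(low, high)` with `0 < low < high`.
#' @export
#' @examples
#' assign_target_range("mechanical_valve")
#' assign_target_range("other", override = c(2.5, 3.5))
assign_target_range <- function(indication, override = NULL) {
  if (!is.null(override)) {
    override <- as.numeric(override)
    if (length(override) != 2L || any(!is.finite(override)) ||
        override[1] <= 0 || override[1] >= override[2]) {
      stop("`override` must be c(low, high) with 0 < low < high", call. = FALSE)
    }
    return(c(low = override[1], high = override[2]))
  }
  ranges <- list(
    mechanical_valve    = c(low = 2.0, high = 2.5),
    bioprosthetic_valve = c(low = 1.8, high = 2.3),
    valve_repair        = c(low = 1.5, high = 2.5),
    other               = c(low = 2.0, high = 3.0)
  )
  if (!is.character(indication) || length(indication) != 1L ||
      !indication %in% names(ranges)) {
    stop("unrecognized indication label: ",
         paste(utils::head(as.character(indication), 1), collapse = ""),
         call. = FALSE)
  }
  ranges[[indication]]
}

#' @rdname assign_target_range
#' @export
indication_levels <- function() {
  c("mechanical_valve", "bioprosthetic_valve", "valve_repair", "other")
}

# ---- Genotype -------------------------------------------------------------

cyp2c9_diplotypes <- function() {
  c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3")
}

#' Genotype descriptor
#'
#' @param cyp2c9 CYP2C9 diplotype over the *1/*2/*3 star alleles, e.g.
#'   `"*1/*3"`. Allele order is not significant (`"*3/*1"` is normalized).
#' @param vkorc1 VKORC1 -1639G>A genotype: `"GG"`, `"GA"` or `"AA"`.
#' @param known `FALSE` when genotyping was not performed; consumers then
#'   ignore the diplotype fields and fall back to neutral imputation.
#' @return an object of class `warf_genotype`.
#' @export
genotype <- function(cyp2c9 = "*1/*1", vkorc1 = "GG", known = TRUE) {
  stopifnot(is.logical(known), length(known) == 1L)
  # normalize allele order
  alleles <- sort(strsplit(as.character(cyp2c9), "/", fixed = TRUE)[[1]])
  cyp <- paste(alleles, collapse = "/")
  if (!cyp %in% cyp2c9_diplotypes()) {
    stop("invalid CYP2C9 diplotype: ", cyp2c9, call. = FALSE)
  }
  if (!vkorc1 %in% c("GG", "GA", "AA")) {
    stop("invalid VKORC1 genotype: ", vkorc1, call. = FALSE)
  }
  structure(list(cyp2c9 = cyp, vkorc1 = vkorc1, known = known),
            class = "warf_genotype")
}

# Gene-dose feature encoding: CYP2C9 reduced-function allele count (*2 or
# *3), an indicator for *3 carriage, and the VKORC1 -1639A allele count.
# Ordinal coding is the convention in published warfarin dosing algorithms.
genotype_features <- function(g) {
  if (!isTRUE(g$known)) {
    return(c(cyp_variant_alleles = NA_real_, cyp_star3 = NA_real_,
             vkorc1_a = NA_real_))
  }
  alleles <- strsplit(g$cyp2c9, "/", fixed = TRUE)[[1]]
  c(cyp_variant_alleles = sum(alleles %in% c("*2", "*3")),
    cyp_star3 = as.numeric(any(alleles == "*3")),
    vkorc1_a = c(GG = 0, GA = 1, AA = 2)[[g$vkorc1]])
}

# ---- Patient records ------------------------------------------------------

#' Construct a single-patient longitudinal record
#'
#' The universal exchange object: fixed covariates plus an ordered visit
#' series (day since warfarin initiation, measured INR, adjusted daily dose).
#'
#' @param patient_id opaque identifier string.
#' @param age,height,weight age in years, height in cm, weight in kg.
#' @param genotype a [genotype()] object.
#' @param amiodarone,digoxin logical comedication flags.
#' @param indication one of [indication_levels()].
#' @param visits data.frame with numeric columns `day`, `inr`, `dose`
#'   (mg/day); days must be strictly increasing within the patient.
#' @param target optional `c(low, high)` override of the indication's
#'   therapeutic INR range.
#' @return an object of class `warf_patient`.
#' @export
patient_record <- function(patient_id, age, height, weight,
                           genotype = warfdose::genotype(),
                           amiodarone = FALSE, digoxin = FALSE,
                           indication = "other", visits, target = NULL) {
  stopifnot(inherits(genotype, "warf_genotype"))
  if (!is.numeric(age) || age <= 0) stop("age must be > 0", call. = FALSE)
  if (!is.numeric(height) || height <= 100 || height >= 220) {
    stop("height must lie in (100, 220) cm", call. = FALSE)
  }
  if (!is.numeric(weight) || weight <= 25 || weight >= 200) {
    stop("weight must lie in (25, 200) kg", call. = FALSE)
  }
  visits <- as.data.frame(visits)
  req <- c("day", "inr", "dose")
  if (!all(req %in% names(visits))) {
    stop("visits needs columns day, inr, dose", call. = FALSE)
  }
  visits <- visits[req]
  if (nrow(visits) < 1L) stop("at least one visit is required", call. = FALSE)
  if (any(!is.finite(visits$inr)) || any(visits$inr <= 0)) {
    stop("INR values must be finite and positive", call. = FALSE)
  }
  if (any(visits$dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (is.unsorted(visits$day, strictly = TRUE)) {
    if (anyDuplicated(visits$day)) {
      stop("duplicate visit day for patient ", patient_id, ": day ",
           visits$day[duplicated(visits$day)][1], call. = FALSE)
    }
    warning("visits for patient ", patient_id,
            " were out of order; re-sorted by day", call. = FALSE)
    visits <- visits[order(visits$day), , drop = FALSE]
    rownames(visits) <- NULL
  }
  tr <- assign_target_range(indication, override = target)
  structure(
    list(patient_id = as.character(patient_id),
         fixed = list(age = as.numeric(age), height = as.numeric(height),
                      weight = as.numeric(weight), genotype = genotype,
                      amiodarone = isTRUE(amiodarone),
                      digoxin = isTRUE(digoxin)),
         indication = indication,
         target = tr,
         visits = visits),
    class = "warf_patient")
}

#' @export
print.warf_patient <- function(x, ...) {
  g <- x$fixed$genotype
  cat(sprintf("<warf_patient %s> %s, target INR [%.1f, %.1f]\n",
              x$patient_id, x$indication, x$target[["low"]],
              x$target[["high"]]))
  cat(sprintf("  age %.0f y, %.0f cm, %.0f kg; CYP2C9 %s, VKORC1 %s%s\n",
              x$fixed$age, x$fixed$height, x$fixed$weight,
              if (g$known) g$cyp2c9 else "?",
              if (g$known) g$vkorc1 else "?",
              if (g$known) "" else " (genotype unknown)"))
  cat(sprintf("  %d visits over days %g..%g\n", nrow(x$visits),
              min(x$visits$day), max(x$visits$day)))
  invisible(x)
}

#' @export
print.warf_cohort <- function(x, ...) {
  nv <- vapply(x, function(p) nrow(p$visits), integer(1))
  cat(sprintf("<warf_cohort> %d patients, %d visits (median %g per patient)\n",
              length(x), sum(nv), stats::median(nv)))
  invisible(x)
}

as_cohort <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "warf_patient")))
  structure(records, class = "warf_cohort")
}

# Fixed-covariate feature vector used by the model's feedforward branch.
# Genotype features are NA when genotype is unknown; normalization maps NA
# to 0 (the training mean), the neutral imputation.
encode_fixed <- function(patient) {
  f <- patient$fixed
  c(age = f$age, height = f$height, weight = f$weight,
    genotype_features(f$genotype),
    amiodarone = as.numeric(f$amiodarone), digoxin = as.numeric(f$digoxin))
}

fixed_feature_names <- function() {
  c("age", "height", "weight", "cyp_variant_alleles", "cyp_star3",
    "vkorc1_a", "amiodarone", "digoxin")
}

step_feature_names <- function() {
  c("dose_prev", "inr", "interval_next", "dose")
}

# ---- Normalization --------------------------------------------------------

#' Feature normalization statistics
#'
#' Per-feature mean and standard deviation computed from training data only,
#' used for z-scoring `(x - mean) / sd`. Constant features are assigned
#' `sd = 1` and flagged so normalization is always well defined.
#'
#' @param x numeric matrix (rows = observations) or data.frame with named
#'   columns. `NA`s are ignored in the moments.
#' @return object of class `warf_stats`: data.frame with columns `feature`,
#'   `mean`, `sd`, `constant`.
#' @export
norm_stats <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("features must be named", call. = FALSE)
  mu <- apply(x, 2, mean, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  constant <- !is.finite(sd) | sd <= 0
  sd[constant] <- 1
  mu[!is.finite(mu)] <- 0
  structure(
    data.frame(feature = colnames(x), mean = unname(mu), sd = unname(sd),
               constant = unname(constant), stringsAsFactors = FALSE),
    class = c("warf_stats", "data.frame"))
}

stats_lookup <- function(stats, feature) {
  i <- match(feature, stats$feature)
  if (anyNA(i)) {
    stop("unknown feature in normalization stats: ",
         paste(feature[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Normalize or denormalize feature values
#'
#' `normalize()` applies the z-transform `(x - mean) / sd` with the stored
#' training-set statistics; `denormalize()` is its exact inverse. `NA`
#' inputs (unknown genotype) normalize to 0, the training mean.
#'
#' @param x numeric vector of raw (or normalized) values.
#' @param stats a [norm_stats()] object.
#' @param feature feature name (recycled against `x`).
#' @return numeric vector.
#' @export
normalize <- function(x, stats, feature) {
  i <- stats_lookup(stats, feature)
  if (any(!is.finite(x) & !is.na(x))) {
    stop("non-finite value passed to normalize()", call. = FALSE)
  }
  out <- (x - stats$mean[i]) / stats$sd[i]
  out[is.na(out)] <- 0
  out
}

#' @rdname normalize
#' @export
denormalize <- function(x, stats, feature) {
  i <- stats_lookup(stats, feature)
  x * stats$sd[i] + stats$mean[i]
}
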