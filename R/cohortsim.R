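#' Simulation parameters for the virtual anticoagulation cohort
#'
#' The generative model is a delayed Emax (Hill) dose--response with
#' first-order onset: a patient's steady-state INR at daily dose \eqn{d} is
#' \deqn{INR_{ss}(d) = INR_0 + E_{max} \frac{d^h}{ED_{50}^h + d^h},}
#' and the latent INR relaxes toward it with rate `ke` (per day), so the
#' effect of a dose change is delayed and the early titration phase
#' (days 3--5) is unstable. Genotype scales sensitivity multiplicatively:
#' each VKORC1 -1639A allele multiplies the patient's ED50 by
#' `sens_vkorc1_per_A` and each reduced-function CYP2C9 allele (*2/*3) by
#' `sens_cyp2c9_per_allele`, with lognormal interindividual variability on
#' top. Measured INR carries multiplicative lognormal noise. This simulator
#' is a synthetic stand-in calibrated so that cohort-level anchors match a
#' valve-surgery population (baseline INR about 1.5, mean stable dose near
#' 2.6 mg/day, Han Chinese-like allele frequencies); it is not a mechanistic
#' warfarin PK/PD model.
#'
#' @param baseline_inr INR before warfarin exposure (default 1.5).
#' @param emax maximal INR elevation above baseline.
#' @param ed50_base dose (mg/day) giving half-maximal effect in a wild-type
#'   (GG, *1/*1) patient.
#' @param hill Hill shape exponent.
#' @param sens_vkorc1_per_A,sens_cyp2c9_per_allele multiplicative ED50
#'   reduction per variant allele, in (0, 1].
#' @param amiodarone_ed50_factor static ED50 multiplier under amiodarone.
#' @param iiv_sd SD of lognormal interindividual ED50 variability.
#' @param ke first-order rate of approach to steady state, per day.
#' @param noise_sd SD of multiplicative (lognormal) INR measurement noise.
#' @param freq_vkorc1_A,freq_cyp2c9_star2,freq_cyp2c9_star3 population
#'   allele frequencies (Hardy--Weinberg sampling).
#' @param age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd
#'   truncated-normal anthropometric distributions.
#' @param p_amiodarone,p_digoxin comedication prevalences.
#' @param p_indication named probabilities over [indication_levels()].
#' @param initial_dose starting dose, mg/day.
#' @return object of class `warf_sim_params`.
#' @export
sim_params <- function(baseline_inr = 1.5, emax = 2.6, ed50_base = 9.5,
                       hill = 1.6, sens_vkorc1_per_A = 0.72,
                       sens_cyp2c9_per_allele = 0.62,
                       amiodarone_ed50_factor = 0.8, iiv_sd = 0.25,
                       ke = 0.35, noise_sd = 0.10,
                       freq_vkorc1_A = 0.90, freq_cyp2c9_star2 = 0.02,
                       freq_cyp2c9_star3 = 0.04,
                       age_mean = 56, age_sd = 10,
                       height_mean = 161, height_sd = 8,
                       weight_mean = 59, weight_sd = 11,
                       p_amiodarone = 0.05, p_digoxin = 0.85,
                       p_indication = c(mechanical_valve = 0.50,
                                        bioprosthetic_valve = 0.40,
                                        valve_repair = 0.08,
                                        other = 0.02),
                       initial_dose = 2.5) {
  p <- as.list(environment())
  if (p$emax <= 0 || p$ed50_base <= 0 || p$hill <= 0 || p$ke <= 0) {
    stop("emax, ed50_base, hill and ke must be positive", call. = FALSE)
  }
  if (p$noise_sd < 0 || p$iiv_sd < 0) {
    stop("noise_sd and iiv_sd must be >= 0", call. = FALSE)
  }
  for (s in c("sens_vkorc1_per_A", "sens_cyp2c9_per_allele",
              "amiodarone_ed50_factor")) {
    if (p[[s]] <= 0 || p[[s]] > 1) {
      stop(s, " must lie in (0, 1]", call. = FALSE)
    }
  }
  freqs <- c(p$freq_vkorc1_A, p$freq_cyp2c9_star2, p$freq_cyp2c9_star3)
  if (any(freqs < 0) || any(freqs > 1) ||
      p$freq_cyp2c9_star2 + p$freq_cyp2c9_star3 > 1) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p$p_indication) - 1) > 1e-8) {
    stop("p_indication must sum to 1", call. = FALSE)
  }
  structure(p, class = "warf_sim_params")
}

#' Clinician dose-titration policy
#'
#' At each follow-up visit the simulated clinician re-estimates the
#' patient's sensitivity and moves the dose a fraction `gain` of the way
#' toward the dose whose steady-state INR would equal the target-range
#' midpoint under that estimate, then rounds to the tablet grid and clamps
#' to `[min_dose, max_dose]`. The sensitivity estimate blends, on the log
#' scale, a genotype-informed prior (the population dose--response scaled
#' by the patient's genotype, the kind of pharmacogenetic initiation
#' algorithm used in genotype-guided management) with the value obtained by
#' inverting the dose--response at the measured INR, taken at face value as
#' steady state. The prior's weight decays as `prior_weight^k` over visits
#' k down to a floor of `prior_floor`, so genotype drives early adjustments,
#' accumulated INR evidence drives the later ones, and the clinician keeps a
#' residual anchor on the pharmacogenetic algorithm throughout maintenance
#' (the anchoring seen in genotype-guided management). Because the measured INR lags steady state early and carries
#' noise, this titration reproduces the early-phase overshoot and
#' fluctuation (days 3--5) and the intermittent one-step dose churn seen in
#' practice. `gain = 0` freezes the dose. The default visit schedule is
#' dense early (days 3, 5, 7, then weekly to day 30, then fortnightly) with
#' uniform jitter of up to `jitter_days` on visits after day 7, emulating
#' irregular real-world monitoring.
#'
#' @param gain proportional adjustment gain in [0, 1].
#' @param grid tablet rounding grid, mg (default 0.25).
#' @param min_dose,max_dose dose bounds, mg/day.
#' @param prior_weight per-visit decay of the genotype prior's weight in
#'   the clinician's sensitivity estimate, in [0, 1).
#' @param prior_floor lower bound on the genotype prior's weight, in
#'   [0, 1).
#' @param schedule_days follow-up days relative to initiation (day 0 is the
#'   initiation visit and always included).
#' @param jitter_days maximum uniform jitter (days) applied to scheduled
#'   visits after day 7; strict day ordering is preserved.
#' @return object of class `warf_policy`.
#' @export
dosing_policy <- function(gain = 0.5, grid = 0.25, min_dose = 0.5,
                          max_dose = 10, prior_weight = 0.5,
                          prior_floor = 0.15,
                          schedule_days = c(3, 5, 7, 14, 21, 28,
                                            seq(42, 84, by = 14)),
                          jitter_days = 2) {
  if (gain < 0 || gain > 1) stop("gain must lie in [0, 1]", call. = FALSE)
  if (grid <= 0) stop("grid must be positive", call. = FALSE)
  if (min_dose < 0 || max_dose <= min_dose) {
    stop("need 0 <= min_dose < max_dose", call. = FALSE)
  }
  if (prior_weight < 0 || prior_weight >= 1) {
    stop("prior_weight must lie in [0, 1)", call. = FALSE)
  }
  if (prior_floor < 0 || prior_floor >= 1) {
    stop("prior_floor must lie in [0, 1)", call. = FALSE)
  }
  schedule_days <- sort(unique(as.numeric(schedule_days)))
  if (length(schedule_days) < 1L || any(schedule_days < 1)) {
    stop("schedule must contain at least one day >= 1", call. = FALSE)
  }
  structure(list(gain = gain, grid = grid, min_dose = min_dose,
                 max_dose = max_dose, prior_weight = prior_weight,
                 prior_floor = prior_floor,
                 schedule_days = schedule_days,
                 jitter_days = jitter_days),
            class = "warf_policy")
}

# Patient-specific ED50 given genotype, comedication and lognormal IIV draw.
patient_ed50 <- function(params, vkorc1_a, cyp_variant, amiodarone, iiv = 1) {
  params$ed50_base *
    params$sens_vkorc1_per_A^vkorc1_a *
    params$sens_cyp2c9_per_allele^cyp_variant *
    (if (amiodarone) params$amiodarone_ed50_factor else 1) *
    iiv
}

#' Steady-state INR under the simulator's dose--response model
#'
#' @param dose daily dose, mg/day (vectorized, >= 0).
#' @param ed50 patient-specific ED50 (see [sample_patient()]), mg/day.
#' @param params a [sim_params()] object.
#' @return steady-state INR; equals `baseline_inr` at dose 0 and is strictly
#'   increasing in dose.
#' @export
steady_state_inr <- function(dose, ed50, params = sim_params()) {
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  dh <- dose^params$hill
  params$baseline_inr + params$emax * dh / (ed50^params$hill + dh)
}

# Dose whose steady-state INR equals `inr_target` (inverse Hill).
dose_for_inr <- function(inr_target, ed50, params) {
  delta <- inr_target - params$baseline_inr
  if (delta <= 0) return(0)
  if (delta >= params$emax) {
    stop("target INR unreachable under emax", call. = FALSE)
  }
  ed50 * (delta / (params$emax - delta))^(1 / params$hill)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x >= hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

sample_genotype <- function(params) {
  a_count <- stats::rbinom(1, 2, params$freq_vkorc1_A)
  vk <- c("GG", "GA", "AA")[a_count + 1L]
  p_allele <- c(`*1` = 1 - params$freq_cyp2c9_star2 - params$freq_cyp2c9_star3,
                `*2` = params$freq_cyp2c9_star2,
                `*3` = params$freq_cyp2c9_star3)
  alleles <- sample(names(p_allele), 2, replace = TRUE, prob = p_allele)
  genotype(cyp2c9 = paste(sort(alleles), collapse = "/"), vkorc1 = vk)
}

#' Draw one virtual patient
#'
#' Samples fixed covariates (genotypes under Hardy--Weinberg, truncated
#' normal anthropometrics, Bernoulli comedication, categorical indication)
#' and the patient's latent dose sensitivity (ED50 with lognormal
#' interindividual variability). Uses the current RNG state; seed the
#' stream with [generate_cohort()] or [with_seed()]-style wrappers for
#' reproducibility.
#'
#' @param params a [sim_params()] object.
#' @param patient_id identifier for the resulting record.
#' @return list with elements `fixed` (covariate list as in
#'   [patient_record()]), `indication`, and latent `ed50` (mg/day).
#' @export
sample_patient <- function(params = sim_params(), patient_id = "p1") {
  g <- sample_genotype(params)
  amiodarone <- stats::runif(1) < params$p_amiodarone
  digoxin <- stats::runif(1) < params$p_digoxin
  indication <- sample(names(params$p_indication), 1,
                       prob = params$p_indication)
  gf <- genotype_features(g)
  ed50 <- patient_ed50(params, gf[["vkorc1_a"]], gf[["cyp_variant_alleles"]],
                       amiodarone,
                       iiv = stats::rlnorm(1, 0, params$iiv_sd))
  list(patient_id = as.character(patient_id),
       age = rtruncnorm1(1, params$age_mean, params$age_sd, 18, 95),
       height = rtruncnorm1(1, params$height_mean, params$height_sd, 120, 210),
       weight = rtruncnorm1(1, params$weight_mean, params$weight_sd, 30, 150),
       genotype = g, amiodarone = amiodarone, digoxin = digoxin,
       indication = indication, ed50 = ed50)
}

#' Simulate a patient's titration follow-up
#'
#' Integrates the latent INR between visits with the closed-form solution of
#' \eqn{dINR/dt = k_e (INR_{ss}(d) - INR)}, applies multiplicative lognormal
#' measurement noise at each visit (measurements reported to 2 decimals),
#' and lets the policy adjust the dose at every visit. The emitted record
#' contains the initiation visit (day 0, baseline INR, initial dose) plus
#' the policy-scheduled follow-ups.
#'
#' @param patient a draw from [sample_patient()].
#' @param policy a [dosing_policy()].
#' @param params a [sim_params()].
#' @param horizon_days simulate visits up to this day.
#' @return a [patient_record()].
#' @export
simulate_followup <- function(patient, policy = dosing_policy(),
                              params = sim_params(), horizon_days = 90) {
  days <- policy$schedule_days[policy$schedule_days <= horizon_days]
  if (!length(days)) stop("horizon precedes the first follow-up", call. = FALSE)
  if (policy$jitter_days > 0) {
    jit <- days > 7
    days[jit] <- days[jit] +
      sample(seq(-policy$jitter_days, policy$jitter_days), sum(jit),
             replace = TRUE)
    days <- sort(unique(pmax(days, 1)))
    days <- days[days <= horizon_days]
  }
  mid <- mean(assign_target_range(patient$indication))
  gf <- genotype_features(patient$genotype)
  ed50_geno <- patient_ed50(params, gf[["vkorc1_a"]],
                            gf[["cyp_variant_alleles"]], patient$amiodarone,
                            iiv = 1) # genotype prior: no access to IIV
  snap <- function(d) {
    min(max(round(d / policy$grid) * policy$grid, policy$min_dose),
        policy$max_dose)
  }
  dose <- snap(params$initial_dose)
  latent <- params$baseline_inr
  measure <- function(x) {
    m <- x * stats::rlnorm(1, 0, params$noise_sd)
    max(round(m, 2), 0.5)
  }
  n <- length(days) + 1L
  out <- data.frame(day = c(0, days), inr = numeric(n), dose = numeric(n))
  out$inr[1] <- measure(latent)
  out$dose[1] <- dose
  prev_day <- 0
  for (k in seq_along(days)) {
    ss <- steady_state_inr(dose, patient$ed50, params)
    latent <- ss + (latent - ss) * exp(-params$ke * (days[k] - prev_day))
    if (!is.finite(latent)) stop("non-finite INR state", call. = FALSE)
    inr_obs <- measure(latent)
    out$inr[k + 1L] <- inr_obs
    # clinician inverts the dose-response at the observed INR (taken as
    # steady state), blends with the genotype prior, and titrates
    delta <- min(max(inr_obs - params$baseline_inr, 0.02 * params$emax),
                 0.98 * params$emax)
    ed50_meas <- dose * ((params$emax - delta) / delta)^(1 / params$hill)
    w <- max(policy$prior_weight^k, policy$prior_floor)
    ed50_hat <- exp(w * log(ed50_geno) + (1 - w) * log(ed50_meas))
    d_hat <- dose_for_inr(mid, ed50_hat, params)
    dose <- snap(dose + policy$gain * (d_hat - dose))
    out$dose[k + 1L] <- dose
    prev_day <- days[k]
  }
  patient_record(patient_id = patient$patient_id, age = patient$age,
                 height = patient$height, weight = patient$weight,
                 genotype = patient$genotype, amiodarone = patient$amiodarone,
                 digoxin = patient$digoxin, indication = patient$indication,
                 visits = out)
}

#' Generate a seeded synthetic cohort
#'
#' @param n number of patients (>= 1).
#' @param seed integer RNG seed; the same `(n, seed, params, policy)` yields
#'   an identical cohort (and, via [write_cohort()], a byte-identical file).
#' @param params a [sim_params()].
#' @param policy a [dosing_policy()].
#' @param horizon_days follow-up horizon.
#' @param path optional file path; when given the cohort is also written as
#'   a cohort CSV.
#' @param id_prefix prefix for generated patient ids.
#' @return a `warf_cohort`.
#' @export
#' @examples
#' coh <- generate_cohort(3, seed = 1)
#' coh
generate_cohort <- function(n, seed, params = sim_params(),
                            policy = dosing_policy(), horizon_days = 90,
                            path = NULL, id_prefix = "sim") {
  stopifnot(n >= 1)
  records <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      p <- sample_patient(params, sprintf("%s%04d", id_prefix, i))
      simulate_followup(p, policy, params, horizon_days)
    })
  })
  cohort <- as_cohort(records)
  if (!is.null(path)) write_cohort(cohort, path)
  cohort
}
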