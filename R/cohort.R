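# Published demographic table for the 18-patient SCID-HSCT cohort:
# mean, SD and observed range per continuous covariate, and comedication
# counts out of 18. Drives the synthetic-cohort generator.
.demographics_continuous <- data.frame(
  covariate = c("age", "albumin", "alt", "ast", "creatinine", "urea",
                "total_protein", "total_bile_acid", "direct_bilirubin",
                "total_bilirubin", "hematocrit", "hemoglobin", "mch", "mchc"),
  mean = c(0.82, 32.76, 38.12, 61.96, 17.72, 2.77, 57.30, 7.08, 4.28, 8.79,
           29.13, 93.58, 25.28, 321.00),
  sd = c(0.56, 3.66, 38.05, 31.48, 3.79, 1.64, 7.35, 5.33, 5.53, 8.53,
         7.50, 24.48, 4.16, 19.56),
  low = c(0.33, 25.10, 11.00, 29.30, 9.00, 0.60, 46.80, 0.10, 0.80, 2.20,
          22.80, 69.00, 19.00, 289.00),
  high = c(3.01, 40.80, 140.10, 152.00, 27.00, 7.00, 75.40, 21.30, 24.40,
           39.70, 53.31, 167.00, 33.30, 366.00),
  stringsAsFactors = FALSE)

.demographics_binary <- c(caspofungin = 9, ethambutol = 10, glucocorticoids = 17,
                          isoniazide = 14, micafungin = 9, mycophenolic_acid = 6,
                          omeprazole = 13, vancomycin = 10) / 18

#' Specification of a synthetic SCID-HSCT cohort
#'
#' Describes the demographic and sampling structure emulated by the
#' generator: defaults mirror the study cohort (18 subjects; weight median
#' 7.50 kg, range 4.20-12.60 kg, coefficient of variation 1.62/7.28; a mean
#' of 7.2 trough concentrations per subject). Trough draws default to days
#' 2, 4, 6, 8, 10, 13 and 15 after the first dose; the mean of 7.2
#' observations per subject is met exactly by giving
#' `round(n_subjects * obs_per_subject_mean) - 7 * n_subjects` subjects one
#' extra trough day. The pre-titration dose defaults to 0.3 mg/kg/day split
#' twice daily -- an assumption, as actual doses received were never printed.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param weight_median median body weight, kg.
#' @param weight_range numeric length 2, truncation range for weights (kg).
#' @param weight_cv coefficient of variation of weight (drives the log-normal
#'   spread before truncation).
#' @param obs_per_subject_mean target mean trough count per subject.
#' @param dose_per_kg total daily dose, mg/kg/day (split over two doses).
#' @param dosing_interval h between doses.
#' @param sampling_days day indices (1 day = 24 h) of pre-dose trough draws.
#' @param seed default RNG seed used by the sampling functions.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18, weight_median = 7.50,
                        weight_range = c(4.20, 12.60), weight_cv = 1.62 / 7.28,
                        obs_per_subject_mean = 7.2, dose_per_kg = 0.3,
                        dosing_interval = 12,
                        sampling_days = c(2, 4, 6, 8, 10, 13, 15),
                        seed = 1L) {
  stopifnot(n_subjects >= 1, length(weight_range) == 2,
            weight_range[1] < weight_range[2], weight_cv > 0,
            obs_per_subject_mean >= 1, dose_per_kg > 0, dosing_interval > 0,
            length(sampling_days) >= 1, all(sampling_days > 0))
  if (weight_median <= weight_range[1] || weight_median >= weight_range[2])
    stop("infeasible truncation: weight_median must lie strictly inside weight_range")
  structure(list(n_subjects = as.integer(n_subjects),
                 weight_median = weight_median, weight_range = weight_range,
                 weight_cv = weight_cv,
                 obs_per_subject_mean = obs_per_subject_mean,
                 dose_per_kg = dose_per_kg, dosing_interval = dosing_interval,
                 sampling_days = sort(unique(as.integer(sampling_days))),
                 seed = seed),
            class = "cohort_spec")
}

rtrunc <- function(n, sampler, low, high, max_tries = 10000) {
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    x <- sampler(n)
    out <- c(out, x[x >= low & x <= high])
    tries <- tries + 1
    if (tries > max_tries) stop("truncated sampling failed to accept values")
  }
  out[seq_len(n)]
}

#' Sample demographics for a synthetic cohort
#'
#' Weights are log-normal with median equal to the spec median (log-scale SD
#' from the coefficient of variation), truncated by rejection to the spec
#' range. Continuous covariates are normal with the published cohort means
#' and SDs, truncated to the published ranges; comedication flags are
#' Bernoulli with probability equal to the published count over 18.
#' Covariates are sampled independently: only body weight enters the final
#' model, so their joint structure is immaterial downstream.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return data.frame with one row per subject: `id`, `weight` (kg, rounded
#'   to 0.01) and covariate columns.
#' @export
sample_demographics <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  sdlog <- sqrt(log(1 + spec$weight_cv^2))
  weight <- rtrunc(n, function(k) rlnorm(k, log(spec$weight_median), sdlog),
                   spec$weight_range[1], spec$weight_range[2])
  out <- data.frame(id = seq_len(n), weight = round(weight, 2))
  for (i in seq_len(nrow(.demographics_continuous))) {
    r <- .demographics_continuous[i, ]
    out[[r$covariate]] <- round(
      rtrunc(n, function(k) rnorm(k, r$mean, r$sd), r$low, r$high), 2)
  }
  for (nm in names(.demographics_binary))
    out[[nm]] <- rbinom(n, 1, .demographics_binary[[nm]])
  out
}

# Deterministic allocation of trough days: every subject gets
# floor(total/n) days, the first (total mod n) subjects one more; the day
# pool extends past the configured days in 2-day steps when needed.
allocate_days <- function(spec) {
  n <- spec$n_subjects
  total <- round(n * spec$obs_per_subject_mean)
  base <- total %/% n
  extra <- total %% n
  n_i <- rep(base, n) + as.integer(seq_len(n) <= extra)
  pool <- spec$sampling_days
  while (max(n_i) > length(pool))
    pool <- c(pool, max(pool) + 2L)
  lapply(n_i, function(k) pool[seq_len(k)])
}

#' Simulate a synthetic cohort dataset
#'
#' Forward simulation from the generative model: per subject,
#' \eqn{\eta \sim N(0, diag(\omega^2))}; twice-daily doses of
#' `weight * dose_per_kg / 2` mg from time 0 through the last trough day;
#' pre-dose trough concentrations on the allocated sampling days perturbed by
#' the combined residual-error model. Simulated observations below zero are
#' clamped to 0; values below the 2.0 ng/ml assay lower limit are flagged
#' (column `BLQ`) but never dropped. True random effects are retained in the
#' `true_eta` attribute for recovery testing. Observed concentrations are
#' rounded to 0.001 ng/ml so that written CSV files round-trip bit-exactly.
#'
#' @param spec a [cohort_spec()].
#' @param model a [population_model()]; the default is the published final
#'   model.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return A `pk_dataset` (see [as_pk_dataset()]) with attribute `true_eta`,
#'   a data.frame of the generative `eta_cl`, `eta_v` per subject.
#' @export
simulate_cohort <- function(spec, model = population_model(),
                            seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "population_model"))
  demog <- sample_demographics(spec, seed = seed)  # seeds the RNG stream
  days <- allocate_days(spec)
  n <- spec$n_subjects
  eta <- cbind(rnorm(n, 0, model$omega_cl), rnorm(n, 0, model$omega_v))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    wt <- demog$weight[i]
    obs_t <- 24 * days[[i]]
    dose_t <- seq(0, max(obs_t) - spec$dosing_interval,
                  by = spec$dosing_interval)
    amt <- wt * spec$dose_per_kg / 2
    tp <- typical_params(model, wt, demog[i, , drop = FALSE])
    ipred <- conc_profile_cpp(obs_t, dose_t, rep(amt, length(dose_t)),
                              tp$cl * exp(eta[i, 1]), tp$v * exp(eta[i, 2]),
                              model$ka)
    dv <- ipred * (1 + rnorm(length(ipred), 0, model$sigma_prop)) +
      rnorm(length(ipred), 0, model$sigma_add)
    dv <- round(pmax(dv, 0), 3)
    sub <- rbind(
      data.frame(ID = i, TIME = obs_t, EVID = 0L, AMT = NA_real_, DV = dv,
                 MDV = 0L),
      data.frame(ID = i, TIME = dose_t, EVID = 1L, AMT = amt, DV = NA_real_,
                 MDV = 1L))
    sub <- sub[order(sub$TIME, sub$EVID), , drop = FALSE]  # trough before dose
    sub$WT <- wt
    for (nm in setdiff(names(demog), c("id", "weight")))
      sub[[nm]] <- demog[[nm]][i]
    sub$BLQ <- ifelse(sub$EVID == 0L & sub$DV < 2.0, 1L, 0L)
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- as_pk_dataset(out)
  attr(out, "true_eta") <- data.frame(id = seq_len(n), eta_cl = eta[, 1],
                                      eta_v = eta[, 2])
  out
}
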