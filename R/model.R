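#' Population pharmacokinetic model for oral tacrolimus
#'
#' Container for the full generative model: typical apparent clearance and
#' volume at the 70 kg reference weight, fixed allometric exponents, the fixed
#' first-order absorption rate constant, log-normal inter-individual
#' variability (IIV) on CL/F and V/F, and a combined
#' proportional-plus-additive residual-error model
#' \eqn{M = N(1 + \epsilon_1) + \epsilon_2}.
#'
#' The defaults are the final published estimates for children with SCID
#' undergoing HSCT: CL/F 13.1 L/h and V/F 10900 L at 70 kg (exponents
#' 0.75 and 1), Ka fixed at 4.48/h, IIV standard deviations 0.451 (CL/F)
#' and 0.592 (V/F), residual SDs 0.257 (proportional) and 1.265 ng/ml
#' (additive). omega and sigma are interpreted and stored as standard
#' deviations, the usual reporting convention for estimates of this
#' magnitude.
#'
#' @param tv_cl typical CL/F at `ref_weight`, L/h.
#' @param tv_v typical V/F at `ref_weight`, L.
#' @param ka first-order absorption rate constant, 1/h (fixed in estimation).
#' @param ref_weight allometric reference body weight, kg.
#' @param exp_cl,exp_v allometric exponents for CL/F and V/F.
#' @param omega_cl,omega_v IIV standard deviations (dimensionless, log scale).
#' @param sigma_prop,sigma_add residual-error SDs: proportional
#'   (dimensionless) and additive (ng/ml).
#' @param covariate_effects list of [covariate_effect()] terms beyond the
#'   always-present weight allometry.
#' @return An object of class `population_model`.
#' @seealso [typical_clearance()], [individual_params()], [simulate_cohort()]
#' @examples
#' m <- population_model()
#' typical_clearance(m, 7.5)
#' @export
population_model <- function(tv_cl = 13.1, tv_v = 10900, ka = 4.48,
                             ref_weight = 70, exp_cl = 0.75, exp_v = 1,
                             omega_cl = 0.451, omega_v = 0.592,
                             sigma_prop = 0.257, sigma_add = 1.265,
                             covariate_effects = list()) {
  stopifnot(tv_cl > 0, tv_v > 0, ka > 0, ref_weight > 0,
            is.finite(exp_cl), is.finite(exp_v),
            omega_cl >= 0, omega_v >= 0, sigma_prop >= 0, sigma_add >= 0)
  if (length(covariate_effects) && is.null(names(covariate_effects)))
    names(covariate_effects) <- vapply(covariate_effects, function(e)
      paste(e$parameter, e$covariate, sep = "_"), character(1))
  structure(list(tv_cl = tv_cl, tv_v = tv_v, ka = ka,
                 ref_weight = ref_weight, exp_cl = exp_cl, exp_v = exp_v,
                 omega_cl = omega_cl, omega_v = omega_v,
                 sigma_prop = sigma_prop, sigma_add = sigma_add,
                 covariate_effects = covariate_effects),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (1-cpt oral, allometric weight scaling)\n")
  cat(sprintf("  CL/F %g L/h, V/F %g L at %g kg (exponents %g / %g), Ka %g /h\n",
              x$tv_cl, x$tv_v, x$ref_weight, x$exp_cl, x$exp_v, x$ka))
  cat(sprintf("  IIV SD: omega_CL %g, omega_V %g; residual SD: prop %g, add %g ng/ml\n",
              x$omega_cl, x$omega_v, x$sigma_prop, x$sigma_add))
  for (e in x$covariate_effects)
    cat(sprintf("  covariate: %s on %s (%s form), theta = %g\n",
                e$covariate, toupper(e$parameter), e$form, e$theta))
  invisible(x)
}

#' Covariate effect term
#'
#' A single parameter-covariate relation tested or retained during stepwise
#' covariate modelling. Continuous covariates use the power form
#' \eqn{TV \times (cov/cov_{median})^\theta}; categorical (0/1) covariates
#' use the linear-shift form \eqn{TV \times (1 + \theta \, cov)}.
#'
#' @param parameter `"cl"` or `"v"`.
#' @param covariate dataset column name holding the covariate.
#' @param form `"power"` (continuous) or `"linear"` (categorical).
#' @param theta effect size (0 = no effect).
#' @param ref centering value for the power form (the population median);
#'   `NA` means "compute from the dataset at fit time".
#' @return An object of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter = c("cl", "v"), covariate,
                             form = c("power", "linear"),
                             theta = 0, ref = NA_real_) {
  parameter <- match.arg(parameter)
  form <- match.arg(form)
  stopifnot(is.character(covariate), length(covariate) == 1L,
            is.finite(theta) || is.na(theta))
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 theta = theta, ref = ref),
            class = "covariate_effect")
}

#' Individual random effects
#'
#' Subject-level deviations entering the model as
#' \eqn{P_i = TV \times e^{\eta}}; the zero vector reproduces the typical
#' individual.
#'
#' @param eta_cl,eta_v finite reals (log-scale deviations for CL/F and V/F).
#' @return An object of class `random_effects`.
#' @export
random_effects <- function(eta_cl = 0, eta_v = 0) {
  stopifnot(is.finite(eta_cl), is.finite(eta_v))
  structure(list(eta_cl = eta_cl, eta_v = eta_v), class = "random_effects")
}

#' Individual PK parameter set
#'
#' @param cl_f apparent clearance, L/h.
#' @param v_f apparent volume of distribution, L.
#' @param ka absorption rate constant, 1/h. Exact equality with the
#'   elimination rate constant `cl_f/v_f` is rejected (flip-flop degeneracy);
#'   near-equality is handled analytically by [concentration_profile()].
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(cl_f, v_f, ka) {
  stopifnot(cl_f > 0, v_f > 0, ka > 0)
  if (identical(ka, cl_f / v_f))
    stop("ka equals cl_f/v_f exactly: absorption/elimination not separable")
  structure(list(cl_f = cl_f, v_f = v_f, ka = ka), class = "pk_params")
}

resolve_effects <- function(model) {
  for (e in model$covariate_effects)
    if (e$form == "power" && is.na(e$ref))
      stop("unresolved covariate reference (median) for ", e$covariate,
           "; supply `ref` or fit the model first")
  model
}

# Typical CL/F and V/F for given weight(s) and optional covariate rows.
# `covariates`: data.frame with one row per weight (or NULL).
typical_params <- function(model, weight, covariates = NULL) {
  stopifnot(all(weight > 0))
  model <- resolve_effects(model)
  cl <- model$tv_cl * (weight / model$ref_weight)^model$exp_cl
  v <- model$tv_v * (weight / model$ref_weight)^model$exp_v
  for (e in model$covariate_effects) {
    if (is.null(covariates) || is.null(covariates[[e$covariate]]))
      stop("covariate '", e$covariate, "' required by the model is missing")
    x <- covariates[[e$covariate]]
    fac <- if (e$form == "power") {
      if (any(x <= 0)) stop("power-form covariate '", e$covariate,
                            "' must be strictly positive")
      (x / e$ref)^e$theta
    } else {
      1 + e$theta * x
    }
    if (any(!is.finite(fac)) || any(fac <= 0)) return(NULL)  # invalid region
    if (e$parameter == "cl") cl <- cl * fac else v <- v * fac
  }
  list(cl = cl, v = v)
}

#' Typical (population) clearance at a given body weight
#'
#' Allometric scaling \eqn{CL/F = \theta_{CL} (WT/70)^{0.75}} with the
#' package defaults; e.g. 13.1 L/h at 70 kg gives 0.36 L/h/kg at 5 kg and
#' 0.26 L/h/kg at 20 kg.
#'
#' @param model a [population_model()].
#' @param weight body weight(s), kg; must be strictly positive.
#' @return CL/F in L/h (vectorized over `weight`).
#' @export
typical_clearance <- function(model, weight) {
  if (any(weight <= 0)) stop("weight must be strictly positive")
  model$tv_cl * (weight / model$ref_weight)^model$exp_cl
}

#' Typical (population) volume of distribution at a given body weight
#'
#' Linear allometry \eqn{V/F = \theta_V (WT/70)}.
#'
#' @inheritParams typical_clearance
#' @return V/F in L (vectorized over `weight`).
#' @export
typical_volume <- function(model, weight) {
  if (any(weight <= 0)) stop("weight must be strictly positive")
  model$tv_v * (weight / model$ref_weight)^model$exp_v
}

#' Individual PK parameters from typical values and random effects
#'
#' \eqn{P_i = TV(WT) \times e^{\eta_i}} for CL/F and V/F; Ka is fixed at the
#' model value.
#'
#' @inheritParams typical_clearance
#' @param eta a [random_effects()] object.
#' @param covariates optional single-row data.frame with covariate values
#'   required by the model's covariate effects.
#' @return A [pk_params()] object.
#' @export
individual_params <- function(model, weight, eta = random_effects(),
                              covariates = NULL) {
  if (length(weight) != 1L || weight <= 0)
    stop("weight must be a single strictly positive value")
  tp <- typical_params(model, weight, covariates)
  if (is.null(tp)) stop("covariate effects produce non-positive parameters")
  pk_params(cl_f = tp$cl * exp(eta$eta_cl), v_f = tp$v * exp(eta$eta_v),
            ka = model$ka)
}

#' Concentration-time profile under multiple oral doses
#'
#' Closed-form superposition of one-compartment first-order
#' absorption/elimination terms,
#' \deqn{C(t) = \sum_d \frac{D_d k_a}{V (k_a - k_e)}
#'   \left(e^{-k_e (t - t_d)} - e^{-k_a (t - t_d)}\right),}
#' with \eqn{k_e = CL/V}; doses with \eqn{t < t_d} contribute nothing, and the
#' analytic \eqn{k_a \to k_e} limit replaces the difference term when
#' \eqn{|k_a - k_e|(t - t_d) < 10^{-9}}. Amounts are mg and volumes L, so the
#' raw result is mg/L; it is returned multiplied by 1000, i.e. in
#' \eqn{\mu}g/L = ng/ml, the whole-blood unit used in tacrolimus TDM.
#'
#' A dose given exactly at an evaluation time contributes zero there, so
#' evaluating at a dosing time yields the pre-dose (trough) concentration.
#'
#' @param params a [pk_params()] object.
#' @param doses data.frame with columns `time` (h, >= 0) and `amount` (mg, > 0).
#' @param times evaluation times, h (>= 0).
#' @return concentrations in ng/ml, one per element of `times`.
#' @export
concentration_profile <- function(params, doses, times) {
  stopifnot(inherits(params, "pk_params"),
            is.data.frame(doses), all(c("time", "amount") %in% names(doses)),
            all(times >= 0))
  if (nrow(doses)) stopifnot(all(doses$time >= 0), all(doses$amount > 0))
  conc_profile_cpp(as.numeric(times), as.numeric(doses$time),
                   as.numeric(doses$amount), params$cl_f, params$v_f,
                   params$ka)
}

#' Apply the combined residual-error model
#'
#' \eqn{M = N(1+\epsilon_1) + \epsilon_2}: given prediction `pred` and a pair
#' of residual draws, returns the "observed" value. With \eqn{\epsilon_1 \sim
#' N(0,\sigma_1^2)} and \eqn{\epsilon_2 \sim N(0,\sigma_2^2)} the conditional
#' variance is \eqn{pred^2\sigma_1^2 + \sigma_2^2}. Negative outputs are
#' possible (additive error) and are deliberately not clamped here; clamping
#' belongs to the reporting/generation layer, never the likelihood.
#'
#' @param model a [population_model()] (carries the sigmas; not used in the
#'   arithmetic itself but documents the generative context).
#' @param pred non-negative model prediction(s), ng/ml.
#' @param eps numeric of length 2 `(eps1, eps2)`, or an `n x 2` matrix paired
#'   with `n` predictions.
#' @return perturbed concentration(s), ng/ml.
#' @export
apply_residual_error <- function(model, pred, eps) {
  stopifnot(all(pred >= 0))
  if (is.matrix(eps)) {
    stopifnot(ncol(eps) == 2, nrow(eps) == length(pred))
    pred * (1 + eps[, 1]) + eps[, 2]
  } else {
    stopifnot(length(eps) == 2)
    pred * (1 + eps[1]) + eps[2]
  }
}
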