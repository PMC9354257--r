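# --- dataset compilation -----------------------------------------------------

# Split an event table into flat per-subject arrays for the compiled kernel.
compile_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "pk_dataset"))
  ids <- unique(dataset$ID)
  obs <- dataset$EVID == 0L & dataset$MDV == 0L
  dose <- dataset$EVID == 1L
  obs_time <- dose_time <- dose_amt <- obs_dv <- numeric(0)
  obs_ptr <- dose_ptr <- integer(length(ids) + 1L)
  for (k in seq_along(ids)) {
    oi <- which(obs & dataset$ID == ids[k])
    di <- which(dose & dataset$ID == ids[k])
    if (!length(oi)) stop("subject ", ids[k], " has no usable observations")
    obs_time <- c(obs_time, dataset$TIME[oi])
    obs_dv <- c(obs_dv, dataset$DV[oi])
    dose_time <- c(dose_time, dataset$TIME[di])
    dose_amt <- c(dose_amt, dataset$AMT[di])
    obs_ptr[k + 1L] <- length(obs_time)
    dose_ptr[k + 1L] <- length(dose_time)
  }
  first <- dataset[!duplicated(dataset$ID), , drop = FALSE]
  first <- first[match(ids, first$ID), , drop = FALSE]
  list(ids = ids, obs_time = obs_time, obs_dv = obs_dv, obs_ptr = obs_ptr,
       dose_time = dose_time, dose_amt = dose_amt, dose_ptr = dose_ptr,
       subjects = first)
}

# Fill in NA covariate-centering values with dataset medians (power form).
resolve_model_refs <- function(model, subjects) {
  eff <- model$covariate_effects
  for (k in seq_along(eff)) {
    e <- eff[[k]]
    if (e$form == "power" && is.na(e$ref)) {
      x <- subjects[[e$covariate]]
      if (is.null(x)) stop("covariate '", e$covariate, "' absent from dataset")
      eff[[k]]$ref <- median(x)
      if (eff[[k]]$ref <= 0) stop("non-positive median for power covariate '",
                                  e$covariate, "'")
    }
  }
  model$covariate_effects <- eff
  model
}

foce_eval <- function(cd, model) {
  tp <- typical_params(model, cd$subjects$WT, cd$subjects)
  if (is.null(tp)) return(NULL)
  foce_cpp(cd$obs_time, cd$obs_dv, cd$obs_ptr,
           cd$dose_time, cd$dose_amt, cd$dose_ptr,
           tp$cl, tp$v, model$ka,
           model$omega_cl, model$omega_v, model$sigma_prop, model$sigma_add)
}

#' Marginal-likelihood objective (conditional estimation with interaction)
#'
#' Returns the NONMEM-style objective function value: -2 times the
#' approximate log marginal likelihood summed over subjects, with all
#' \eqn{2\pi} constants dropped. Per subject, the conditional mode
#' \eqn{\hat\eta} maximizes the joint density of the observations (residual
#' variance \eqn{f^2\sigma_1^2 + \sigma_2^2} evaluated at the individual
#' prediction -- the "interaction") and the \eqn{N(0,\Omega)} prior; the
#' marginal integral is then Laplace-approximated at \eqn{\hat\eta}. In the
#' \eqn{\omega \to 0} limit the objective reduces to the fixed-effects
#' weighted least-squares deviance
#' \eqn{\sum[(DV-PRED)^2/g + \log g]}.
#'
#' @param dataset a `pk_dataset`; every subject needs at least one usable
#'   observation.
#' @param model a [population_model()]; unresolved covariate medians are
#'   computed from the dataset.
#' @return list with `ofv` (total and the per-subject breakdown
#'   `ofv_by_subject`) and `post_hoc`, a data.frame of conditional modes
#'   (`id`, `eta_cl`, `eta_v`).
#' @export
foce_objective <- function(dataset, model) {
  cd <- compile_dataset(dataset)
  model <- resolve_model_refs(model, cd$subjects)
  res <- foce_eval(cd, model)
  if (is.null(res)) stop("covariate effects give non-positive typical values")
  list(ofv = res$ofv, ofv_by_subject = res$ofv_by_subject,
       post_hoc = data.frame(id = cd$ids, eta_cl = res$eta_cl,
                             eta_v = res$eta_v))
}

# --- parameter vector plumbing ----------------------------------------------

.log_pars <- c("tv_cl", "tv_v", "omega_cl", "omega_v", "sigma_prop", "sigma_add")

par_skeleton <- function(model, fixed) {
  bad <- setdiff(fixed, c(.log_pars, "ka"))
  if (length(bad)) stop("unknown parameter name(s) in `fixed`: ",
                        paste(bad, collapse = ", "))
  free_log <- setdiff(.log_pars, fixed)
  start <- if (length(free_log)) log(unlist(model[free_log])) else numeric(0)
  lower <- rep(log(1e-6), length(free_log))
  upper <- rep(log(1e6), length(free_log))
  names(start) <- free_log
  th_names <- character(0)
  if (length(model$covariate_effects)) {
    th_names <- paste0("theta_", vapply(model$covariate_effects, function(e)
      paste(e$parameter, e$covariate, sep = "_"), character(1)))
    th0 <- vapply(model$covariate_effects, `[[`, numeric(1), "theta")
    start <- c(start, setNames(th0, th_names))
    lower <- c(lower, rep(-25, length(th0)))
    upper <- c(upper, rep(25, length(th0)))
  }
  list(start = start, lower = lower, upper = upper,
       free_log = free_log, theta_names = th_names)
}

model_from_par <- function(model, par, skel) {
  for (nm in skel$free_log) model[[nm]] <- exp(par[[nm]])
  for (k in seq_along(skel$theta_names))
    model$covariate_effects[[k]]$theta <- par[[skel$theta_names[k]]]
  model
}

# --- maximum likelihood fit --------------------------------------------------

#' Fit the population model by conditional estimation
#'
#' Minimizes [foce_objective()] over the log-transformed positive parameters
#' (typical values, IIV and residual SDs) plus any covariate effect sizes
#' (natural scale). `ka` must be in `fixed`: with trough-only oral data the
#' absorption constant is not identifiable and is fixed at its literature
#' value. Relative standard errors come from the inverse Hessian of the
#' objective at the optimum (delta method on the log scale, so SE% of a
#' log-parameter is 100 times its log-scale SE).
#'
#' @param dataset a `pk_dataset`.
#' @param start a [population_model()] holding starting values (and the
#'   covariate structure to estimate).
#' @param fixed character vector of parameter names held at their `start`
#'   values; must contain `"ka"`. Valid names: `"ka"`, `"tv_cl"`, `"tv_v"`,
#'   `"omega_cl"`, `"omega_v"`, `"sigma_prop"`, `"sigma_add"`.
#' @param control passed to [stats::optim()]'s BFGS (defaults:
#'   `reltol = 1e-12`, `maxit = 500`, finite-difference step `1e-4`).
#' @return An object of class `pk_fit`: `estimates` (a `population_model`),
#'   `se_percent`, `ofv`, `post_hoc` conditional modes, `converged`, and the
#'   optimizer bookkeeping.
#' @export
fit_popmodel <- function(dataset, start = population_model(), fixed = "ka",
                         control = list()) {
  if (!"ka" %in% fixed)
    stop("`fixed` must contain \"ka\": absorption is not identifiable from troughs")
  cd <- compile_dataset(dataset)
  start <- resolve_model_refs(start, cd$subjects)
  skel <- par_skeleton(start, fixed)
  obj <- function(p) {
    if (any(p < skel$lower) || any(p > skel$upper)) return(1e10)
    m <- model_from_par(start, as.list(p), skel)
    res <- tryCatch(foce_eval(cd, m), error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    res$ofv
  }
  if (!length(skel$start)) {
    # everything fixed: nothing to optimize, just evaluate
    final <- foce_eval(cd, start)
    return(structure(list(
      estimates = start, se_percent = setNames(numeric(0), character(0)),
      ofv = final$ofv,
      post_hoc = data.frame(id = cd$ids, eta_cl = final$eta_cl,
                            eta_v = final$eta_v),
      converged = is.finite(final$ofv), fixed = fixed,
      optimizer = list(convergence = 0L, counts = c(0L, 0L),
                       objective = final$ofv)),
      class = "pk_fit"))
  }
  # BFGS on log-parameters; the finite-difference step is matched to the
  # noise floor of the nested conditional-mode optimization.
  ctl <- modifyList(list(reltol = 1e-12, maxit = 500,
                         ndeps = rep(1e-4, length(skel$start))),
                    control)
  opt <- optim(skel$start, obj, method = "BFGS", control = ctl)
  est_model <- model_from_par(start, as.list(opt$par), skel)
  final <- foce_eval(cd, est_model)
  se <- se_percent_from_hessian(obj, opt$par, skel, est_model)
  structure(list(
    estimates = est_model,
    se_percent = se,
    ofv = final$ofv,
    post_hoc = data.frame(id = cd$ids, eta_cl = final$eta_cl,
                          eta_v = final$eta_v),
    converged = opt$convergence == 0 && is.finite(final$ofv),
    fixed = fixed,
    optimizer = list(convergence = opt$convergence, counts = opt$counts,
                     objective = opt$value)),
    class = "pk_fit")
}

# SE% via the inverse of the numerically differenced OFV Hessian;
# Var(theta_hat) = 2 * H^-1 because OFV = -2 log L.
se_percent_from_hessian <- function(obj, par, skel, model) {
  p <- length(par)
  H <- matrix(NA_real_, p, p)
  # step large enough that the inner-optimization noise floor (~1e-7 on the
  # objective) cannot corrupt the second differences
  hstep <- pmax(0.01, 0.01 * abs(par))
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    H[i, j] <- H[j, i] <-
      (obj(par + ei + ej) - obj(par + ei - ej) -
         obj(par - ei + ej) + obj(par - ei - ej)) / (4 * hstep[i] * hstep[j])
  }
  se <- rep(NA_real_, p)
  ok <- tryCatch({
    cov <- 2 * solve(H)
    d <- diag(cov)
    se[d > 0] <- sqrt(d[d > 0])
    TRUE
  }, error = function(e) FALSE)
  out <- setNames(rep(NA_real_, p), names(par))
  if (ok) {
    # log-scale SE is already relative; thetas are natural scale
    for (k in seq_len(p)) {
      nm <- names(par)[k]
      out[nm] <- if (nm %in% skel$free_log) 100 * se[k]
      else if (abs(par[k]) > 1e-12) 100 * se[k] / abs(par[k])
      else NA_real_
    }
  }
  out
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: OFV %.3f (%s)\n", x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  print(fit_parameter_table(x))
  invisible(x)
}

#' Parameter table for a fit (estimate and SE%)
#'
#' Machine-readable mirror of the usual final-parameter report layout; the
#' bootstrap columns (median, percentile CI, bias) are appended by
#' [bootstrap_model()]'s own table.
#'
#' @param fit a `pk_fit`.
#' @return data.frame with columns `parameter`, `estimate`, `se_percent`.
#' @export
fit_parameter_table <- function(fit) {
  m <- fit$estimates
  nm <- c(.log_pars, "ka")
  est <- c(unlist(m[.log_pars]), ka = m$ka)
  se <- fit$se_percent[match(nm, names(fit$se_percent))]
  se[nm == "ka"] <- NA_real_
  tab <- data.frame(parameter = nm, estimate = unname(est),
                    se_percent = unname(se))
  for (k in seq_along(m$covariate_effects)) {
    e <- m$covariate_effects[[k]]
    pnm <- paste0("theta_", e$parameter, "_", e$covariate)
    tab <- rbind(tab, data.frame(parameter = pnm, estimate = e$theta,
                                 se_percent = unname(fit$se_percent[pnm])))
  }
  tab$fixed <- tab$parameter %in% fit$fixed
  tab
}

# --- stepwise covariate modelling -------------------------------------------

#' Stepwise covariate selection on OFV thresholds
#'
#' Forward step: each remaining candidate is added to the current model and
#' refit; the candidate with the largest OFV drop is included if the drop
#' exceeds `include_threshold` (3.84, chi-square p < 0.05 at 1 df); repeat
#' until no candidate qualifies. Backward step: each included candidate is
#' removed in turn and only retained if its removal raises the OFV by more
#' than `exclude_threshold` (6.63, p < 0.01). Body weight enters every model
#' through the fixed allometric exponents (0.75 / 1) and is never a
#' candidate. Candidates whose refit fails are skipped and recorded in the
#' trace, never silently dropped.
#'
#' @param dataset a `pk_dataset`.
#' @param base_fit a converged `pk_fit` for the covariate-free (allometry
#'   only) model.
#' @param candidates list of [covariate_effect()] objects with `theta = 0`.
#' @param include_threshold,exclude_threshold OFV decision bars.
#' @return list with `fit` (the final `pk_fit`), `model` (its estimates) and
#'   `trace`, a data.frame of every decision (phase, candidate, OFV, delta,
#'   action).
#' @export
covariate_step <- function(dataset, base_fit, candidates,
                           include_threshold = 3.84,
                           exclude_threshold = 6.63) {
  stopifnot(inherits(base_fit, "pk_fit"))
  if (!base_fit$converged) stop("base fit has not converged")
  cand_name <- function(e) paste(e$parameter, e$covariate, sep = "_")
  name_effects <- function(effs) {
    names(effs) <- vapply(effs, cand_name, character(1))
    effs
  }
  trace <- data.frame(phase = character(0), candidate = character(0),
                      ofv = numeric(0), delta = numeric(0),
                      action = character(0))
  note <- function(phase, cand, ofv, delta, action)
    rbind(trace, data.frame(phase = phase, candidate = cand, ofv = ofv,
                            delta = delta, action = action))

  current <- base_fit
  included <- list()
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    fits <- vector("list", length(remaining))
    drops <- rep(NA_real_, length(remaining))
    for (k in seq_along(remaining)) {
      m <- current$estimates
      m$covariate_effects <- name_effects(c(included, remaining[k]))
      f <- tryCatch(fit_popmodel(dataset, start = m, fixed = current$fixed),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        trace <- note("forward", cand_name(remaining[[k]]), NA, NA, "skip (refit failed)")
        next
      }
      fits[[k]] <- f
      drops[k] <- current$ofv - f$ofv
      trace <- note("forward", cand_name(remaining[[k]]), f$ofv, drops[k], "tested")
    }
    if (all(is.na(drops)) || max(drops, na.rm = TRUE) <= include_threshold) break
    best <- which.max(drops)
    trace <- note("forward", cand_name(remaining[[best]]),
                  fits[[best]]$ofv, drops[best], "included")
    included <- name_effects(c(included, remaining[best]))
    current <- fits[[best]]
    remaining <- remaining[-best]
  }

  if (length(included)) {
    keep <- rep(TRUE, length(included))
    for (k in seq_along(included)) {
      m <- current$estimates
      m$covariate_effects <- name_effects(included[which(keep & seq_along(included) != k)])
      f <- tryCatch(fit_popmodel(dataset, start = m, fixed = current$fixed),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        trace <- note("backward", cand_name(included[[k]]), NA, NA, "skip (refit failed)")
        next
      }
      rise <- f$ofv - current$ofv
      if (rise > exclude_threshold) {
        trace <- note("backward", cand_name(included[[k]]), f$ofv, rise, "retained")
      } else {
        trace <- note("backward", cand_name(included[[k]]), f$ofv, rise, "removed")
        keep[k] <- FALSE
        current <- f
      }
    }
    included <- included[keep]
  }
  list(fit = current, model = current$estimates, trace = trace,
       included = included)
}
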