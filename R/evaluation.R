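#' Bootstrap bias in percent
#'
#' \eqn{bias = (median - estimate)/estimate \times 100\%}, reported to three
#' decimals as in the usual bootstrap-validation table.
#'
#' @param estimate original point estimate (non-zero).
#' @param median bootstrap median.
#' @return bias in percent, rounded to 3 decimals (vectorized).
#' @export
bias_percent <- function(estimate, median) {
  if (any(estimate == 0)) stop("bias undefined for a zero estimate")
  round((median - estimate) / estimate * 100, 3)
}

#' Goodness-of-fit diagnostics table
#'
#' One row per observation: population prediction `PRED` (random effects at
#' zero), individual prediction `IPRED` (at the conditional mode), the
#' individual weighted residual
#' \eqn{iWRES = (DV - IPRED)/\sqrt{IPRED^2\sigma_1^2 + \sigma_2^2}}, and the
#' conditional weighted residual `CWRES` from the first-order expansion of
#' the model at the conditional mode: the linearized residual
#' \eqn{DV - f(\hat\eta) + G\hat\eta} decorrelated by the Cholesky factor of
#' the subject-level covariance \eqn{V = diag(g) + G \Omega G'}. Both are
#' approximately standard normal under a correct model.
#'
#' @param dataset a `pk_dataset`.
#' @param fit a converged `pk_fit`.
#' @return data.frame of class `pk_diagnostics`: `ID`, `TIME`, `DV`, `PRED`,
#'   `IPRED`, `IWRES`, `CWRES`.
#' @export
diagnostics <- function(dataset, fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (!fit$converged) stop("diagnostics require a converged fit")
  model <- fit$estimates
  if (model$sigma_prop == 0 && model$sigma_add == 0)
    stop("degenerate model: zero residual variance")
  cd <- compile_dataset(dataset)
  model <- resolve_model_refs(model, cd$subjects)
  tp <- typical_params(model, cd$subjects$WT, cd$subjects)
  Om <- diag(c(model$omega_cl^2, model$omega_v^2), 2)
  out <- vector("list", length(cd$ids))
  for (k in seq_along(cd$ids)) {
    oi <- (cd$obs_ptr[k] + 1L):cd$obs_ptr[k + 1L]
    di <- seq_len(cd$dose_ptr[k + 1L] - cd$dose_ptr[k]) + cd$dose_ptr[k]
    tt <- cd$obs_time[oi]; dv <- cd$obs_dv[oi]
    dt <- cd$dose_time[di]; da <- cd$dose_amt[di]
    eta <- as.numeric(fit$post_hoc[fit$post_hoc$id == cd$ids[k],
                                   c("eta_cl", "eta_v")])
    prof <- function(e) conc_profile_cpp(tt, dt, da, tp$cl[k] * exp(e[1]),
                                         tp$v[k] * exp(e[2]), model$ka)
    pred <- prof(c(0, 0))
    ipred <- prof(eta)
    g <- ipred^2 * model$sigma_prop^2 + model$sigma_add^2
    if (any(g <= 0)) stop("zero residual variance for subject ", cd$ids[k])
    iwres <- (dv - ipred) / sqrt(g)
    h <- 1e-5
    G <- cbind((prof(eta + c(h, 0)) - prof(eta - c(h, 0))) / (2 * h),
               (prof(eta + c(0, h)) - prof(eta - c(0, h))) / (2 * h))
    V <- diag(g, length(g)) + G %*% Om %*% t(G)
    rlin <- dv - ipred + as.vector(G %*% eta)
    cwres <- as.vector(forwardsolve(t(chol(V)), rlin))
    out[[k]] <- data.frame(ID = cd$ids[k], TIME = tt, DV = dv, PRED = pred,
                           IPRED = ipred, IWRES = iwres, CWRES = cwres)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pk_diagnostics", class(res))
  res
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original subject count,
#' refits each replicate from the original estimates, and summarizes the
#' converged replicates by the median, the 2.5th/97.5th percentile interval,
#' and the bias \eqn{(median - estimate)/estimate \times 100}. Non-converged
#' replicates are excluded and counted; more than 20% failures sets the
#' `warning` flag.
#'
#' @param dataset a `pk_dataset`.
#' @param fit the original `pk_fit` (provides both the resampling reference
#'   estimates and the refit starting values).
#' @param n number of bootstrap replicates (the reference analysis used
#'   1000).
#' @param seed RNG seed.
#' @param indices optional list of length `n` giving the resampled subject
#'   ids per replicate (bypasses random resampling; used for reproducibility
#'   tests).
#' @return An object of class `pk_bootstrap`: per-parameter `table`
#'   (estimate, median, ci_low, ci_high, bias_percent), `n_requested`,
#'   `n_converged`, `warning`, and the raw replicate estimates.
#' @export
bootstrap_model <- function(dataset, fit, n = 1000, seed = NULL,
                            indices = NULL) {
  stopifnot(inherits(fit, "pk_fit"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(dataset$ID)
  skel_tab <- fit_parameter_table(fit)
  pnames <- skel_tab$parameter[!skel_tab$fixed]
  draws <- matrix(NA_real_, n, length(pnames),
                  dimnames = list(NULL, pnames))
  for (r in seq_len(n)) {
    take <- if (is.null(indices)) sample(ids, length(ids), replace = TRUE)
    else indices[[r]]
    parts <- lapply(seq_along(take), function(j) {
      sub <- dataset[dataset$ID == take[j], , drop = FALSE]
      sub$ID <- j
      sub
    })
    boot_data <- do.call(rbind, parts)
    attr_keep <- class(dataset)
    class(boot_data) <- attr_keep
    f <- tryCatch(fit_popmodel(boot_data, start = fit$estimates,
                               fixed = fit$fixed),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      tab <- fit_parameter_table(f)
      draws[r, ] <- tab$estimate[match(pnames, tab$parameter)]
    }
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) stop("no bootstrap replicate converged")
  est <- skel_tab$estimate[match(pnames, skel_tab$parameter)]
  med <- apply(draws[ok, , drop = FALSE], 2, median)
  ci <- apply(draws[ok, , drop = FALSE], 2, quantile, probs = c(0.025, 0.975))
  structure(list(
    table = data.frame(parameter = pnames, estimate = est, median = med,
                       ci_low = ci[1, ], ci_high = ci[2, ],
                       bias_percent = bias_percent(est, med),
                       row.names = NULL),
    n_requested = n, n_converged = sum(ok),
    warning = (n - sum(ok)) / n > 0.2,
    draws = draws[ok, , drop = FALSE]), class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d replicates converged%s\n", x$n_converged,
              x$n_requested,
              if (x$warning) " (WARNING: >20% failures)" else ""))
  tab <- x$table
  tab$ci <- sprintf("(%.3g, %.3g)", tab$ci_low, tab$ci_high)
  print(tab[, c("parameter", "estimate", "median", "ci", "bias_percent")])
  invisible(x)
}
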