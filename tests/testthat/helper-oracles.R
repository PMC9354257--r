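# Independent oracles and small dataset builders shared across the suite.

# Plain-R closed-form profile (independent reimplementation of the compiled
# kernel, used by the quadrature oracle). cl, v may be vectors (eta grids).
r_profile_grid <- function(t, dose_time, dose_amt, cl, v, ka) {
  ke <- cl / v
  f <- numeric(length(cl))
  for (d in seq_along(dose_time)) {
    tau <- t - dose_time[d]
    if (tau < 0) next
    f <- f + dose_amt[d] * ka / (v * (ka - ke)) *
      (exp(-ke * tau) - exp(-ka * tau))
  }
  f * 1000
}

# Fixed-step classical RK4 integration of the two-state system
#   A' = -ka A ;  X' = ka A - ke X ;  C = X / V * 1000  [ng/ml]
# with bolus doses into A. Sampling at a dose time is pre-dose.
ode_profile <- function(cl, v, ka, dose_time, dose_amt, times, h = 0.01) {
  ke <- cl / v
  deriv <- function(s) c(-ka * s[1], ka * s[1] - ke * s[2])
  events <- sort(unique(c(dose_time, times)))
  s <- c(0, 0)
  t <- 0
  out <- numeric(length(times))
  for (ev in events) {
    if (ev > t) {
      nstep <- ceiling((ev - t) / h)
      hh <- (ev - t) / nstep
      for (i in seq_len(nstep)) {
        k1 <- deriv(s)
        k2 <- deriv(s + hh / 2 * k1)
        k3 <- deriv(s + hh / 2 * k2)
        k4 <- deriv(s + hh * k3)
        s <- s + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t <- ev
    }
    out[times == ev] <- s[2] / v * 1000
    s[1] <- s[1] + sum(dose_amt[dose_time == ev])
  }
  out
}

# Dense-grid quadrature of the exact marginal likelihood for one subject,
# reported on the NONMEM scale (-2 logLik minus n*log(2*pi)).
quad_ofv_subject <- function(y, tt, dt, da, tvcl, tvv, ka, om, sg,
                             npt = 241, span = 6) {
  stopifnot(all(om > 0))
  e1 <- seq(-span * om[1], span * om[1], length.out = npt)
  e2 <- seq(-span * om[2], span * om[2], length.out = npt)
  g1 <- rep(e1, times = npt)
  g2 <- rep(e2, each = npt)
  cl <- tvcl * exp(g1)
  v <- tvv * exp(g2)
  ll <- dnorm(g1, 0, om[1], log = TRUE) + dnorm(g2, 0, om[2], log = TRUE)
  for (j in seq_along(y)) {
    f <- r_profile_grid(tt[j], dt, da, cl, v, ka)
    g <- f^2 * sg[1]^2 + sg[2]^2
    ll <- ll - 0.5 * ((y[j] - f)^2 / g + log(2 * pi * g))
  }
  m <- max(ll)
  I <- sum(exp(ll - m)) * diff(e1[1:2]) * diff(e2[1:2])
  -2 * (m + log(I)) - length(y) * log(2 * pi)
}

# Quadrature oracle for a whole pk_dataset under a population_model.
quad_ofv <- function(dataset, model) {
  total <- 0
  for (id in unique(dataset$ID)) {
    sub <- dataset[dataset$ID == id, ]
    obs <- sub[sub$EVID == 0 & sub$MDV == 0, ]
    dos <- sub[sub$EVID == 1, ]
    wt <- sub$WT[1]
    total <- total + quad_ofv_subject(
      obs$DV, obs$TIME, dos$TIME, dos$AMT,
      typical_clearance(model, wt), typical_volume(model, wt), model$ka,
      c(model$omega_cl, model$omega_v), c(model$sigma_prop, model$sigma_add))
  }
  total
}

# Hand-rolled event table: one subject with given doses/observations.
make_subject_rows <- function(id, wt, dose_time, dose_amt, obs_time, dv) {
  rbind(
    data.frame(ID = id, TIME = obs_time, EVID = 0L, AMT = NA_real_, DV = dv,
               MDV = 0L, WT = wt),
    data.frame(ID = id, TIME = dose_time, EVID = 1L, AMT = dose_amt,
               DV = NA_real_, MDV = 1L, WT = wt))
}

make_dataset <- function(...) {
  df <- do.call(rbind, list(...))
  df <- df[order(df$ID, df$TIME, df$EVID), ]
  rownames(df) <- NULL
  as_pk_dataset(df)
}

# Simulate a toy subject's DVs from known parameters and build the dataset.
simulate_toy <- function(n_subjects, wt, model, obs_days, dose_per_kg = 0.3,
                         seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    w <- wt[(i - 1) %% length(wt) + 1]
    obs_t <- 24 * obs_days
    dose_t <- seq(0, max(obs_t) - 12, by = 12)
    amt <- w * dose_per_kg / 2
    p <- individual_params(model, w,
                           random_effects(rnorm(1, 0, model$omega_cl),
                                          rnorm(1, 0, model$omega_v)))
    f <- concentration_profile(p, data.frame(time = dose_t,
                                             amount = rep(amt, length(dose_t))),
                               obs_t)
    dv <- pmax(f * (1 + rnorm(length(f), 0, model$sigma_prop)) +
                 rnorm(length(f), 0, model$sigma_add), 0.05)
    rows[[i]] <- make_subject_rows(i, w, dose_t, rep(amt, length(dose_t)),
                                   obs_t, round(dv, 4))
  }
  do.call(make_dataset, rows)
}
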