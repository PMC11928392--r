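# shared fixtures, all generated in code

mono_samples <- function(A, lam, times) {
  data.frame(time_h = times, conc = A * exp(-lam * times))
}

biexp_samples <- function(A1, l1, A2, l2, times) {
  data.frame(time_h = times, conc = A1 * exp(-l1 * times) - A2 * exp(-l2 * times))
}

# brute-force Breslow partial likelihood for one covariate (oracle for Cox)
breslow_loglik <- function(beta, times, events, x) {
  o <- order(times)
  times <- times[o]; events <- events[o]; x <- x[o]
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

grid_search_beta <- function(times, events, x, lo = -8, hi = 8) {
  stats::optimize(function(b) breslow_loglik(b, times, events, x),
                  c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
}

# pairwise-enumeration U statistic (oracle for Mann-Whitney)
enumerate_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# product-limit survival by direct multiplication (oracle for Kaplan-Meier)
brute_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut)); s <- 1
  for (k in seq_along(ut)) {
    n_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# one small fitted cohort reused across tests (built once per test file)
small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      coh <- generate_cohort(cohort_config(n_patients = 6, seed = 11))
      fits <- fit_cohort_kinetics(coh$activity)
      doses <- compute_doses(fits, coh$activity)
      memo <<- list(cohort = coh, fits = fits, doses = doses)
    }
    memo
  }
})
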