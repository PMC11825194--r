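# Independent oracles, coded separately from the package's fitting routes.

# Brute-force product-limit estimator: explicit loop over unique event
# times, events processed before censorings at tied times.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    t <- ut[k]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ut, surv = surv)
}

# Efron-approximation Cox partial log-likelihood for counting-process data
# with a single covariate; reduces to the exact likelihood without ties.
cox_pll_efron <- function(beta, start, stop, event, x) {
  ll <- 0
  for (t in sort(unique(stop[event]))) {
    risk <- which(start < t & stop >= t)
    dead <- which(stop == t & event)
    d <- length(dead)
    rsum <- sum(exp(beta * x[risk]))
    dsum <- sum(exp(beta * x[dead]))
    ll <- ll + beta * sum(x[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(rsum - (l / d) * dsum)
    }
  }
  ll
}

# Brute-force maximiser of the single-covariate partial likelihood.
cox_mle_oracle <- function(start, stop, event, x) {
  stats::optimize(function(b) cox_pll_efron(b, start, stop, event, x),
                  interval = c(-8, 8), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Mean of a normal distribution truncated to [lo, hi] (for the generator's
# weight/age marginal checks).
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}
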