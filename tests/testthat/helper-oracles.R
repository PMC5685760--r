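# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (and the survival package where the point is
# to check it): brute-force enumeration and hand-written likelihoods.

# Breslow partial log-likelihood for a single covariate, written from
# the definition: sum over event times of [x_i beta - log sum_{at risk} exp(x_j beta)]
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# grid maximization of the Breslow partial likelihood
grid_cox_beta <- function(time, event, x, lo = -3, hi = 3, tol = 1e-5) {
  stats::optimize(function(b) breslow_loglik(b, time, event, x),
                  c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

# exhaustive pair-counting AUC
pair_count_auc <- function(scores, event) {
  cases <- scores[event == 1]; ctrls <- scores[event == 0]
  tot <- 0
  for (s in cases) tot <- tot + sum(s > ctrls) + 0.5 * sum(s == ctrls)
  tot / (length(cases) * length(ctrls))
}

# hand product-limit estimator
hand_km <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (tj in ut[ut <= at]) {
    d <- sum(time == tj & event == 1)
    y <- sum(time >= tj)
    s <- s * (1 - d / y)
  }
  s
}

# brute-force OLS by grid search over (intercept, slope)
grid_ols_slope <- function(x, y) {
  obj <- function(p) sum((y - p[1] - p[2] * x)^2)
  stats::optim(c(mean(y), 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))$par[2]
}

# small uncensored/censored toy cohort used in several places
toy_surv <- function() {
  list(time = c(1, 1.5, 2, 3), event = c(1, 0, 1, 0))
}

# a quick simulated survival dataset with a prognostic marker
sim_marker_cohort <- function(n, beta = 0.8, seed = 1, cens_rate = 0.02) {
  set.seed(seed)
  x <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.02 * exp(beta * x))
  cc <- stats::rexp(n, cens_rate)
  list(time = pmin(tt, cc), event = as.integer(tt <= cc), x = x)
}
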