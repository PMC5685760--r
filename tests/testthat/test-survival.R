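test_that("Kaplan-Meier matches hand product-limit computation", {
  # 4 events, no censoring: S drops by 1/4 at each
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # all censored: S stays 1
  kmc <- km_estimate(1:4, rep(0, 4))
  sfn <- attr(kmc, "surv_fn")
  expect_equal(sfn(10), 1)
  # events at 1 and 2, censored at 1.5 and 3: S(2) = (3/4)(1/2) = 0.375
  d <- toy_surv()
  km2 <- km_estimate(d$time, d$event)
  sfn2 <- attr(km2, "surv_fn")
  expect_equal(sfn2(2), 0.375)
  expect_equal(sfn2(2), hand_km(d$time, d$event, 2))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("log-rank matches the hand O-E tabulation", {
  # A events {1,3}, B events {2,4}: O_A = 2, E_A = 4/3, Var = 0.7222
  lr <- logrank_test(c(1, 3, 2, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$chi2, (2 - 4 / 3)^2 / (1 / 4 + 2 / 9 + 1 / 4),
               tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # identical groups -> zero statistic
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "B", "B", "A"))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)), "two")
})

test_that("log-rank chi2 grows with n for separated groups", {
  mk <- function(n) {
    time <- c(seq_len(n), seq_len(n) + n)
    logrank_test(time, rep(1, 2 * n), rep(c("late", "early"), each = n))$chi2
  }
  expect_gt(mk(40), mk(10))
})

test_that("Cox fit matches a brute-force partial-likelihood grid search", {
  d <- sim_marker_cohort(60, beta = 0.8, seed = 2)
  x <- as.numeric(d$x > 0)   # single binary covariate, tie-free times
  fit <- cox_fit(d$time, d$event, data.frame(x = x), ties = "breslow")
  expect_equal(unname(fit$beta),
               grid_cox_beta(d$time, d$event, x), tolerance = 1e-4)
})

test_that("log-rank equals the Cox score test at beta = 0 on tie-free data", {
  d <- sim_marker_cohort(80, beta = 0.5, seed = 3)
  g <- as.numeric(d$x > 0)
  lr <- logrank_test(d$time, d$event, g)
  sc <- survival::coxph(survival::Surv(d$time, d$event) ~ g,
                        ties = "breslow")
  expect_equal(lr$chi2, unname(sc$score), tolerance = 1e-6)
})

test_that("null covariates give HR near 1; separation is an error", {
  d <- sim_marker_cohort(1500, beta = 0, seed = 4)
  fit <- cox_fit(d$time, d$event, data.frame(x = d$x))
  expect_equal(unname(fit$hr), 1, tolerance = 0.15)
  expect_error(cox_fit(c(1, 2), c(1, 1), data.frame(x = c(1, 0))),
               "separation|monotone")
  d2 <- sim_marker_cohort(50, beta = 0.4, seed = 5)
  expect_error(cox_fit(d2$time, d2$event,
                       data.frame(a = d2$x, b = 2 * d2$x)),
               "rank")
})

test_that("forward stepwise keeps the real signal and drops noise", {
  set.seed(7)
  n <- 400
  x <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  tt <- rexp(n, 0.02 * exp(1.0 * x$signal))
  cc <- rexp(n, 0.015)
  sw <- forward_stepwise_cox(pmin(tt, cc), as.integer(tt <= cc), x, names(x))
  expect_equal(sw$selected, "signal")
  expect_true(all(c("step", "variable", "lr_stat", "p", "entered") %in%
                    names(sw$trace)))
})

test_that("a duplicated predictor never enters after the original", {
  d <- sim_marker_cohort(200, beta = 0.9, seed = 8)
  x <- data.frame(m = d$x, m_copy = d$x)
  sw <- forward_stepwise_cox(d$time, d$event, x, names(x))
  expect_equal(sw$selected, "m")
})

test_that("all-null candidates usually select the empty model", {
  empty <- 0
  for (r in 1:30) {
    d <- sim_marker_cohort(150, beta = 0, seed = 100 + r)
    x <- data.frame(a = d$x, b = rnorm(150))
    sw <- forward_stepwise_cox(d$time, d$event, x, names(x))
    empty <- empty + (length(sw$selected) == 0)
  }
  expect_gt(empty / 30, 0.75)   # ~(1 - alpha)^2 with alpha = 0.05
})

test_that("the cutpoint scan equals an exhaustive survdiff scan", {
  d <- sim_marker_cohort(90, beta = 0.7, seed = 10)
  co <- contal_oquigley(d$time, d$event, d$x)
  oracle <- vapply(co$scan$cutpoint, function(cc) {
    g <- d$x > cc
    sqrt(survival::survdiff(survival::Surv(d$time, d$event) ~ g)$chisq)
  }, 0)
  expect_equal(abs(co$scan$z), oracle, tolerance = 1e-10)
  expect_equal(co$max_stat, max(oracle), tolerance = 1e-10)
  k_best <- which.max(oracle)
  expect_equal(co$cutoff, co$scan$cutpoint[k_best])
  expect_gt(co$cutoff, min(d$x))
  expect_lt(co$cutoff, max(d$x))
})

test_that("cutpoint edge cases behave as specified", {
  d <- sim_marker_cohort(60, beta = 0.5, seed = 11)
  expect_error(contal_oquigley(d$time, d$event, rep(1, 60)), "constant")
  # two distinct marker values: the single admissible cutoff is returned
  m2 <- rep(c(0, 1), each = 30)
  co2 <- contal_oquigley(d$time, d$event, m2)
  expect_equal(co2$cutoff, 0.5)
  expect_equal(nrow(co2$scan), 1L)
  # permutation p is deterministic given the seed
  pa <- contal_oquigley(d$time, d$event, d$x, p_method = "permutation",
                        B = 100, seed = 5)$p_corrected
  pb <- contal_oquigley(d$time, d$event, d$x, p_method = "permutation",
                        B = 100, seed = 5)$p_corrected
  expect_identical(pa, pb)
})

test_that("sensitivity/specificity at the cutoff classify the binary event", {
  d <- sim_marker_cohort(80, beta = 1.0, seed = 12)
  co <- contal_oquigley(d$time, d$event, d$x)
  high <- d$x > co$cutoff
  expect_equal(co$sensitivity, mean(high[d$event == 1]))
  expect_equal(co$specificity, mean(!high[d$event == 0]))
  expect_equal(co$auc_binary, (co$sensitivity + co$specificity) / 2)
})

test_that("risk weights follow the rounded coefficient-ratio rule", {
  fake_fit <- structure(list(beta = c(a = 0.9, b = 0.9, c = 0.9)),
                        class = "cox_fit")
  expect_equal(unname(risk_weights(fake_fit, "b")), c(1, 1, 1))
  fake2 <- structure(list(beta = c(a = 1.31, b = 1.0, c = 0.24)),
                     class = "cox_fit")
  expect_equal(unname(risk_weights(fake2, "b")), c(1.30, 1.00, 0.25))
  fake0 <- structure(list(beta = c(a = 1, b = 0)), class = "cox_fit")
  expect_error(risk_weights(fake0, "b"), "zero")
})

test_that("weights recovered from simulation sit within one rounding step", {
  d <- simulate_cohort(cohort_spec(
    n_patients = 4000,
    beta = c(nodal_suvmax = 0.65, wbmtv = 0.50, hf = 0.125), seed = 31))
  z <- as.data.frame(attr(d, "z"))
  fit <- cox_fit(d$time_months, d$event, z)
  w <- risk_weights(fit, "wbmtv")
  expect_equal(unname(w["nodal_suvmax"]), 1.3, tolerance = 0.06)
  expect_equal(unname(w["hf"]), 0.25, tolerance = 0.3)
})

test_that("risk grouping recovers ordered clusters and degenerates cleanly", {
  set.seed(13)
  n <- 150
  cluster <- rep(1:3, each = n / 3)
  scores <- c(rnorm(n / 3, 0, 0.1), rnorm(n / 3, 2, 0.1), rnorm(n / 3, 4, 0.1))
  tt <- rexp(n, 0.01 * exp(cluster - 1))
  cc <- rep(200, n)
  time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  g <- assign_risk_groups(scores, time, ev, n_groups = 3)
  expect_equal(length(attr(g, "cutoffs")), 2L)
  expect_gt(mean(g[cluster == 3] == 3), 0.9)
  expect_gt(mean(g[cluster == 1] == 1), 0.9)
  expect_true(attr(g, "logrank")$p < 0.001)
  # n_groups = 2 reduces to the single Contal-O'Quigley split
  g2 <- assign_risk_groups(scores, time, ev, n_groups = 2)
  co <- contal_oquigley(time, ev, scores)
  expect_equal(attr(g2, "cutoffs"), co$cutoff)
  expect_error(assign_risk_groups(rep(1, n), time, ev), "constant")
})
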