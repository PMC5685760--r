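test_that("roc_auc equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(21)
  for (r in 1:10) {
    n <- sample(20:150, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    ev <- rbinom(n, 1, 0.4)
    if (sum(ev) == 0 || sum(ev) == n) next
    expect_identical(roc_auc(sc, ev)$auc, pair_count_auc(sc, ev))
  }
  # null scores at large n sit near 0.5
  set.seed(22)
  expect_equal(roc_auc(rnorm(4000), rbinom(4000, 1, 0.3))$auc, 0.5,
               tolerance = 0.05)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("roc_auc cross-checks against pROC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- rnorm(100); ev <- rbinom(100, 1, 0.4)
  r <- suppressMessages(pROC::roc(ev, sc, direction = "<"))
  expect_equal(roc_auc(sc, ev)$auc, as.numeric(pROC::auc(r)),
               tolerance = 1e-10)
})

test_that("DeLong comparison: self gives p = 1, order does not matter", {
  set.seed(24)
  sc <- rnorm(80); ev <- rbinom(80, 1, 0.4)
  self <- compare_auc_paired(sc, sc, ev)
  expect_equal(self$p, 1)
  sc2 <- sc + rnorm(80, 0, 2)
  ab <- compare_auc_paired(sc, sc2, ev)
  ba <- compare_auc_paired(sc2, sc, ev)
  expect_equal(ab$p, ba$p)
})

test_that("DeLong p matches pROC and rejects informative vs noise", {
  skip_if_not_installed("pROC")
  set.seed(25)
  n <- 200
  ev <- rbinom(n, 1, 0.4)
  good <- ev + rnorm(n, 0, 0.8)
  noise <- rnorm(n)
  ours <- compare_auc_paired(good, noise, ev)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(ev, good, direction = "<", quiet = TRUE),
    pROC::roc(ev, noise, direction = "<", quiet = TRUE),
    method = "delong"))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  # power check over replicates
  rej <- 0
  for (r in 1:25) {
    set.seed(300 + r)
    ev <- rbinom(n, 1, 0.4)
    good <- ev + rnorm(n, 0, 0.8)
    rej <- rej + (compare_auc_paired(good, rnorm(n), ev)$p < 0.05)
  }
  expect_gt(rej / 25, 0.8)
})

test_that("IDI matches its hand-computed toy and the slope identity", {
  ev <- c(1, 1, 0, 0)
  out <- idi(p_old = c(0.6, 0.8, 0.3, 0.1), p_new = c(0.7, 0.9, 0.2, 0.1),
             event = ev)
  expect_equal(out$idi, 0.15)
  # p_new = p_old -> 0
  expect_equal(idi(c(.2, .4, .6), c(.2, .4, .6), c(1, 0, 1))$idi, 0)
  # identity: IDI = (new slope) - (old slope)
  set.seed(26)
  po <- runif(50); pn <- runif(50); ev <- rbinom(50, 1, 0.5)
  slope <- function(p) mean(p[ev == 1]) - mean(p[ev == 0])
  expect_equal(idi(po, pn, ev)$idi, slope(pn) - slope(po), tolerance = 1e-12)
})

test_that("IDI type-I error is near nominal for a null added covariate", {
  rej <- 0; reps <- 100
  for (r in seq_len(reps)) {
    set.seed(400 + r)
    n <- 500
    x <- rnorm(n); junk <- rnorm(n)
    ev <- rbinom(n, 1, plogis(-0.5 + x))
    po <- fitted(glm(ev ~ x, family = binomial()))
    pn <- fitted(glm(ev ~ x + junk, family = binomial()))
    rej <- rej + (idi(po, pn, ev)$p < 0.05)
  }
  expect_lt(rej / reps, 0.15)
})

test_that("NRI counts reclassification moves as defined", {
  out <- nri(p_old = c(0.2, 0.6, 0.4), p_new = c(0.3, 0.5, 0.3),
             event = c(1, 1, 0))
  expect_equal(out$nri, 1.0)
  expect_equal(nri(c(.2, .4), c(.2, .4), c(1, 0))$nri, 0)
  # all events up, all nonevents down: maximum 2
  expect_equal(nri(c(.2, .2, .8, .8), c(.4, .4, .6, .6),
                   c(1, 1, 0, 0))$nri, 2)
  # categorical variant: moves only across category bounds
  cat_out <- nri(c(0.1, 0.45, 0.3), c(0.12, 0.55, 0.2), c(1, 1, 0),
                 categories = 0.5)
  expect_equal(cat_out$p_up_event, 0.5)
  expect_equal(cat_out$p_down_nonevent, 0)
})

test_that("time-dependent AUC reduces exactly to binary AUC when uncensored", {
  expect_equal(td_roc_auc(c(3, 2, 1, 0), 1:4, rep(1, 4), 2.5), 1.0)
  set.seed(27)
  n <- 120
  sc <- rnorm(n); tt <- rexp(n, 0.05)
  for (t in quantile(tt, c(0.3, 0.6))) {
    expect_identical(td_roc_auc(sc, tt, rep(1, n), t),
                     roc_auc(sc, as.numeric(tt <= t))$auc)
  }
  expect_error(td_roc_auc(sc, tt, rep(1, n), max(tt) + 1), "at risk")
  expect_error(td_roc_auc(sc, tt, rep(1, n), min(tt) / 2), "events")
})

test_that("censored AUC(t) stays close to the uncensored truth", {
  set.seed(28)
  n <- 2500
  x <- rnorm(n)
  tt <- rexp(n, 0.03 * exp(0.9 * x))
  truth <- td_roc_auc(x, tt, rep(1, n), 20)
  cc <- runif(n, 0, 60)           # heavy random censoring
  est <- td_roc_auc(x, pmin(tt, cc), as.integer(tt <= cc), 20)
  expect_equal(est, truth, tolerance = 0.03)
})

test_that("iAUC: constant AUC(t) passes through; perfect marker gives 1", {
  set.seed(29)
  n <- 100
  tt <- rexp(n, 0.05)
  # perfectly time-ordered marker, no censoring
  expect_equal(as.numeric(iauc(-tt, tt, rep(1, n))), 1.0)
  # weights normalize: if every AUC(t) equals a, iauc = a
  sc <- rnorm(n)
  grid <- quantile(tt, c(0.2, 0.4, 0.6), names = FALSE)
  a <- 0.637
  fake <- iauc(sc, tt, rep(1, n), t_grid = grid)
  curve <- attr(fake, "curve")
  expect_equal(sum(curve$weight), 1, tolerance = 1e-12)
  expect_equal(sum(curve$weight * a), a, tolerance = 1e-12)
})

test_that("iAUC is invariant to strictly monotone score transforms", {
  set.seed(30)
  n <- 150
  x <- rnorm(n)
  tt <- rexp(n, 0.03 * exp(0.8 * x))
  cc <- runif(n, 0, 80)
  time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  i1 <- as.numeric(iauc(x, time, ev))
  i2 <- as.numeric(iauc(exp(2 * x) + 5, time, ev))
  expect_identical(i1, i2)
  # null marker sits near 0.5
  i0 <- mean(vapply(1:10, function(r) {
    set.seed(500 + r)
    as.numeric(iauc(rnorm(n), time, ev))
  }, 0))
  expect_equal(i0, 0.5, tolerance = 0.05)
})

test_that("iAUC bootstrap CI: self-difference collapses, seeds reproduce", {
  set.seed(31)
  n <- 120
  x <- rnorm(n)
  tt <- rexp(n, 0.03 * exp(0.7 * x))
  cc <- runif(n, 0, 80)
  time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  self <- iauc_difference_ci(x, x, time, ev, B = 100, seed = 2)
  expect_equal(self$diff, 0)
  expect_equal(self$ci95, c(0, 0))
  y <- rnorm(n)
  a <- iauc_difference_ci(x, y, time, ev, B = 100, seed = 3)
  b <- iauc_difference_ci(x, y, time, ev, B = 100, seed = 3)
  expect_identical(a$ci95, b$ci95)
  expect_error(iauc_difference_ci(x, x, time, ev, B = 50), "B must")
})

test_that("Spearman correlations match hand rank computation", {
  tab <- correlate_features(data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3)))
  expect_equal(tab$rho, 0.6)       # 1 - 6*4/(4*15)
  mono <- correlate_features(data.frame(x = 1:20, y = (1:20)^3))
  expect_equal(mono$rho, 1)
  expect_error(correlate_features(data.frame(x = rep(1, 5), y = 1:5)),
               "constant")
})

test_that("group comparison table reproduces t and chi-square behavior", {
  # identical groups -> t = 0, p = 1
  f <- data.frame(a = rep(c(1, 2, 3), 2))
  g <- rep(c(0, 1), each = 3)
  tab <- compare_groups(f, g)
  expect_equal(tab$statistic, 0)
  expect_equal(tab$p, 1)
  # strongly separated means: t ~ 38.7, p < 1e-10
  set.seed(32)
  x0 <- rnorm(30); x0 <- (x0 - mean(x0)) / sd(x0) * 0.1
  x1 <- rnorm(30); x1 <- (x1 - mean(x1)) / sd(x1) * 0.1 + 1
  tab2 <- compare_groups(data.frame(m = c(x0, x1)), rep(0:1, each = 30))
  expect_equal(abs(tab2$statistic), 1 / (0.1 * sqrt(2 / 30)),
               tolerance = 1e-6)
  expect_lt(tab2$p, 1e-10)
  # balanced 2x2 table -> chi2 = 0
  tab3 <- compare_groups(
    data.frame(k = rep(c("a", "b", "a", "b"), 10)),
    rep(c(0, 0, 1, 1), 10))
  expect_equal(tab3$statistic, 0)
})
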