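#' ROC area under the curve with standard error
#'
#' AUC as the Mann-Whitney U statistic divided by n1*n0 (ties count
#' one half); SE by the Hanley-McNeil formula.
#'
#' @param scores risk scores (higher = more event-like).
#' @param event binary outcome, 0/1, both classes present.
#' @return list with `auc`, `se`, `n1`, `n0`.
#' @export
roc_auc <- function(scores, event) {
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  n1 <- sum(event == 1); n0 <- sum(event == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[event == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  list(auc = auc, se = se, n1 = n1, n0 = n0)
}

# DeLong placement values: for each case, the fraction of controls it
# beats (ties half); and symmetrically for controls
.delong_placements <- function(scores, event) {
  cases <- scores[event == 1]; ctrls <- scores[event == 0]
  v10 <- vapply(cases, function(s)
    (sum(s > ctrls) + 0.5 * sum(s == ctrls)) / length(ctrls), 0)
  v01 <- vapply(ctrls, function(s)
    (sum(cases > s) + 0.5 * sum(cases == s)) / length(cases), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong paired test for two correlated AUCs
#'
#' Two-sided test of equal AUC for two risk models evaluated on the same
#' subjects, using the DeLong placement-value covariance.
#'
#' @param scores_a,scores_b scores of the two models (same subjects).
#' @param event binary outcome, 0/1.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, event) {
  if (length(scores_a) != length(scores_b))
    stop("models must score the same subjects")
  pa <- .delong_placements(scores_a, event)
  pb <- .delong_placements(scores_b, event)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  d <- pa$auc - pb$auc
  v <- stats::var(pa$v10 - pb$v10) / n1 + stats::var(pa$v01 - pb$v01) / n0
  if (v <= 0) {
    if (abs(d) < 1e-12) return(list(auc_a = pa$auc, auc_b = pb$auc,
                                    z = 0, p = 1))
    stop("degenerate DeLong variance with unequal AUCs")
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Integrated discrimination improvement
#'
#' IDI = (mean increase in predicted probability among events) minus
#' (mean increase among nonevents); equivalently, the change in the
#' discrimination slope between the old and new model. z from the
#' two-independent-samples SE of the probability differences.
#'
#' @param p_old,p_new predicted event probabilities in \[0, 1\].
#' @param event binary outcome, 0/1.
#' @return list with `idi`, `z`, `p`.
#' @export
idi <- function(p_old, p_new, event) {
  if (any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1))
    stop("probabilities must be in [0, 1]")
  e1 <- event == 1; e0 <- event == 0
  if (!any(e1) || !any(e0)) stop("both classes must be present")
  d <- p_new - p_old
  est <- mean(d[e1]) - mean(d[e0])
  se <- sqrt(stats::var(d[e1]) / sum(e1) + stats::var(d[e0]) / sum(e0))
  z <- if (is.na(se) || se == 0) { if (abs(est) < 1e-12) 0 else Inf }
       else est / se
  list(idi = est, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Net reclassification improvement
#'
#' Category-free by default: any increase in predicted probability is an
#' upward move. NRI = \[P(up|event) - P(down|event)\] +
#' \[P(down|nonevent) - P(up|nonevent)\]; z from the usual
#' proportion-based SE. With `categories`, moves are counted across the
#' monotone category bounds instead.
#'
#' @param p_old,p_new predicted probabilities.
#' @param event binary outcome, 0/1.
#' @param categories optional increasing interior cut points defining
#'   risk categories.
#' @return list with `nri`, `z`, `p`, and the four move proportions.
#' @export
nri <- function(p_old, p_new, event, categories = NULL) {
  if (any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1))
    stop("probabilities must be in [0, 1]")
  e1 <- event == 1; e0 <- event == 0
  if (!any(e1) || !any(e0)) stop("both classes must be present")
  if (!is.null(categories)) {
    co <- findInterval(p_old, sort(categories))
    cn <- findInterval(p_new, sort(categories))
    up <- cn > co; down <- cn < co
  } else {
    up <- p_new > p_old; down <- p_new < p_old
  }
  pue <- mean(up[e1]);  pde <- mean(down[e1])
  pun <- mean(up[e0]);  pdn <- mean(down[e0])
  est <- (pue - pde) + (pdn - pun)
  se <- sqrt((pue + pde) / sum(e1) + (pun + pdn) / sum(e0))
  z <- if (is.na(se) || se == 0) { if (abs(est) < 1e-12) 0 else Inf }
       else est / se
  list(nri = est, z = z, p = 2 * stats::pnorm(-abs(z)),
       p_up_event = pue, p_down_event = pde,
       p_up_nonevent = pun, p_down_nonevent = pdn)
}

# Kaplan-Meier of the censoring distribution as a function with a
# left-limit option: G(t-) = P(C >= t)
.censor_km_fn <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  steps <- sf$time[sf$n.event > 0]
  surv <- sf$surv[sf$n.event > 0]
  function(t, left = FALSE) {
    if (!length(steps)) return(rep(1, length(t)))
    idx <- findInterval(t, steps, left.open = left)
    c(1, surv)[idx + 1L]
  }
}

#' Cumulative/dynamic time-dependent AUC
#'
#' AUC(t) with cases = subjects with an event by t and controls =
#' subjects still event-free beyond t; censoring before t is handled by
#' inverse-probability-of-censoring weights from the Kaplan-Meier
#' estimate of the censoring distribution (cases weighted by
#' 1/G(t_i-)). With no censoring this reduces exactly to [roc_auc()] on
#' the indicator of time <= t.
#'
#' @param scores risk scores.
#' @param time,event survival data.
#' @param t evaluation time; some events by t and some subjects beyond t
#'   are required.
#' @return AUC(t), scalar.
#' @export
td_roc_auc <- function(scores, time, event, t) {
  .check_surv(time, event)
  .td_auc_one(scores, time, event, t,
              G = .censor_km_fn(time, event),
              si = match(scores, sort(unique(scores))),
              nu = length(unique(scores)))
}

# one AUC(t) with the censoring KM and score indexing precomputed, so a
# grid of evaluation times shares the setup
.td_auc_one <- function(scores, time, event, t, G, si, nu) {
  case <- time <= t & event == 1
  ctrl <- time > t
  if (!any(case)) stop("no events by t = ", t)
  if (!any(ctrl)) stop("no subjects at risk beyond t = ", t)
  w <- 1 / G(time[case], left = TRUE)
  # controls share the constant weight 1/G(t), which cancels in the ratio
  cnt_ctrl <- tabulate(si[ctrl], nbins = nu)
  less <- c(0, cumsum(cnt_ctrl))[si[case]]
  eq <- cnt_ctrl[si[case]]
  sum(w * (less + eq / 2)) / (sum(w) * sum(ctrl))
}

#' Integrated time-dependent AUC
#'
#' Weighted average of the cumulative/dynamic AUC(t) over event times up
#' to `t_max`, with weights proportional to 2 f(t) S(t) from the
#' Kaplan-Meier estimate of the event-time distribution (the
#' survival-weighted concordance average), normalized to 1 over the
#' usable grid points.
#'
#' @param scores risk scores.
#' @param time,event survival data.
#' @param t_grid evaluation times; default = unique event times up to
#'   `t_max`, thinned to at most `max_grid` quantile-spaced points.
#' @param t_max upper end of the evaluation window; default = 90th
#'   percentile of observed follow-up.
#' @param max_grid cap on the number of default grid points (the
#'   survival-weighted average changes negligibly beyond ~50 points
#'   while the cost grows linearly).
#' @return iAUC, scalar; the per-time AUC(t) and weights are attached as
#'   attribute `curve`.
#' @export
iauc <- function(scores, time, event, t_grid = NULL, t_max = NULL,
                 max_grid = 50L) {
  .check_surv(time, event)
  if (is.null(t_max)) t_max <- stats::quantile(time, 0.9, names = FALSE)
  if (is.null(t_grid)) {
    t_grid <- sort(unique(time[event == 1 & time <= t_max]))
    if (length(t_grid) > max_grid)
      t_grid <- unique(stats::quantile(t_grid,
        probs = seq(0, 1, length.out = max_grid), type = 1, names = FALSE))
  }
  t_grid <- t_grid[t_grid <= t_max]
  if (length(t_grid) < 2L) stop("need >= 2 usable grid points")
  km <- km_estimate(time, event)
  S <- attr(km, "surv_fn")
  Sm <- stats::stepfun(km$time, c(1, km$survival), right = TRUE)  # S(t-)
  G <- .censor_km_fn(time, event)
  u <- sort(unique(scores))
  si <- match(scores, u)
  auc_t <- rep(NA_real_, length(t_grid))
  for (i in seq_along(t_grid)) {
    auc_t[i] <- tryCatch(
      .td_auc_one(scores, time, event, t_grid[i], G, si, length(u)),
      error = function(e) NA_real_)
  }
  # event-time mass per grid interval (t_{j-1}, t_j]; on the full grid of
  # event times this is exactly the KM jump at t_j
  dF <- c(1, S(utils::head(t_grid, -1))) - S(t_grid)
  w <- 2 * dF * S(t_grid)
  ok <- !is.na(auc_t) & w > 0
  if (!any(ok)) stop("no usable grid points for iAUC")
  w <- w[ok] / sum(w[ok])
  out <- sum(w * auc_t[ok])
  attr(out, "curve") <- data.frame(t = t_grid[ok], auc_t = auc_t[ok],
                                   weight = w)
  out
}

#' Bootstrap CI for a difference of integrated AUCs
#'
#' Patient-level bootstrap of iauc(model a) - iauc(model b) on the same
#' subjects; percentile 95% CI. Degenerate resamples (no events, or an
#' unusable grid) are skipped and counted; more than 10% skipped is an
#' error. Deterministic given `seed`.
#'
#' @param scores_a,scores_b scores of the two models.
#' @param time,event survival data.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param t_max evaluation window end, fixed from the original data by
#'   default so resamples are integrated over a common window.
#' @return list with `diff`, `ci95`, `iauc_a`, `iauc_b`, `n_skipped`.
#' @export
iauc_difference_ci <- function(scores_a, scores_b, time, event,
                               B = 1000, seed = 1L, t_max = NULL) {
  if (B < 100) stop("B must be >= 100")
  if (length(scores_a) != length(scores_b))
    stop("models must score the same subjects")
  if (is.null(t_max)) t_max <- stats::quantile(time, 0.9, names = FALSE)
  ia <- iauc(scores_a, time, event, t_max = t_max)
  ib <- iauc(scores_b, time, event, t_max = t_max)
  set.seed(seed)
  n <- length(time)
  boots <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    boots[b, ] <- tryCatch(
      c(iauc(scores_a[idx], time[idx], event[idx], t_max = t_max),
        iauc(scores_b[idx], time[idx], event[idx], t_max = t_max)),
      error = function(e) c(NA_real_, NA_real_))
  }
  ok <- stats::complete.cases(boots)
  if (mean(!ok) > 0.1)
    stop("more than 10% of bootstrap resamples were degenerate")
  d <- boots[ok, 1] - boots[ok, 2]
  list(diff = as.numeric(ia) - as.numeric(ib),
       ci95 = unname(stats::quantile(d, c(0.025, 0.975))),
       iauc_a = as.numeric(ia), iauc_b = as.numeric(ib),
       n_skipped = sum(!ok))
}

#' Spearman correlations for chosen feature pairs
#'
#' Rank correlation with midrank ties; p-value via the t approximation.
#'
#' @param features data.frame of features.
#' @param pairs list of length-2 character vectors (or a 2-column
#'   matrix) naming the pairs; default = all pairs of columns.
#' @return data.frame with `feature_a`, `feature_b`, `rho`, `p`.
#' @export
correlate_features <- function(features, pairs = NULL) {
  if (is.null(pairs)) {
    nm <- names(features)
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  }
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  rows <- lapply(pairs, function(pr) {
    x <- features[[pr[1]]]; y <- features[[pr[2]]]
    if (length(x) < 3L) stop("need >= 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant feature in pair ", pr[1], "-", pr[2],
           ": Spearman correlation undefined")
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(feature_a = pr[1], feature_b = pr[2],
               rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Two-group comparison table (continuous and categorical features)
#'
#' Continuous features are compared with a two-sample t-test (pooled
#' variance by default, i.e. Student's t; Welch available) and reported
#' as mean +/- SD per group; categorical (factor/character) features with
#' a Pearson chi-square test without continuity correction.
#'
#' @param features data.frame.
#' @param group binary grouping vector.
#' @param var_equal pooled-variance t-test if TRUE (default).
#' @return data.frame with one row per feature: group summaries, test
#'   name, statistic and p-value (NA with a flag for degenerate
#'   variance).
#' @export
compare_groups <- function(features, group, var_equal = TRUE) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("need exactly two groups")
  lv <- levels(g)
  rows <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    if (is.numeric(x)) {
      m <- tapply(x, g, mean); s <- tapply(x, g, stats::sd)
      sm <- sprintf("%.3g ± %.3g", m, s)
      if (all(s == 0, na.rm = TRUE)) {
        return(data.frame(feature = nm, group1 = sm[1], group2 = sm[2],
                          test = "t", statistic = NA_real_, p = NA_real_,
                          degenerate = TRUE))
      }
      tt <- stats::t.test(x ~ g, var.equal = var_equal)
      data.frame(feature = nm, group1 = sm[1], group2 = sm[2], test = "t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 degenerate = FALSE)
    } else {
      tab <- table(x, g)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      cnt <- apply(tab, 2, function(cl)
        paste(sprintf("%s:%d", rownames(tab), cl), collapse = " "))
      data.frame(feature = nm, group1 = cnt[1], group2 = cnt[2],
                 test = "chisq", statistic = unname(ct$statistic),
                 p = ct$p.value, degenerate = any(ct$expected <= 0))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  rownames(out) <- NULL
  out
}

#' Fit named risk models over predictor sets
#'
#' For the binary-outcome ROC/IDI/NRI block, each model is a logistic
#' regression of the event indicator on its predictors (scores =
#' fitted probabilities); for the time-dependent block, a Cox model
#' (scores = linear predictor).
#'
#' @param data data.frame with `time_months`, `event` and the
#'   predictors.
#' @param model_sets named list, each element a character vector of
#'   predictor columns.
#' @param type `"logistic"` or `"cox"`.
#' @return named list of lists: `name`, `predictors`, `scores`.
#' @export
fit_risk_models <- function(data, model_sets,
                            type = c("logistic", "cox")) {
  type <- match.arg(type)
  lapply(stats::setNames(names(model_sets), names(model_sets)), function(nm) {
    preds <- model_sets[[nm]]
    x <- data[, preds, drop = FALSE]
    scores <- if (type == "logistic") {
      fml <- stats::as.formula(paste("event ~",
        paste(sprintf("`%s`", preds), collapse = " + ")))
      unname(stats::fitted(stats::glm(fml, data = data, family = stats::binomial())))
    } else {
      fit <- cox_fit(data$time_months, data$event, x)
      unname(stats::predict(fit$model, type = "lp"))
    }
    list(name = nm, predictors = preds, scores = scores)
  })
}

#' Discrimination report across nested risk models
#'
#' The machine twin of a model-comparison table: per model, the binary
#' ROC AUC (logistic predicted probabilities) with SE and 95% CI and the
#' integrated time-dependent AUC (Cox linear predictor); against the
#' reference model, the DeLong p (P1), IDI p (P2), NRI p (P3) and the
#' bootstrap 95% CI of the iAUC difference.
#'
#' @param data data.frame with `time_months`, `event`, predictors.
#' @param model_sets named list of predictor sets.
#' @param reference name of the reference model (compared against).
#' @param B bootstrap resamples for the iAUC difference CI.
#' @param seed seed for the bootstrap.
#' @return data.frame, one row per model.
#' @export
discrimination_report <- function(data, model_sets, reference,
                                  B = 500, seed = 1L) {
  if (!reference %in% names(model_sets)) stop("unknown reference model")
  logit <- fit_risk_models(data, model_sets, "logistic")
  coxm <- fit_risk_models(data, model_sets, "cox")
  ref_p <- logit[[reference]]$scores
  ref_lp <- coxm[[reference]]$scores
  rows <- lapply(names(model_sets), function(nm) {
    ra <- roc_auc(logit[[nm]]$scores, data$event)
    row <- data.frame(model = nm,
                      auc = ra$auc, auc_se = ra$se,
                      auc_lo = max(0, ra$auc - 1.96 * ra$se),
                      auc_hi = min(1, ra$auc + 1.96 * ra$se),
                      p_auc = NA_real_, idi = NA_real_, p_idi = NA_real_,
                      nri = NA_real_, p_nri = NA_real_,
                      iauc = as.numeric(iauc(coxm[[nm]]$scores,
                                             data$time_months, data$event)),
                      iauc_diff = NA_real_,
                      iauc_diff_lo = NA_real_, iauc_diff_hi = NA_real_)
    if (nm != reference) {
      row$p_auc <- compare_auc_paired(logit[[nm]]$scores, ref_p,
                                      data$event)$p
      ii <- idi(ref_p, logit[[nm]]$scores, data$event)
      row$idi <- ii$idi; row$p_idi <- ii$p
      nn <- nri(ref_p, logit[[nm]]$scores, data$event)
      row$nri <- nn$nri; row$p_nri <- nn$p
      dd <- iauc_difference_ci(coxm[[nm]]$scores, ref_lp,
                               data$time_months, data$event,
                               B = B, seed = seed)
      row$iauc_diff <- dd$diff
      row$iauc_diff_lo <- dd$ci95[1]; row$iauc_diff_hi <- dd$ci95[2]
    }
    row
  })
  do.call(rbind, rows)
}
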