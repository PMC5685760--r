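#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return object of class `km_estimate`: data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`; the right-continuous
#'   step function is attached as attribute `surv_fn` (S(0) = 1).
#' @export
km_estimate <- function(time, event) {
  .check_surv(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    survival = sf$surv)
  attr(out, "surv_fn") <- stats::stepfun(sf$time, c(1, sf$surv),
                                         right = FALSE)
  class(out) <- c("km_estimate", "data.frame")
  out
}

.check_surv <- function(time, event) {
  if (length(time) < 1L) stop("need at least one subject")
  if (any(time <= 0)) stop("all follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank with hypergeometric
#' variance; df = number of groups - 1.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("need at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie correction by default)
#' and reports coefficients, hazard ratios with 95% CIs, Wald p-values
#' and the partial log-likelihood. Monotone likelihood (perfect
#' separation) and rank deficiency are turned into errors with a
#' diagnostic rather than silently returning divergent estimates.
#'
#' @param time,event survival data (>= 1 event).
#' @param x data.frame or matrix of covariates (fitted as given).
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_fit`: list with `beta`, `se`, `hr`,
#'   `ci95` (2-column matrix), `p`, `loglik`, `loglik_null`, `ties`,
#'   `n`, `n_event`, and the underlying `model`.
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_surv(time, event)
  if (sum(event) < 1) stop("need at least one event")
  x <- as.data.frame(x)
  if (anyNA(x)) stop("missing covariate values")
  dat <- cbind(data.frame(.time = time, .event = event), x)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(x)), collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w),
                ignore.case = TRUE))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("rank-deficient design: ", paste(names(beta)[is.na(beta)],
                                          collapse = ", "))
  se <- sqrt(diag(fit$var))
  if (diverged || any(abs(beta) > 15))
    stop("monotone partial likelihood (perfect separation); ",
         "coefficients diverge for: ",
         paste(names(beta)[abs(beta) == max(abs(beta))], collapse = ", "))
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  structure(list(beta = beta, se = se, hr = exp(beta), ci95 = ci,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 ties = ties, n = length(time), n_event = sum(event),
                 model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    lower95 = x$ci95[, "lower"], upper95 = x$ci95[, "upper"],
                    p = x$p)
  cat(sprintf("Cox PH fit (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  print(tab, ...)
  invisible(x)
}

#' Forward stepwise Cox selection
#'
#' At each step, fits the current model plus each remaining candidate and
#' adds the candidate with the smallest likelihood-ratio p-value, if it
#' is below `alpha_enter`; stops when none qualifies. Candidates that
#' fail to fit (rank deficiency against the current model, separation)
#' are skipped at that step. The selection trace records every evaluated
#' step.
#'
#' @param time,event survival data.
#' @param data data.frame holding the candidate columns.
#' @param candidates character vector of column names.
#' @param alpha_enter entry threshold for the LR p-value.
#' @param ties tie handling, as in [cox_fit()].
#' @return list with `fit` (a `cox_fit`, or NULL if nothing entered),
#'   `selected` (character), and `trace` (data.frame: step, variable,
#'   lr_stat, p, entered).
#' @export
forward_stepwise_cox <- function(time, event, data, candidates,
                                 alpha_enter = 0.05,
                                 ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(candidates) < 1L) stop("need at least one candidate")
  selected <- character(0)
  loglik_cur <- cox_null_loglik(time, event, ties)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    stats_ <- vapply(remaining, function(v) {
      ll <- tryCatch(cox_fit(time, event, data[, c(selected, v), drop = FALSE],
                             ties = ties)$loglik,
                     error = function(e) NA_real_)
      if (is.na(ll)) return(c(NA_real_, NA_real_))
      lr <- 2 * (ll - loglik_cur)
      c(lr, stats::pchisq(lr, 1, lower.tail = FALSE))
    }, c(0, 0))
    lr <- stats::setNames(stats_[1, ], remaining)
    pv <- stats::setNames(stats_[2, ], remaining)
    ok <- !is.na(pv)
    best <- if (any(ok)) remaining[ok][which.min(pv[ok])] else NA_character_
    enters <- !is.na(best) && pv[best] < alpha_enter
    trace[[step]] <- data.frame(step = step, variable = remaining,
                                lr_stat = lr, p = pv,
                                entered = enters & remaining == best,
                                row.names = NULL)
    if (!enters) break
    selected <- c(selected, best)
    loglik_cur <- loglik_cur + lr[best] / 2
  }
  fit <- if (length(selected))
    cox_fit(time, event, data[, selected, drop = FALSE], ties = ties)
  else NULL
  list(fit = fit, selected = selected, trace = do.call(rbind, trace))
}

# partial log-likelihood of the null (empty) Cox model; the dummy
# covariate is deterministic so the RNG state is left untouched
cox_null_loglik <- function(time, event, ties = "efron") {
  dat <- data.frame(.time = time, .event = event,
                    .z = seq_along(time) %% 2)
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(.time, .event) ~ .z, data = dat, ties = ties,
    control = survival::coxph.control(iter.max = 0), init = 0))
  fit$loglik[1]
}

# Per-cutoff standardized log-rank scan used by contal_oquigley().
# Returns cut positions (group sizes k), midpoint cutpoints, U, V, z.
# U(k) = sum over the k lowest-marker subjects of (event_i - H(t_i)),
# the log-rank numerator in counting-process form; V(k) is the usual
# hypergeometric variance summed over event times.
.co_scan_setup <- function(time, event, marker) {
  tau <- sort(unique(time[event == 1]))
  d <- vapply(tau, function(t) sum(time == t & event == 1), 0)
  Y <- vapply(tau, function(t) sum(time >= t), 0)
  # Nelson-Aalen cumulative hazard at each subject's own time
  H_at <- c(0, cumsum(d / Y))[findInterval(time, tau) + 1L]
  M <- event - H_at
  cvar <- ifelse(Y > 1, d * (Y - d) / (Y - 1), 0)   # d*(Y-d)/(Y-1)
  ind <- outer(time, tau, `>=`)                      # n x D at-risk indicator
  list(tau = tau, d = d, Y = Y, M = M, cvar = cvar, ind = ind)
}

.co_scan_stat <- function(setup, ord, ks) {
  U <- cumsum(setup$M[ord])[ks]
  Y1 <- apply(setup$ind[ord, , drop = FALSE], 2, cumsum)[ks, , drop = FALSE]
  q <- sweep(Y1, 2, setup$Y, `/`)
  V <- as.vector((q * (1 - q)) %*% (setup$cvar / 1))
  z <- ifelse(V > 0, U / sqrt(V), 0)
  list(U = U, V = V, z = z)
}

#' Maximally selected log-rank cutpoint (Contal-O'Quigley)
#'
#' Scans every admissible distinct marker value as a dichotomizing
#' cutoff, computes the standardized log-rank statistic for the
#' low-vs-high split at each, and returns the cutoff maximizing its
#' absolute value. Admissible cutoffs keep at least
#' `min_group_frac * n` subjects in each group, guarding against
#' degenerate splits. The search-corrected p-value uses the
#' Brownian-bridge supremum approximation of Lausen & Schumacher for the
#' maximally selected standardized statistic over the scanned quantile
#' range; a label-permutation p-value (seeded) is available as
#' validation. The sensitivity, specificity and binary AUC
#' ((sens+spec)/2) of classifying the binary event by marker > cutoff
#' are reported alongside.
#'
#' @param time,event survival data.
#' @param marker numeric marker (>= 2 distinct values).
#' @param min_group_frac minimum fraction of subjects per side.
#' @param p_method `"brownian_bridge"` or `"permutation"`.
#' @param B number of permutations when `p_method = "permutation"`.
#' @param seed seed for the permutation p-value.
#' @return object of class `co_cutoff`: list with `cutoff` (midpoint
#'   between the chosen distinct value and the next, so strictly between
#'   marker min and max), `max_stat`, `p_corrected`, `sensitivity`,
#'   `specificity`, `auc_binary`, and the full `scan` data.frame.
#' @export
contal_oquigley <- function(time, event, marker, min_group_frac = 0.1,
                            p_method = c("brownian_bridge", "permutation"),
                            B = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  .check_surv(time, event)
  n <- length(time)
  if (length(unique(marker)) < 2L)
    stop("marker is constant: no cutoff exists")
  ord <- order(marker)
  ms <- marker[ord]
  kmin <- max(1L, ceiling(min_group_frac * n))
  kmax <- n - kmin
  boundary <- which(diff(ms) > 0)                # split between distinct values
  ks <- boundary[boundary >= kmin & boundary <= kmax]
  if (!length(ks))
    stop("no admissible cutoff keeps ", min_group_frac,
         " of subjects in each group")
  setup <- .co_scan_setup(time, event, marker)
  sc <- .co_scan_stat(setup, ord, ks)
  best <- which.max(abs(sc$z))
  k <- ks[best]
  cutoff <- (ms[k] + ms[k + 1]) / 2
  max_stat <- abs(sc$z[best])

  if (p_method == "brownian_bridge") {
    t1 <- ks[1] / n; t2 <- ks[length(ks)] / n
    p <- .lausen_p(max_stat, t1, t2)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm_max <- vapply(seq_len(B), function(b) {
      o <- sample.int(n)
      max(abs(.co_scan_stat(setup, o, ks)$z))
    }, 0)
    p <- (1 + sum(perm_max >= max_stat)) / (B + 1)
  }

  high <- marker > cutoff
  sens <- mean(high[event == 1])
  spec <- mean(!high[event == 0])
  structure(list(cutoff = cutoff, max_stat = max_stat, p_corrected = p,
                 sensitivity = sens, specificity = spec,
                 auc_binary = (sens + spec) / 2,
                 scan = data.frame(k = ks,
                                   cutpoint = (ms[ks] + ms[ks + 1]) / 2,
                                   z = sc$z),
                 p_method = p_method, n = n),
            class = "co_cutoff")
}

# Lausen & Schumacher improved approximation for
# P(sup_{t in [t1,t2]} |B(t)|/sqrt(t(1-t)) > b)
.lausen_p <- function(b, t1, t2) {
  if (b <= 0) return(1)
  logK <- log((t2 * (1 - t1)) / ((1 - t2) * t1))
  p <- 4 * stats::dnorm(b) / b + stats::dnorm(b) * (b - 1 / b) * logK
  min(max(p, 2 * stats::pnorm(-b) * 0), 1)   # clamp to [0, 1]
}

#' Relative risk weights from Cox coefficients
#'
#' Each coefficient is divided by the reference coefficient and rounded
#' to the nearest multiple of `rounding`; the reference weight is exactly
#' 1. Used to build a composite weighted risk score from a multivariable
#' Cox fit.
#'
#' @param fit a [cox_fit()].
#' @param reference name of the reference covariate (non-zero
#'   coefficient).
#' @param rounding rounding step (default 0.05).
#' @return named numeric weights.
#' @export
risk_weights <- function(fit, reference, rounding = 0.05) {
  beta <- fit$beta
  if (!reference %in% names(beta)) stop("unknown reference covariate")
  if (beta[reference] == 0) stop("reference coefficient is zero")
  w <- round(beta / beta[reference] / rounding) * rounding
  w[reference] <- 1
  w
}

#' Risk-group assignment by recursive maximally selected splitting
#'
#' First splits the composite score at its Contal-O'Quigley cutoff; for
#' three groups, whichever child owns the larger maximal standardized
#' log-rank on its own subjects is split again. Labels are ordered by
#' mean score (1 = lowest-risk scores). The log-rank test across the
#' final groups is attached.
#'
#' @param scores composite risk scores.
#' @param time,event survival data.
#' @param n_groups 2 or 3.
#' @param min_group_frac per-split minimum group fraction.
#' @return integer factor of group labels with attributes `cutoffs`
#'   (sorted numeric) and `logrank` (list from [logrank_test()]).
#' @export
assign_risk_groups <- function(scores, time, event, n_groups = 3,
                               min_group_frac = 0.1) {
  if (!n_groups %in% 2:3) stop("n_groups must be 2 or 3")
  root <- contal_oquigley(time, event, scores,
                          min_group_frac = min_group_frac)
  cuts <- root$cutoff
  if (n_groups == 3L) {
    side <- list(scores <= root$cutoff, scores > root$cutoff)
    child <- lapply(side, function(idx) {
      tryCatch(contal_oquigley(time[idx], event[idx], scores[idx],
                               min_group_frac = min_group_frac),
               error = function(e) NULL)
    })
    stat <- vapply(child, function(cs) if (is.null(cs)) -Inf else cs$max_stat, 0)
    if (all(!is.finite(stat)))
      stop("neither side of the first split admits a second cutoff")
    cuts <- sort(c(cuts, child[[which.max(stat)]]$cutoff))
  }
  g <- findInterval(scores, cuts) + 1L
  # order labels by mean score (findInterval already increases with score,
  # but make the contract explicit)
  ord <- order(tapply(scores, g, mean))
  g <- match(g, sort(unique(g))[ord])
  out <- factor(g, levels = seq_len(n_groups))
  attr(out, "cutoffs") <- cuts
  attr(out, "logrank") <- logrank_test(time, event, out)
  out
}
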