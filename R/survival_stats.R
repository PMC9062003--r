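#' Kaplan-Meier product-limit estimate
#'
#' Thin, validated wrapper around [survival::survfit()] returning the curve
#' at event times only. Ties are handled by simultaneous events; a fully
#' censored sample yields a curve constant at 1 (zero event rows).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return data.frame with columns `time`, `surv`, `n_risk`, `n_event`,
#'   restricted to times with at least one event.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], surv = fit$surv[keep],
             n_risk = fit$n.risk[keep], n_event = fit$n.event[keep])
}

#' Mantel-Haenszel log-rank test
#'
#' Wraps [survival::survdiff()]; returns the chi-square statistic, degrees of
#' freedom (groups - 1), p-value and per-group observed/expected event
#' counts.
#'
#' @param time,event survival outcome.
#' @param group group labels (>= 2 nonempty groups).
#' @return list `chi2`, `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop_fmt("logrank_test needs >= 2 groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(chi2 = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       observed = stats::setNames(as.vector(fit$obs), levels(group)),
       expected = stats::setNames(as.vector(fit$exp), levels(group)))
}

#' Univariate Cox proportional-hazards regression
#'
#' Wraps [survival::coxph()] with Breslow tie handling. Monotone-likelihood
#' (perfect separation) fits are returned with `diverged = TRUE` rather than
#' erroring; a zero-variance covariate is an error.
#'
#' @param time,event survival outcome.
#' @param x numeric covariate.
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return list `beta`, `hr`, `se`, `z`, `p`, `ci_lower`, `ci_upper`,
#'   `diverged`.
#' @export
cox_univariate <- function(time, event, x, conf_level = 0.95) {
  stopifnot(length(time) == length(x), length(event) == length(x))
  if (stats::sd(x) == 0) stop_fmt("cox_univariate: covariate has zero variance")
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50, eps = 1e-9)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) diverged <- TRUE
  z <- beta / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(beta = beta, hr = exp(beta), se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       ci_lower = exp(beta - q * se), ci_upper = exp(beta + q * se),
       diverged = diverged)
}

#' Univariate Cox screen of genes for prognostic value
#'
#' Each gene's expression is fitted as the sole covariate; genes with
#' p < alpha are called `protective` (HR < 1) or `risk` (HR > 1), following
#' the convention that a hazard ratio below 1 marks a protective gene.
#' Per-gene failures (zero variance, divergence) are propagated as role
#' `none` with a reason rather than aborting the screen.
#'
#' @param expr [expr_matrix()] aligned with `clin`.
#' @param clin clinical table (same samples, same order).
#' @param alpha screening significance level on the raw p-value.
#' @param adjust if `TRUE`, screen on Benjamini-Hochberg q-values instead of
#'   raw p (off by default: the screen is a candidate filter, not an
#'   inferential claim).
#' @return data.frame, one row per gene: `gene`, `beta`, `hr`, `se`, `z`,
#'   `p`, `q`, `ci_lower`, `ci_upper`, `role`, `reason`.
#' @export
screen_prognostic <- function(expr, clin, alpha = 0.05, adjust = FALSE) {
  stopifnot(ncol(expr) == nrow(clin), all(colnames(expr) == clin$sample_id))
  genes <- rownames(expr)
  res <- lapply(genes, function(g) {
    x <- expr[g, ]
    out <- tryCatch(cox_univariate(clin$time, clin$event, x),
                    error = function(e) conditionMessage(e))
    if (is.character(out))
      return(data.frame(gene = g, beta = NA_real_, hr = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, reason = out))
    data.frame(gene = g, beta = out$beta, hr = out$hr, se = out$se, z = out$z,
               p = out$p, ci_lower = out$ci_lower, ci_upper = out$ci_upper,
               reason = if (out$diverged) "diverged" else "")
  })
  tab <- do.call(rbind, res)
  tab$q <- bh_adjust(tab$p)
  crit <- if (adjust) tab$q else tab$p
  tab$role <- "none"
  ok <- !is.na(crit) & tab$reason == "" & crit < alpha
  tab$role[ok & tab$hr < 1] <- "protective"
  tab$role[ok & tab$hr > 1] <- "risk"
  tab[, c("gene", "beta", "hr", "se", "z", "p", "q",
          "ci_lower", "ci_upper", "role", "reason")]
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every split `marker <= c` vs `marker > c` that keeps both groups at
#' least `minprop * n` and returns the cutpoint maximising the standardised
#' two-group log-rank statistic. Ties in the maximum are broken toward the
#' cutpoint closest to the marker median. Note the selected statistic is
#' inflated relative to a pre-specified split; it is a grouping device, not a
#' valid p-value.
#'
#' @param time,event survival outcome.
#' @param marker numeric marker.
#' @param minprop minimum group proportion (default 0.1).
#' @return list `cutpoint`, `statistic` (standardised log-rank), `n_low`,
#'   `n_high`.
#' @export
best_cutpoint <- function(time, event, marker, minprop = 0.1) {
  n <- length(marker)
  stopifnot(length(time) == n, length(event) == n)
  vals <- sort(unique(marker))
  if (length(vals) < 2L) stop_fmt("best_cutpoint: marker has < 2 distinct values")
  cand <- vals[-length(vals)]                     # split at <= c
  sizes <- vapply(cand, function(c) sum(marker <= c), integer(1L))
  feas <- sizes >= ceiling(minprop * n) & (n - sizes) >= ceiling(minprop * n)
  if (!any(feas)) stop_fmt("best_cutpoint: no split keeps both groups >= %.0f%% of n", 100 * minprop)
  cand <- cand[feas]
  stat <- vapply(cand, function(c) {
    g <- marker > c
    sqrt(survival::survdiff(survival::Surv(time, event) ~ g)$chisq)
  }, numeric(1L))
  best <- which(stat >= max(stat) - 1e-12)
  if (length(best) > 1L) {
    med <- stats::median(marker)
    best <- best[which.min(abs(cand[best] - med))]
  }
  cp <- cand[best[1L]]
  list(cutpoint = cp, statistic = stat[best[1L]],
       n_low = sum(marker <= cp), n_high = sum(marker > cp))
}

#' Time-dependent AUC with inverse-probability-of-censoring weighting
#'
#' Cumulative-case / dynamic-control AUC at each evaluation time: cases are
#' subjects with an observed event by `t`, controls those still under
#' observation beyond `t`. Cases are weighted by 1/G(T-), where G is the
#' Kaplan-Meier estimate of the censoring distribution (Uno-type estimator);
#' the constant control weight 1/G(t) cancels. Times with no cases or no
#' controls return `NA` with a warning.
#'
#' @param time,event survival outcome.
#' @param marker numeric risk marker (higher = earlier event expected).
#' @param eval_times evaluation times within the observed follow-up.
#' @return data.frame `time`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(time, event, marker, eval_times) {
  n <- length(time)
  stopifnot(length(event) == n, length(marker) == n)
  if (any(eval_times > max(time)))
    warn_fmt("eval time(s) beyond observed follow-up")
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {            # left limit of the censoring survival curve
    vapply(t, function(ti) {
      s <- c(1, cfit$surv)[sum(cfit$time < ti) + 1L]
      max(s, 1e-12)
    }, numeric(1L))
  }
  out <- lapply(eval_times, function(t) {
    case <- time <= t & event == 1
    ctrl <- time > t
    if (!any(case) || !any(ctrl)) {
      warn_fmt("AUC undefined at t = %g (no cases or no controls)", t)
      return(data.frame(time = t, auc = NA_real_,
                        n_cases = sum(case), n_controls = sum(ctrl)))
    }
    w <- 1 / G(time[case])
    mi <- marker[case]; mj <- marker[ctrl]
    conc <- vapply(seq_along(mi), function(i)
      sum((mi[i] > mj) + 0.5 * (mi[i] == mj)), numeric(1L))
    data.frame(time = t, auc = sum(w * conc) / (sum(w) * length(mj)),
               n_cases = sum(case), n_controls = sum(ctrl))
  })
  do.call(rbind, out)
}

#' Kruskal-Wallis rank test
#'
#' Wrapper over [stats::kruskal.test()] (tie-corrected H statistic).
#'
#' @param values numeric vector.
#' @param group group labels (>= 2 nonempty groups).
#' @return list `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop_fmt("kruskal_wallis needs >= 2 groups")
  kt <- stats::kruskal.test(values, group)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Columns of `X` are variables. Constant columns yield `NA` correlations
#' with a warning. P-values use the usual t transform on n - 2 df.
#'
#' @param X numeric matrix, observations x variables.
#' @return list `r` (correlation matrix), `p` (p-value matrix, diag `NA`).
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    warn_fmt("constant column(s): %s - correlations undefined",
             paste(colnames(X)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  n <- nrow(X)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Delegates to [stats::p.adjust()] (`method = "BH"`); `NA`s pass through.
#'
#' @param p vector of p-values.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
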