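test_that("Kaplan-Meier matches closed-form product-limit values", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: constant at 1, no event rows
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km0), 0L)
  # tie: S(1) = (1 - 2/3) = 1/3
  km1 <- km_estimate(c(1, 1, 2), c(1, 1, 0))
  expect_equal(km1$surv[km1$time == 1], 1 / 3)
  # permutation invariance
  set.seed(1)
  tt <- rexp(30); ev <- rbinom(30, 1, 0.7)
  p <- sample(30)
  expect_equal(km_estimate(tt, ev), km_estimate(tt[p], ev[p]))
})

test_that("log-rank agrees with a brute-force O-E/V evaluation", {
  # independent oracle: 2x2 table at each event time
  brute_logrank <- function(time, event, g) {
    g <- as.integer(as.factor(g))
    o_minus_e <- 0; v <- 0
    for (t in sort(unique(time[event == 1]))) {
      at <- time >= t
      d <- sum(event == 1 & time == t)
      d1 <- sum(event == 1 & time == t & g == 1L)
      n <- sum(at); n1 <- sum(at & g == 1L)
      o_minus_e <- o_minus_e + d1 - d * n1 / n
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    o_minus_e^2 / v
  }
  # hand-computable 4-sample instance
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 0); g <- c("a", "b", "a", "b")
  lr <- logrank_test(tt, ev, g)
  expect_equal(lr$chi2, brute_logrank(tt, ev, g), tolerance = 1e-9)
  expect_equal(lr$df, 1L)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)
  # random instances with ties and censoring
  for (s in 1:5) {
    set.seed(s)
    tt <- sample(1:8, 40, replace = TRUE); ev <- rbinom(40, 1, 0.7)
    g <- sample(c("a", "b"), 40, replace = TRUE)
    expect_equal(logrank_test(tt, ev, g)$chi2, brute_logrank(tt, ev, g),
                 tolerance = 1e-9)
  }
  # two identical groups (copied samples): no signal
  tt <- rep(c(1, 3, 5), 2); ev <- rep(c(1, 0, 1), 2); g <- rep(c("a", "b"), each = 3)
  lr0 <- logrank_test(tt, ev, g)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-9)
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), ">= 2 groups")
})

test_that("Cox regression honours its exact invariances", {
  d <- sim_surv(100, beta = 0.5, seed = 3L)
  f1 <- cox_univariate(d$time, d$event, d$x)
  f2 <- cox_univariate(d$time, d$event, -d$x)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-9)
  # beta(cx) = beta(x)/c
  f3 <- cox_univariate(d$time, d$event, 2 * d$x)
  expect_equal(f3$beta, f1$beta / 2, tolerance = 1e-8)
  # time rescaling leaves beta unchanged (risk sets preserved)
  f4 <- cox_univariate(3.7 * d$time, d$event, d$x)
  expect_equal(f4$beta, f1$beta, tolerance = 1e-9)
  # CI contains HR, HR > 0
  expect_true(f1$ci_lower < f1$hr && f1$hr < f1$ci_upper)
  expect_error(cox_univariate(d$time, d$event, rep(1, 100)), "zero variance")
  # null covariate at n = 2000: beta near 0
  d0 <- sim_surv(2000, beta = 0, seed = 4L)
  expect_lt(abs(cox_univariate(d0$time, d0$event, d0$x)$beta), 0.07)
})

test_that("Cox flags monotone-likelihood fits instead of erroring", {
  # perfectly separating covariate: all events in the high group, early
  tt <- c(1, 2, 3, 10, 11, 12); ev <- c(1, 1, 1, 0, 0, 0)
  x <- c(5, 5, 5, -5, -5, -5)
  f <- cox_univariate(tt, ev, x)
  expect_true(f$diverged)
})

test_that("prognostic screening assigns roles per the HR/alpha contract", {
  co <- fast_cohort(seed = 21L, n = 150L)
  sub <- co$expr[names(co$truth$gene_roles)[co$truth$gene_roles %in%
                                              c("protective", "risk", "null")], ]
  sub <- expr_matrix(unclass(sub))
  scr <- screen_prognostic(sub, co$clin)
  expect_true(all(scr$role[scr$p < 0.05 & scr$hr < 1 & scr$reason == ""] == "protective"))
  expect_true(all(scr$role[scr$p < 0.05 & scr$hr > 1 & scr$reason == ""] == "risk"))
  expect_true(all(scr$role[scr$p >= 0.05] == "none"))
  # planted direction: a clear majority of protective-truth genes called protective
  roles <- co$truth$gene_roles[scr$gene]
  expect_gt(mean(scr$role[roles == "protective"] == "protective"), 0.9)
  expect_gt(mean(scr$role[roles == "risk"] == "risk"), 0.9)
  # alpha = 0 turns everything off
  scr0 <- screen_prognostic(sub, co$clin, alpha = 0)
  expect_true(all(scr0$role == "none"))
})

test_that("maximally selected cutpoint finds planted splits and obeys ties", {
  set.seed(7)
  g <- rep(c(0, 10), each = 30)
  tt <- c(rexp(30, 1), rexp(30, 0.1)); ev <- rep(1, 60)
  cp <- best_cutpoint(tt, ev, g)
  expect_true(cp$cutpoint >= 0 && cp$cutpoint < 10)
  expect_equal(cp$n_low, 30L)
  # tie rule: marker with two equivalent argmax splits -> median-closer one
  m <- c(1, 1, 2, 2, 3, 3, 4, 4)
  tt2 <- c(1, 2, 1.5, 2.5, 8, 9, 8.5, 9.5); ev2 <- rep(1, 8)
  cp2 <- best_cutpoint(tt2, ev2, m, minprop = 0.25)
  # splits at 2 (low {1,1,2,2}) gives the clean separation
  expect_equal(cp2$cutpoint, 2)
  expect_error(best_cutpoint(tt2, ev2, rep(1, 8)), "< 2 distinct")
  expect_error(best_cutpoint(tt2, ev2, c(1, rep(2, 7)), minprop = 0.4), "no split")
})

test_that("IPCW AUC is exact for perfect markers and rank-invariant", {
  set.seed(11)
  tt <- rexp(60, 0.2); ev <- rep(1, 60)
  a <- time_dependent_auc(tt, ev, -tt, eval_times = quantile(tt, c(0.25, 0.5, 0.75)))
  expect_equal(a$auc, rep(1, 3))
  # monotone transform invariance
  m <- rnorm(60)
  t_ev <- quantile(tt, c(0.3, 0.6))
  a1 <- time_dependent_auc(tt, ev, m, t_ev)
  a2 <- time_dependent_auc(tt, ev, exp(3 * m), t_ev)
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
  # no controls beyond the largest time: flagged NA
  expect_warning(a3 <- time_dependent_auc(tt, ev, m, max(tt)), "no cases or no controls")
  expect_true(is.na(a3$auc))
})

test_that("rank tests and BH behave per their closed forms", {
  expect_equal(kruskal_wallis(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))$H,
               kruskal.test(rep(c(1, 2, 3), 2), factor(rep(c("a", "b"), each = 3)))$statistic,
               ignore_attr = TRUE)
  # identical group distributions -> H = 0
  expect_equal(kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$H, 0)
  expect_error(kruskal_wallis(1:4, rep("a", 4)), ">= 2 groups")
  # direct step-up evaluation
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # q >= p and order preservation
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) > -1e-12))
  expect_true(all(q <= 1))
})

test_that("pearson_matrix has unit diagonal, symmetry, and flags constants", {
  set.seed(3)
  X <- matrix(rnorm(100), 20, dimnames = list(NULL, paste0("v", 1:5)))
  pm <- pearson_matrix(X)
  expect_equal(diag(pm$r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(pm$r, t(pm$r))
  expect_equal(pm$p[1, 2], cor.test(X[, 1], X[, 2])$p.value, tolerance = 1e-9)
  Xc <- cbind(X, vc = 1)
  expect_warning(pmc <- pearson_matrix(Xc), "constant")
  expect_true(is.na(pmc$r["vc", "vc"]))
})
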