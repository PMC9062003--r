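test_that("zscore_genes standardises with the population divisor", {
  e <- toy_expr(12L, 8L, seed = 2L)
  Z <- zscore_genes(e)
  expect_equal(rowMeans(Z), rep(0, 12L), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rowMeans(Z^2), rep(1, 12L), tolerance = 1e-12, ignore_attr = TRUE)
  # zero-variance gene is dropped with a warning
  X <- unclass(e); X[5, ] <- 3
  expect_warning(Z2 <- zscore_genes(expr_matrix(X)), "zero-variance")
  expect_equal(nrow(Z2), 11L)
  expect_false("g05" %in% rownames(Z2))
  expect_error(zscore_genes(X[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("pc1_scores matches an eigen-decomposition oracle", {
  set.seed(4)
  Z <- zscore_genes(toy_expr(15L, 10L, seed = 4L))
  sc <- pc1_scores(Z)
  # oracle: leading eigenvector of the sample Gram matrix
  eg <- eigen(crossprod(Z), symmetric = TRUE)
  oracle <- eg$vectors[, 1L] * sqrt(eg$values[1L])
  if (cor(oracle, sc) < 0) oracle <- -oracle
  expect_equal(as.numeric(sc), oracle, tolerance = 1e-8)
  expect_equal(attr(sc, "var_explained"), eg$values[1L] / sum(eg$values),
               tolerance = 1e-10)
  expect_length(attr(sc, "loadings"), 15L)
})

test_that("pc1 of a single gene is that gene (sign-fixed), and of correlated genes their consensus", {
  set.seed(6)
  v <- rnorm(8)
  Z1 <- zscore_genes(matrix(v, 1, 8,
        dimnames = list("g1", sprintf("s%d", 1:8))))
  sc <- pc1_scores(Z1)
  expect_equal(cor(sc, as.vector(Z1["g1", ])), 1, tolerance = 1e-12, ignore_attr = TRUE)
  # many noisy copies of one signal: PC1 ~ the signal, positively oriented
  base <- rnorm(20)
  X <- t(replicate(10, base + rnorm(20, sd = 0.2)))
  dimnames(X) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:20))
  sc2 <- pc1_scores(zscore_genes(expr_matrix(X)))
  expect_gt(cor(sc2, base), 0.98)
  expect_gt(attr(sc2, "var_explained"), 0.8)
})

test_that("pc1_scores is equivariant under sample permutation", {
  Z <- zscore_genes(toy_expr(10L, 9L, seed = 8L))
  p <- c(4L, 1L, 9L, 2L, 7L, 3L, 5L, 8L, 6L)
  s1 <- pc1_scores(Z)
  s2 <- pc1_scores(Z[, p])
  expect_equal(as.numeric(s2), as.numeric(s1)[p], tolerance = 1e-10)
  expect_identical(names(s2), names(s1)[p])
})

test_that("the score vanishes when protective and risk blocks coincide", {
  e <- toy_expr(10L, 8L, seed = 10L)
  g <- rownames(e)[1:5]
  sc <- compute_m6ascore(e, list(protective = g, risk = g))
  expect_equal(sc$m6ascore, rep(0, 8L), tolerance = 1e-10)
  expect_equal(sc$pc1_protective, sc$pc1_risk, tolerance = 1e-12)
})

test_that("the score tracks the planted latent signal on a synthetic cohort", {
  co <- fast_cohort(seed = 30L, n = 100L)
  roles <- co$truth$gene_roles
  sc <- compute_m6ascore(co$expr,
                         list(protective = names(roles)[roles == "protective"],
                              risk = names(roles)[roles == "risk"]))
  expect_gt(abs(cor(sc$m6ascore, co$truth$latent_score)), 0.95)
  # adding pure-noise genes to the expression matrix cannot change the score:
  # only the named blocks enter
  X2 <- rbind(unclass(co$expr),
              EXTRA01 = rnorm(100), EXTRA02 = rnorm(100))
  sc2 <- compute_m6ascore(expr_matrix(X2),
                          list(protective = names(roles)[roles == "protective"],
                               risk = names(roles)[roles == "risk"]))
  expect_equal(sc2$m6ascore, sc$m6ascore, tolerance = 1e-12)
  # joint mode agrees in direction
  scj <- compute_m6ascore(co$expr,
                          list(protective = names(roles)[roles == "protective"],
                               risk = names(roles)[roles == "risk"]),
                          mode = "joint")
  expect_gt(abs(cor(scj$m6ascore, co$truth$latent_score)), 0.8)
})

test_that("compute_m6ascore accepts a screen data.frame and enforces minimum genes", {
  co <- fast_cohort(seed = 31L, n = 100L)
  scr <- screen_prognostic(co$expr, co$clin)
  sc <- compute_m6ascore(co$expr, scr)
  expect_identical(sc$sample_id, colnames(co$expr))
  expect_error(compute_m6ascore(co$expr, list(protective = rownames(co$expr)[1],
                                              risk = rownames(co$expr)[2:4])),
               "relaxing")
})

test_that("dichotomize honours the strict high rule and the median fallback", {
  set.seed(14)
  n <- 21L
  sc <- data.frame(sample_id = sprintf("s%02d", 1:n), m6ascore = rnorm(n))
  clin <- clinical_table(data.frame(sample_id = sc$sample_id,
                                    time = rexp(n, 0.1), event = rbinom(n, 1, 0.8)))
  d <- dichotomize(sc, clin, method = "median")
  m <- median(sc$m6ascore)
  expect_identical(d$group, ifelse(sc$m6ascore > m, "high", "low"))
  expect_identical(sum(d$group == "low"), 11L)         # odd n: median goes low
  dm <- dichotomize(sc, clin, method = "maxstat")
  expect_true(all(dm$group[dm$m6ascore > dm$cutpoint[1]] == "high"))
  k <- sum(dm$group == "low")
  expect_true(k >= ceiling(0.1 * n) && n - k >= ceiling(0.1 * n))
  sc$m6ascore <- rep(1, n)
  expect_error(dichotomize(sc, clin), "constant")
})

test_that("response_summary reports exact proportions and a perfect AUC", {
  sc <- data.frame(sample_id = sprintf("s%02d", 1:8),
                   m6ascore = c(5, 6, 7, 8, 1, 2, 3, 4),
                   group = rep(c("high", "low"), each = 4))
  clin <- data.frame(sample_id = sc$sample_id,
                     response = c("CR", "PR", "CR", "SD", "PD", "PD", "SD", NA))
  rs <- response_summary(sc, clin)
  expect_equal(rs$n_missing, 1L)
  expect_equal(unname(rs$proportions["high", c("CR", "PR", "SD")]),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(rs$proportions["low", "PD"]), 2 / 3)
  # responders (scores 5,6,7) all outrank non-responders (8? no: SD) ->
  # responders are 5,6,7; non-responders are 8,1,2,3; AUC by hand:
  resp <- c(5, 6, 7); nonr <- c(8, 1, 2, 3)
  auc_hand <- mean(outer(resp, nonr, ">") + 0.5 * outer(resp, nonr, "=="))
  expect_equal(rs$auc, auc_hand, tolerance = 1e-12)
  expect_true(rs$wilcox_p > 0 && rs$wilcox_p <= 1)
  # group with no response data warns
  clin$response[5:8] <- NA
  expect_warning(response_summary(sc, clin), "no response data")
})
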