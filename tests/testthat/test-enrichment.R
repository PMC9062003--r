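test_that("gsea_es equals the brute-force running sum on random instances", {
  for (s in 1:10) {
    set.seed(s)
    N <- sample(20:100, 1L)
    stat <- setNames(rnorm(N), sprintf("g%03d", seq_len(N)))
    set <- sample(names(stat), sample(3:10, 1L))
    for (w in c(0, 1)) {
      expect_equal(gsea_es(stat, set, weight = w)$es,
                   unname(brute_es(stat, set, weight = w)), tolerance = 1e-12)
    }
  }
})

test_that("enrichment score flips sign under statistic reversal (weight 0)", {
  set.seed(3)
  stat <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  set <- names(sort(stat, decreasing = TRUE))[1:8]   # top block -> strongly positive
  e1 <- gsea_es(stat, set, weight = 0)$es
  e2 <- gsea_es(-stat, set, weight = 0)$es
  expect_gt(e1, 0.5)
  expect_lt(e2, -0.4)
  # unweighted walk is antisymmetric up to tie-breaking at the extremum
  expect_equal(e1, -e2, tolerance = 0.1)
  expect_error(gsea_es(stat, character(0)), "no members")
  expect_error(gsea_es(stat, names(stat)), "equals universe")
})

test_that("leading edge is the members up to the (signed) extremum", {
  stat <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3), paste0("g", 1:8))
  le <- gsea_es(stat, c("g1", "g2", "g8"), weight = 0)
  # running sum peaks after g2; g8 lies beyond the peak
  expect_setequal(le$leading_edge, c("g1", "g2"))
})

test_that("gsea recovers a planted set and is calibrated under the null", {
  set.seed(21)
  X <- matrix(rnorm(60 * 20, mean = 5), 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:20)))
  X[1:10, 1:10] <- X[1:10, 1:10] + 1.5
  g <- rep(c("A", "B"), each = 10)
  sets <- structure(list(up_set = sprintf("g%02d", 1:10),
                         null_set = sprintf("g%02d", 31:40),
                         tiny = sprintf("g%02d", 1:2)),
                    class = "gene_sets")
  expect_warning(res <- gsea(expr_matrix(X), g, sets, n_perm = 200L, seed = 2L),
                 "skipping 1 set")
  expect_setequal(res$set, c("up_set", "null_set"))
  up <- res[res$set == "up_set", ]
  expect_gt(up$es, 0)
  expect_lt(up$p, 0.02)
  expect_gt(abs(up$nes), abs(res$nes[res$set == "null_set"]))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= 0 & res$q <= 1))
  # determinism
  expect_warning(res2 <- gsea(expr_matrix(X), g, sets, n_perm = 200L, seed = 2L))
  expect_equal(res, res2)
})

test_that("gsea permutation p-values are near-uniform under a true null", {
  set.seed(31)
  pvals <- vapply(1:40, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(30 * 16, mean = 5), 30,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:16)))
    g <- rep(c("A", "B"), each = 8)
    sets <- structure(list(s1 = sprintf("g%02d", 1:8)), class = "gene_sets")
    gsea(expr_matrix(X), g, sets, n_perm = 99L, seed = s)$p
  }, numeric(1L))
  # one-sided exceedance probabilities: both tails populated, KS not extreme
  expect_gt(mean(pvals < 0.5), 0.2)
  expect_lt(mean(pvals < 0.5), 0.85)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("ssgsea is exactly invariant to per-sample monotone transforms", {
  e <- toy_expr(40L, 6L, seed = 12L)
  sets <- structure(list(a = rownames(e)[1:7], b = rownames(e)[20:30]),
                    class = "gene_sets")
  s1 <- ssgsea(e, sets)
  X <- unclass(e)
  s2 <- ssgsea(expr_matrix(exp(0.7 * X)), sets)     # strictly increasing map
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_identical(dim(s1), c(2L, 6L))
  expect_error(ssgsea(e, structure(list(u = rownames(e)), class = "gene_sets")),
               "equals the universe")
  expect_warning(
    s3 <- ssgsea(e, structure(list(a = rownames(e)[1:7], z = c("nope1", "nope2")),
                              class = "gene_sets")),
    "no genes in the universe")
  expect_identical(rownames(s3), "a")
})

test_that("ssgsea ranks a planted high-expression set above the rest", {
  set.seed(5)
  X <- matrix(rnorm(50 * 8, mean = 4), 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  X[1:10, 1:4] <- X[1:10, 1:4] + 4                 # set high in samples 1-4
  sets <- structure(list(hi = sprintf("g%02d", 1:10)), class = "gene_sets")
  sc <- ssgsea(expr_matrix(X), sets)
  expect_gt(min(sc[1, 1:4]), max(sc[1, 5:8]))
  # normalisation only rescales
  scn <- ssgsea(expr_matrix(X), sets, normalize = TRUE)
  expect_equal(cor(sc[1, ], scn[1, ]), 1, tolerance = 1e-12)
})

test_that("estimate_scores combined equals immune + stromal", {
  e <- toy_expr(40L, 5L, seed = 17L)
  es <- estimate_scores(e, rownames(e)[1:8], rownames(e)[9:16])
  expect_equal(es$combined_score, es$immune_score + es$stromal_score)
  expect_identical(es$sample_id, colnames(e))
})

test_that("ora matches a direct hypergeometric enumeration", {
  universe <- sprintf("g%02d", 1:40)
  sets <- structure(list(s1 = universe[1:10], s2 = universe[11:14],
                         all = universe), class = "gene_sets")
  genes <- universe[c(1:6, 12, 30)]
  res <- ora(genes, universe, sets)
  # closed form: sum over j >= overlap of choose(K,j) choose(N-K, n-j)/choose(N,n)
  closed <- function(K, ov, N, n)
    sum(choose(K, ov:min(K, n)) * choose(N - K, n - (ov:min(K, n)))) / choose(N, n)
  expect_equal(res$p[res$set == "s1"], closed(10, 6, 40, 8), tolerance = 1e-12)
  expect_equal(res$p[res$set == "s2"], closed(4, 1, 40, 8), tolerance = 1e-12)
  # query drawn entirely from the universe-sized set: p = 1
  expect_equal(res$p[res$set == "all"], 1, tolerance = 1e-12)
  expect_equal(res$q, bh_adjust(res$p))
  expect_error(ora(character(0), universe, sets), "empty query")
  expect_error(ora(c("g01", "zzz"), universe, sets), "outside the universe")
})
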