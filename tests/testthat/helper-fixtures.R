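# Shared in-code fixtures for the test suite. Everything is generated
# programmatically under fixed seeds; nothing is read from disk.

# small random expression matrix with named dims
toy_expr <- function(n_genes = 10L, n_samples = 6L, seed = 1L, mean = 5) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, mean), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expr_matrix(m)
}

# two well-separated sample blobs in feature space; genes x samples.
# block 1 is shifted up on the first half of the genes and block 2 on the
# second half, so each block has a coherent profile shape (visible to
# correlation distance), not just an overall level difference.
planted_blobs <- function(n_per = 10L, n_genes = 20L, shift = 4, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * 2 * n_per), n_genes)
  h <- seq_len(n_genes %/% 2)
  m[h, seq_len(n_per)] <- m[h, seq_len(n_per)] + shift
  m[-h, n_per + seq_len(n_per)] <- m[-h, n_per + seq_len(n_per)] + shift
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(2L * n_per)))
  list(expr = expr_matrix(m),
       truth = rep(c(1L, 2L), each = n_per))
}

# exponential survival data, optionally with a prognostic covariate
sim_surv <- function(n, beta = 0, seed = 1L, cens = 0.3) {
  set.seed(seed)
  x <- stats::rnorm(n)
  rate <- 0.1 * exp(beta * x)
  t_ev <- stats::rexp(n, rate)
  t_c <- if (cens > 0) stats::rexp(n, 0.1 * cens / (1 - cens)) else rep(Inf, n)
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), x = x)
}

# map predicted cluster labels onto truth labels by majority overlap
match_labels <- function(pred, truth) {
  tab <- table(pred, truth)
  map <- colnames(tab)[apply(tab, 1L, which.max)]
  names(map) <- rownames(tab)
  unname(map[as.character(pred)])
}

# independent brute-force running-sum GSEA enrichment score (oracle)
brute_es <- function(stat, set, weight = 1) {
  ord <- order(stat, decreasing = TRUE)
  genes <- names(stat)[ord]
  s <- abs(stat[ord])^weight
  nh <- sum(genes %in% set)
  nr <- sum(s[genes %in% set])
  run <- 0; best <- 0
  for (i in seq_along(genes)) {
    run <- if (genes[i] %in% set) run + s[i] / nr else run - 1 / (length(genes) - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# small deterministic signature matrix for deconvolution tests
toy_signature <- function(n_types = 5L, markers = 8L, seed = 3L) {
  set.seed(seed)
  g <- sprintf("m%02d", seq_len(n_types * markers))
  m <- matrix(stats::runif(length(g) * n_types, 1, 8), length(g),
              dimnames = list(g, sprintf("ct%d", seq_len(n_types))))
  for (j in seq_len(n_types))
    m[((j - 1L) * markers + 1L):(j * markers), j] <- stats::runif(markers, 60, 140)
  signature_matrix(m)
}

# one Dirichlet draw (uses the package-internal gamma construction)
rdirichlet_1 <- function(alpha) as.vector(modpattern:::rdirichlet_mat(1L, alpha))

fast_cohort <- function(seed = 1L, n = 120L, ...) {
  generate_cohort(cohort_config(n_samples = n, seed = seed, ...))
}
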