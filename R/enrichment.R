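#' Walk-down enrichment score for one gene set
#'
#' Genes are ordered by decreasing rank statistic. Walking down the list,
#' hitting a set member increments the running sum by |stat|^weight
#' (normalised so hit increments total 1) and a miss decrements by
#' 1/(N - Nh). The enrichment score is the maximum deviation from zero
#' (signed); the position of the extremum defines the leading edge.
#'
#' @param stat named numeric rank statistic over the gene universe.
#' @param set character vector of member genes.
#' @param weight exponent on |stat| for hit increments (1 = classic weighted
#'   statistic).
#' @return list `es`, `leading_edge` (member genes up to/after the peak).
#' @export
gsea_es <- function(stat, set, weight = 1) {
  ord <- order(stat, decreasing = TRUE)
  stat <- stat[ord]
  genes <- names(stat)
  hit <- genes %in% set
  nh <- sum(hit)
  N <- length(genes)
  if (nh == 0L) stop_fmt("gsea_es: set has no members in the universe")
  if (nh == N) stop_fmt("gsea_es: set equals universe")
  w <- abs(stat)^weight
  nr <- sum(w[hit])
  inc <- ifelse(hit, if (nr > 0) w / nr else 1 / nh, -1 / (N - nh))
  run <- cumsum(inc)
  i_max <- which.max(abs(run))
  es <- run[i_max]
  le <- if (es >= 0) genes[seq_len(i_max)][hit[seq_len(i_max)]]
        else genes[i_max:N][hit[i_max:N]]
  list(es = es, leading_edge = le)
}

#' @noRd
rank_statistic <- function(X, ia, rank_stat) {
  m1 <- rowMeans(X[, ia, drop = FALSE]); m2 <- rowMeans(X[, !ia, drop = FALSE])
  if (rank_stat == "s2n") {
    s1 <- apply(X[, ia, drop = FALSE], 1L, stats::sd)
    s2 <- apply(X[, !ia, drop = FALSE], 1L, stats::sd)
    return((m1 - m2) / pmax(s1 + s2, 1e-8))
  }
  n1 <- sum(ia); n2 <- sum(!ia)
  v1 <- apply(X[, ia, drop = FALSE], 1L, stats::var)
  v2 <- apply(X[, !ia, drop = FALSE], 1L, stats::var)
  dg <- n1 + n2 - 2
  sg2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  prior <- fit_f_dist(sg2, dg)
  post <- if (is.infinite(prior$d0)) rep(prior$s02, length(sg2)) else
    (prior$d0 * prior$s02 + dg * sg2) / (prior$d0 + dg)
  (m1 - m2) / sqrt(post * (1 / n1 + 1 / n2))
}

#' Gene-set enrichment analysis with phenotype permutation
#'
#' Genes are ranked between two sample classes (moderated t by default,
#' signal-to-noise behind the flag); enrichment scores follow [gsea_es()].
#' The null distribution permutes the class labels and recomputes the
#' ranking, preserving inter-gene correlation. NES divides each ES by the
#' mean |null ES| of the same sign for its set; FDR q uses the standard
#' pooled positive/negative null procedure. Sets overlapping the universe in
#' fewer than `min_size` genes are skipped with a warning.
#'
#' @param expr genes x samples [expr_matrix()].
#' @param groups two-level class labels over samples.
#' @param sets `gene_sets` collection.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param weight hit-increment exponent.
#' @param rank_stat `"moderated_t"` or `"s2n"`.
#' @param min_size minimum set-universe overlap.
#' @return data.frame per set: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (comma-joined).
#' @export
gsea <- function(expr, groups, sets, n_perm = 1000L, seed = 1L, weight = 1,
                 rank_stat = c("moderated_t", "s2n"), min_size = 3L) {
  rank_stat <- match.arg(rank_stat)
  groups <- as.factor(as.character(groups))
  stopifnot(nlevels(groups) == 2L)
  X <- unclass(expr)
  universe <- rownames(X)
  keep <- vapply(sets, function(s) sum(s %in% universe), integer(1L)) >= min_size
  if (any(!keep))
    warn_fmt("skipping %d set(s) with < %d genes in the universe: %s",
             sum(!keep), min_size, paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  if (length(sets) == 0L) stop_fmt("gsea: no usable sets")
  ia <- groups == levels(groups)[1L]

  stat <- rank_statistic(X, ia, rank_stat)
  names(stat) <- universe
  obs <- lapply(sets, function(s) gsea_es(stat, s, weight))
  es <- vapply(obs, `[[`, numeric(1L), "es")

  set.seed(seed)
  null_es <- matrix(NA_real_, length(sets), n_perm,
                    dimnames = list(names(sets), NULL))
  for (b in seq_len(n_perm)) {
    perm_ia <- sample(ia)
    pstat <- rank_statistic(X, perm_ia, rank_stat)
    names(pstat) <- universe
    null_es[, b] <- vapply(sets, function(s) gsea_es(pstat, s, weight)$es, numeric(1L))
  }

  p <- nes <- numeric(length(sets))
  null_nes <- null_es
  for (i in seq_along(sets)) {
    pos <- null_es[i, ] >= 0
    mpos <- mean(abs(null_es[i, pos]))
    mneg <- mean(abs(null_es[i, !pos]))
    null_nes[i, pos] <- null_es[i, pos] / max(mpos, 1e-12)
    null_nes[i, !pos] <- null_es[i, !pos] / max(mneg, 1e-12)
    if (es[i] >= 0) {
      nes[i] <- es[i] / max(mpos, 1e-12)
      p[i] <- (1 + sum(null_es[i, pos] >= es[i])) / (1 + sum(pos))
    } else {
      nes[i] <- es[i] / max(mneg, 1e-12)
      p[i] <- (1 + sum(null_es[i, !pos] <= es[i])) / (1 + sum(!pos))
    }
  }
  pool <- as.vector(null_nes)
  q <- vapply(seq_along(sets), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / max(den, 1e-12))
  }, numeric(1L))

  data.frame(set = names(sets),
             size = vapply(sets, function(s) sum(s %in% universe), integer(1L)),
             es = es, nes = nes, p = p, q = q,
             leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","),
                                   character(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-sample GSEA scores
#'
#' Per sample, genes are ranked by expression (largest = N); the score of a
#' set is the sum over list positions of the difference between the
#' rank-weighted hit ECDF (weight `rank^alpha`) and the unweighted miss
#' ECDF. Rank-based, hence invariant to per-sample monotone transforms.
#'
#' @param expr genes x samples [expr_matrix()].
#' @param sets `gene_sets` collection; a set must not equal the universe.
#' @param alpha rank weighting exponent (0.25 by default).
#' @param normalize divide scores by the full range of achievable scores
#'   across samples (max - min over the returned matrix).
#' @return numeric matrix, sets x samples.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  X <- unclass(expr)
  universe <- rownames(X)
  N <- length(universe)
  overlap_n <- vapply(sets, function(s) sum(s %in% universe), integer(1L))
  if (any(overlap_n == N))
    stop_fmt("ssgsea: set '%s' equals the universe",
             names(sets)[overlap_n == N][1L])
  usable <- overlap_n >= 1L
  if (any(!usable))
    warn_fmt("skipping set(s) with no genes in the universe: %s",
             paste(names(sets)[!usable], collapse = ", "))
  sets <- sets[usable]
  if (length(sets) == 0L) stop_fmt("ssgsea: no usable sets")
  hit_mask <- vapply(sets, function(s) universe %in% s, logical(N))

  scores <- matrix(NA_real_, length(sets), ncol(X),
                   dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j], ties.method = "average")      # largest value -> rank N
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^alpha
    for (i in seq_along(sets)) {
      hit <- hit_mask[ord, i]
      nh <- sum(hit)
      p_hit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
      p_miss <- cumsum(!hit) / (N - nh)
      scores[i, j] <- sum(p_hit - p_miss)
    }
  }
  if (normalize) scores <- scores / (max(scores) - min(scores))
  scores
}

#' Immune and stromal infiltration scores
#'
#' ssGSEA scores of an immune and a stromal signature set per sample;
#' the combined score is their sum. (The non-linear tumor-purity transform
#' of the original ESTIMATE method is intentionally not reproduced; the
#' analysis uses only immune/stromal/combined.)
#'
#' @param expr genes x samples [expr_matrix()].
#' @param immune_set,stromal_set character gene vectors.
#' @param alpha rank weighting exponent passed to [ssgsea()].
#' @return data.frame `sample_id`, `immune_score`, `stromal_score`,
#'   `combined_score`.
#' @export
estimate_scores <- function(expr, immune_set, stromal_set, alpha = 0.25) {
  sc <- ssgsea(expr, structure(list(immune = immune_set, stromal = stromal_set),
                               class = "gene_sets"), alpha = alpha)
  data.frame(sample_id = colnames(sc),
             immune_score = sc["immune", ],
             stromal_score = sc["stromal", ],
             combined_score = sc["immune", ] + sc["stromal", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of a query gene list against
#' each set, BH-adjusted across sets.
#'
#' @param genes query gene list (must be a subset of `universe`).
#' @param universe background gene list.
#' @param sets `gene_sets` collection (membership intersected with the
#'   universe).
#' @return data.frame per set: `set`, `set_size`, `overlap`, `p`, `q`.
#' @export
ora <- function(genes, universe, sets) {
  if (length(genes) == 0L) stop_fmt("ora: empty query gene list")
  if (!all(genes %in% universe)) stop_fmt("ora: query genes outside the universe")
  genes <- unique(genes)
  universe <- unique(universe)
  N <- length(universe)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(genes, s))
    p <- stats::phyper(ov - 1, length(s), N - length(s), length(genes),
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
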