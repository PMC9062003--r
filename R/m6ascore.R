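#' Z-score genes across samples
#'
#' Per-gene centring and scaling to unit population standard deviation
#' (divisor n, not n - 1; documented choice — the score construction is a
#' descriptive projection, not an inferential estimate). Zero-variance genes
#' are dropped with a warning.
#'
#' @param expr genes x samples matrix.
#' @return Standardised matrix (possibly fewer rows).
#' @export
zscore_genes <- function(expr) {
  X <- unclass(expr)
  if (ncol(X) < 2L) stop_fmt("zscore_genes: need >= 2 samples (sd undefined)")
  mu <- rowMeans(X)
  sdp <- sqrt(rowMeans((X - mu)^2))
  drop <- sdp == 0
  if (any(drop)) {
    warn_fmt("dropping %d zero-variance gene(s): %s", sum(drop),
             paste(utils::head(rownames(X)[drop], 5L), collapse = ", "))
    X <- X[!drop, , drop = FALSE]; mu <- mu[!drop]; sdp <- sdp[!drop]
    if (nrow(X) == 0L) stop_fmt("zscore_genes: no genes left")
  }
  (X - mu) / sdp
}

#' Per-sample scores on the first principal component
#'
#' The samples are projected onto the first right singular vector of the
#' standardised genes x samples matrix (equivalently, PC1 of the samples in
#' gene space). The sign of a principal component is arbitrary; it is fixed
#' so that PC1 correlates positively with the per-sample mean of the
#' standardised genes, and if that correlation is exactly zero, so that the
#' largest-magnitude gene loading is positive.
#'
#' @param Z standardised genes x samples matrix (rows mean 0).
#' @return Named numeric vector of PC1 scores per sample, with the fraction
#'   of variance explained in `attr(, "var_explained")` and the gene
#'   loadings in `attr(, "loadings")`.
#' @export
pc1_scores <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 1L || ncol(Z) < 3L) stop_fmt("pc1_scores: need >= 1 gene and >= 3 samples")
  s <- svd(Z)
  if (s$d[1L] < 1e-12) stop_fmt("pc1_scores: matrix has rank 0")
  scores <- s$v[, 1L] * s$d[1L]
  loadings <- s$u[, 1L]
  cm <- colMeans(Z)
  al <- if (stats::sd(cm) > 0 && stats::sd(scores) > 0) stats::cor(scores, cm) else 0
  flip <- if (abs(al) > 1e-12) al < 0 else loadings[which.max(abs(loadings))] < 0
  if (flip) { scores <- -scores; loadings <- -loadings }
  names(scores) <- colnames(Z)
  attr(scores, "var_explained") <- s$d[1L]^2 / sum(s$d^2)
  attr(scores, "loadings") <- stats::setNames(loadings, rownames(Z))
  scores
}

#' Compute the per-sample m6Ascore from a prognostic screen
#'
#' The score subtracts the first principal component of the risk-gene block
#' from that of the protective-gene block:
#' `m6Ascore = PC1(protective z-scores) - PC1(risk z-scores)`.
#' Each block is z-scored and decomposed separately (mode `"separate"`, the
#' default reading of a sum over two disjoint gene sets); mode `"joint"`
#' instead runs one PCA over both blocks and takes the difference of the
#' per-set loading-weighted sums.
#'
#' @param expr genes x samples [expr_matrix()].
#' @param screen data.frame from [screen_prognostic()] with `gene` and
#'   `role` columns, or a list with `protective` and `risk` gene vectors.
#' @param mode `"separate"` or `"joint"`.
#' @return data.frame `sample_id`, `m6ascore`, `pc1_protective`, `pc1_risk`.
#' @export
compute_m6ascore <- function(expr, screen, mode = c("separate", "joint")) {
  mode <- match.arg(mode)
  if (is.data.frame(screen)) {
    prot <- screen$gene[screen$role == "protective"]
    risk <- screen$gene[screen$role == "risk"]
  } else {
    prot <- screen$protective; risk <- screen$risk
  }
  prot <- intersect(prot, rownames(expr))
  risk <- intersect(risk, rownames(expr))
  if (length(prot) < 2L || length(risk) < 2L)
    stop_fmt(paste0("compute_m6ascore: need >= 2 protective and >= 2 risk genes ",
                    "(got %d, %d); consider relaxing the screening threshold"),
             length(prot), length(risk))
  if (mode == "separate") {
    p1 <- pc1_scores(zscore_genes(expr[prot, , drop = FALSE]))
    r1 <- pc1_scores(zscore_genes(expr[risk, , drop = FALSE]))
  } else {
    Z <- zscore_genes(expr[c(prot, risk), , drop = FALSE])
    sc <- pc1_scores(Z)
    lo <- attr(sc, "loadings")
    p1 <- colSums(lo[intersect(prot, names(lo))] * Z[intersect(prot, names(lo)), , drop = FALSE])
    r1 <- colSums(lo[intersect(risk, names(lo))] * Z[intersect(risk, names(lo)), , drop = FALSE])
  }
  data.frame(sample_id = colnames(expr), m6ascore = as.numeric(p1) - as.numeric(r1),
             pc1_protective = as.numeric(p1), pc1_risk = as.numeric(r1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split samples into high/low score groups
#'
#' Default cutpoint is the maximally selected log-rank threshold
#' ([best_cutpoint()]); a median split is available behind the flag. A
#' sample is `high` iff its score strictly exceeds the cutpoint.
#'
#' @param scores data.frame from [compute_m6ascore()] (or with `sample_id`
#'   and `m6ascore`).
#' @param clin clinical table aligned with `scores`.
#' @param method `"maxstat"` or `"median"`.
#' @param minprop minimum group proportion for the maxstat scan.
#' @return `scores` with added `group` (`high`/`low`) and `cutpoint`
#'   columns.
#' @export
dichotomize <- function(scores, clin, method = c("maxstat", "median"),
                        minprop = 0.1) {
  method <- match.arg(method)
  stopifnot(all(scores$sample_id == clin$sample_id))
  x <- scores$m6ascore
  if (length(unique(x)) < 2L) stop_fmt("dichotomize: score is constant, no feasible split")
  cp <- if (method == "maxstat")
    best_cutpoint(clin$time, clin$event, x, minprop = minprop)$cutpoint
  else {
    m <- stats::median(x)
    # median split: put ties-at-median in the low group; with an odd n and
    # distinct values this yields the ceiling(n/2) vs floor(n/2) partition
    if (all(x <= m) || all(x > m)) max(x[x < m]) else m
  }
  scores$group <- ifelse(x > cp, "high", "low")
  scores$cutpoint <- cp
  scores
}

#' Summarise immunotherapy response by score group
#'
#' Per-group CR/PR/SD/PD proportions, the AUC of the raw score for
#' responder status (responder = CR or PR), and a Wilcoxon rank-sum test of
#' score by responder status. Groups without response data are reported
#' with explicit missingness.
#'
#' @param scores data.frame with `sample_id`, `m6ascore`, `group`.
#' @param clin clinical table with a `response` column, aligned.
#' @return list `proportions` (group x category, rows sum to 1 over
#'   non-missing), `counts`, `auc`, `wilcox_p`, `n_missing`.
#' @export
response_summary <- function(scores, clin) {
  stopifnot(all(scores$sample_id == clin$sample_id))
  if (!"response" %in% colnames(clin)) stop_fmt("clinical table has no response column")
  resp <- factor(clin$response, levels = c("CR", "PR", "SD", "PD"))
  ok <- !is.na(resp)
  if (!any(ok)) stop_fmt("no response data")
  for (g in unique(scores$group))
    if (!any(ok & scores$group == g))
      warn_fmt("group '%s' has no response data", g)
  counts <- table(group = scores$group[ok], response = resp[ok])
  props <- prop.table(counts, margin = 1L)
  responder <- resp[ok] %in% c("CR", "PR")
  auc <- if (length(unique(responder)) == 2L)
    rank_auc(scores$m6ascore[ok], responder) else NA_real_
  wp <- if (length(unique(responder)) == 2L)
    stats::wilcox.test(scores$m6ascore[ok] ~ responder)$p.value else NA_real_
  list(proportions = props, counts = counts, auc = auc, wilcox_p = wp,
       n_missing = sum(!ok))
}
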