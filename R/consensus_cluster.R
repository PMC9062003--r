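#' Partition samples with the inner clusterer
#'
#' @param x samples x features numeric matrix.
#' @param k number of clusters (1 <= k <= nrow(x)).
#' @param method `"hierarchical-pearson"` (1 - Pearson correlation distance,
#'   average linkage; falls back to Euclidean when a sample has zero
#'   variance across features) or `"kmeans"`.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
inner_cluster <- function(x, k, method = c("hierarchical-pearson", "kmeans")) {
  method <- match.arg(method)
  n <- nrow(x)
  if (k > n) stop_fmt("inner_cluster: k = %d exceeds n = %d", k, n)
  if (k == 1L) return(rep(1L, n))
  if (method == "kmeans") {
    return(stats::kmeans(x, centers = k, nstart = 5L)$cluster)
  }
  d <- pearson_dist(x)
  unname(stats::cutree(stats::hclust(d, method = "average"), k = k))
}

#' @noRd
pearson_dist <- function(x) {
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0) || ncol(x) < 2L) return(stats::dist(x))
  stats::as.dist(1 - stats::cor(t(x)))
}

#' Resampling-based consensus clustering
#'
#' For each of `reps` repetitions, `floor(p_item * n)` samples are drawn
#' without replacement and partitioned by the inner clusterer; one
#' hierarchical tree per repetition is cut at every k in `k_range` (kmeans is
#' refit per k). The consensus matrix entry for a sample pair is the number
#' of co-clusterings divided by the number of co-samplings; pairs never drawn
#' together get consensus 0 and are counted in `never_cosampled`. The final
#' assignment for each k is average-linkage hierarchical clustering of
#' 1 - M_k; labels are canonicalised by decreasing cluster size, ties broken
#' by smallest member index, so "cluster 1" (pattern A) is reproducible.
#'
#' @param expr genes x samples [expr_matrix()] (samples are clustered).
#' @param k_range candidate cluster numbers, within `[2, n/3]`.
#' @param reps number of resampling repetitions.
#' @param p_item subsampling fraction of samples.
#' @param seed integer seed.
#' @param method inner clusterer, see [inner_cluster()].
#' @param keep_reps store per-repetition subsamples and partitions (for
#'   auditing the consensus counts).
#' @param center_genes median-center each gene before clustering (default
#'   `TRUE`). Per-gene baselines otherwise dominate sample-sample
#'   correlations and wash out subgroup structure; centering is the standard
#'   preprocessing for expression consensus clustering.
#' @return An object of class `"consensus_result"`: list with `consensus`
#'   (per-k matrices), `assignments` (per-k canonical labels), `cdf` (per-k
#'   function values on a common grid), `area`, `delta_area`, `chosen_k`,
#'   `never_cosampled`, and parameters.
#' @export
run_consensus <- function(expr, k_range = 2:5, reps = 1000L, p_item = 0.8,
                          seed = 1L, method = "hierarchical-pearson",
                          keep_reps = FALSE, center_genes = TRUE) {
  vals <- unclass(expr)
  if (center_genes) vals <- vals - apply(vals, 1L, stats::median)
  n <- ncol(vals)
  if (nrow(vals) < 2L) stop_fmt("run_consensus: need >= 2 features")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > floor(n / 3))
    stop_fmt("k_range must lie within [2, n/3] (n = %d)", n)
  if (n < max(k_range) * 3L) stop_fmt("need at least 3 samples per candidate cluster")
  m <- floor(p_item * n)
  xs <- t(vals)                                     # samples x genes
  set.seed(seed)

  cosample <- matrix(0, n, n)
  cocluster <- stats::setNames(
    lapply(k_range, function(k) matrix(0, n, n)), paste0("k", k_range))
  rep_store <- if (keep_reps) vector("list", reps) else NULL

  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m))
    cosample[idx, idx] <- cosample[idx, idx] + 1
    part_k <- if (method == "hierarchical-pearson") {
      tree <- stats::hclust(pearson_dist(xs[idx, , drop = FALSE]), method = "average")
      lapply(k_range, function(k) unname(stats::cutree(tree, k = k)))
    } else {
      lapply(k_range, function(k) inner_cluster(xs[idx, , drop = FALSE], k, method))
    }
    names(part_k) <- paste0("k", k_range)
    for (kn in names(part_k)) {
      same <- outer(part_k[[kn]], part_k[[kn]], "==")
      cocluster[[kn]][idx, idx] <- cocluster[[kn]][idx, idx] + same
    }
    if (keep_reps) rep_store[[r]] <- list(idx = idx, partitions = part_k)
  }

  off <- upper.tri(cosample)
  never <- sum(cosample[off] == 0)
  if (never > 0L)
    warn_fmt("%d sample pair(s) never co-sampled; their consensus is set to 0", never)

  consensus <- lapply(cocluster, function(cc) {
    M <- ifelse(cosample > 0, cc / pmax(cosample, 1), 0)
    diag(M) <- 1
    dimnames(M) <- list(colnames(vals), colnames(vals))
    M
  })

  assignments <- stats::setNames(vector("list", length(k_range)), paste0("k", k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    M <- consensus[[paste0("k", k)]]
    tree <- stats::hclust(stats::as.dist(1 - M), method = "average")
    lab <- unname(stats::cutree(tree, k = k))
    assignments[[i]] <- stats::setNames(canonical_labels(lab), colnames(vals))
  }

  grid <- seq(0, 1, length.out = 1001L)
  cdf <- lapply(consensus, function(M) stats::ecdf(M[off])(grid))
  area <- vapply(cdf, function(f) sum(diff(grid) * (utils::head(f, -1L) + utils::tail(f, -1L)) / 2),
                 numeric(1L))
  res <- structure(list(
    consensus = consensus, assignments = assignments,
    cdf = cdf, cdf_grid = grid, area = area,
    k_range = k_range, reps = reps, p_item = p_item, seed = seed,
    method = method, never_cosampled = never,
    rep_store = rep_store
  ), class = "consensus_result")
  sel <- select_k(res)
  res$delta_area <- sel$delta_area
  res$chosen_k <- sel$chosen_k
  res
}

#' @noRd
canonical_labels <- function(lab) {
  sz <- table(lab)
  first <- vapply(names(sz), function(l) min(which(lab == l)), integer(1L))
  ord <- order(-as.vector(sz), first)
  map <- stats::setNames(seq_along(ord), names(sz)[ord])
  as.integer(map[as.character(lab)])
}

#' Select the number of clusters from consensus CDFs
#'
#' The empirical CDF of the upper-triangle consensus entries is integrated
#' by the trapezoid rule to an area A_k; the relative delta area is
#' `(A_k - A_{k-1}) / A_{k-1}` (for the smallest k, A_k itself). The chosen
#' k is the largest k whose delta area exceeds `threshold`; if none does,
#' the elbow (argmax of delta area) is used. Identical CDFs across k fall
#' back to the smallest candidate with a warning.
#'
#' @param result a `"consensus_result"`.
#' @param threshold relative delta-area threshold (default 0.1).
#' @return list `chosen_k`, `delta_area` (named by k), `area`.
#' @export
select_k <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "consensus_result"))
  if (length(result$k_range) < 2L && length(result$area) < 2L) {
    return(list(chosen_k = result$k_range[1L],
                delta_area = stats::setNames(result$area, paste0("k", result$k_range)),
                area = result$area))
  }
  A <- result$area
  k_range <- result$k_range
  delta <- numeric(length(A))
  delta[1L] <- A[1L]
  if (length(A) > 1L)
    delta[-1L] <- diff(A) / utils::head(A, -1L)
  names(delta) <- paste0("k", k_range)
  if (all(abs(delta[-1L]) < 1e-12) && length(A) > 1L) {
    warn_fmt("consensus CDFs are indistinguishable across k; falling back to k = %d", k_range[1L])
    return(list(chosen_k = k_range[1L], delta_area = delta, area = A))
  }
  above <- which(delta > threshold)
  chosen <- if (length(above) > 0L) k_range[max(above)] else k_range[which.max(delta)]
  list(chosen_k = chosen, delta_area = delta, area = A)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering: %d samples, k in {%s}, %d reps, p_item = %.2f\n",
              ncol(x$consensus[[1L]]), paste(x$k_range, collapse = ","),
              x$reps, x$p_item))
  cat(sprintf("chosen k = %d; delta areas: %s\n", x$chosen_k,
              paste(sprintf("%s=%.3f", names(x$delta_area), x$delta_area), collapse = " ")))
  invisible(x)
}
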