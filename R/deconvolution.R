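#' Signature-based cell-fraction estimation for one bulk sample
#'
#' CIBERSORT-style ν-support-vector regression of a linear-scale bulk
#' profile on a cell-type signature matrix: both sides are standardised
#' over the shared signature genes (mixture vector z-scored; signature
#' matrix standardised by its global mean/sd, preserving relative column
#' structure), a linear-kernel ν-SVR is fitted at each ν in `nus`, and the
#' ν with the lowest reconstruction RMSE wins. Negative coefficients are
#' clipped to zero and the remainder normalised to a simplex. A constrained
#' non-negative least-squares backend (`backend = "nnls"`), operating on the
#' raw linear scale, is exact on noiseless mixtures and serves as the
#' reference for the SVR backend.
#'
#' @param sample_expr named numeric vector, linear-scale expression. If your
#'   data are log2, back-transform with `2^x - 1` first.
#' @param sig [signature_matrix()].
#' @param nus ν grid for the SVR.
#' @param backend `"svr"` (default) or `"nnls"`.
#' @return list `fractions` (named, simplex), `rmse`, `r` (Pearson
#'   correlation of reconstruction), `nu` (chosen ν, `NA` for nnls).
#' @export
deconvolve <- function(sample_expr, sig, nus = c(0.25, 0.5, 0.75),
                       backend = c("svr", "nnls")) {
  backend <- match.arg(backend)
  shared <- intersect(names(sample_expr), rownames(sig))
  if (length(shared) < ncol(sig))
    stop_fmt("deconvolve: only %d shared genes for %d cell types",
             length(shared), ncol(sig))
  y <- as.numeric(sample_expr[shared])
  X <- unclass(sig)[shared, , drop = FALSE]

  finish <- function(w, yv, Xv, nu) {
    w <- pmax(w, 0)
    if (sum(w) == 0) return(NULL)                   # degenerate fit
    recon <- as.vector(Xv %*% w)
    rmse <- sqrt(mean((yv - recon)^2))
    r <- if (stats::sd(recon) > 0) stats::cor(yv, recon) else 0
    list(fractions = stats::setNames(w / sum(w), colnames(Xv)),
         rmse = rmse, r = r, nu = nu)
  }

  nnls_fit <- function() {
    w <- pracma::lsqnonneg(X, y)$x
    fit <- finish(w, y, X, NA_real_)
    if (is.null(fit)) stop_fmt("deconvolve: all coefficients non-positive")
    fit
  }
  if (backend == "nnls") return(nnls_fit())

  yz <- (y - mean(y)) / stats::sd(y)
  Xz <- (X - mean(X)) / stats::sd(as.vector(X))
  fits <- lapply(nus, function(nu) {
    m <- e1071::svm(x = Xz, y = yz, type = "nu-regression", kernel = "linear",
                    nu = nu, scale = FALSE)
    w <- as.vector(t(m$coefs) %*% m$SV)
    finish(w, yz, Xz, nu)
  })
  fits <- fits[!vapply(fits, is.null, logical(1L))]
  if (length(fits) == 0L) {
    warn_fmt("SVR weights all non-positive at every nu; falling back to NNLS")
    return(nnls_fit())
  }
  fits[[which.min(vapply(fits, `[[`, numeric(1L), "rmse"))]]
}

#' Deconvolve every sample of an expression matrix
#'
#' @param expr genes x samples matrix; `linear_scale = FALSE` (default)
#'   treats values as log2 and back-transforms with `2^x - 1`.
#' @param sig [signature_matrix()].
#' @param linear_scale set `TRUE` if `expr` is already linear scale.
#' @param ... passed to [deconvolve()].
#' @return list `fractions` (samples x cell types matrix), `rmse`, `r`
#'   (named vectors).
#' @export
deconvolve_matrix <- function(expr, sig, linear_scale = FALSE, ...) {
  X <- unclass(expr)
  if (!linear_scale) X <- 2^X - 1
  res <- lapply(colnames(X), function(s) deconvolve(X[, s], sig, ...))
  fr <- do.call(rbind, lapply(res, `[[`, "fractions"))
  rownames(fr) <- colnames(X)
  list(fractions = fr,
       rmse = stats::setNames(vapply(res, `[[`, numeric(1L), "rmse"), colnames(X)),
       r = stats::setNames(vapply(res, `[[`, numeric(1L), "r"), colnames(X)))
}

#' Permutation p-value for a deconvolution fit
#'
#' The null reconstruction correlation is obtained by shuffling the sample's
#' expression values across gene labels (draws from the sample's empirical
#' distribution) and re-fitting; p is the fraction of null correlations at
#' or above the observed one, with the add-one correction
#' `(1 + #extreme) / (1 + n_perm)`.
#'
#' @param sample_expr named linear-scale expression vector.
#' @param sig [signature_matrix()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param backend passed to [deconvolve()] (nnls is much faster and is the
#'   default here).
#' @return list `p`, `observed_r`, `null_r`.
#' @export
permutation_p <- function(sample_expr, sig, n_perm = 1000L, seed = 1L,
                          backend = "nnls") {
  obs <- deconvolve(sample_expr, sig, backend = backend)
  set.seed(seed)
  null_r <- vapply(seq_len(n_perm), function(b) {
    y <- sample_expr
    names(y) <- sample(names(y))
    out <- tryCatch(deconvolve(y, sig, backend = backend),
                    error = function(e) list(r = 0))
    out$r
  }, numeric(1L))
  list(p = (1 + sum(null_r >= obs$r)) / (1 + n_perm),
       observed_r = obs$r, null_r = null_r)
}

#' Compare estimated fractions across clusters
#'
#' Kruskal-Wallis test per cell type, BH-adjusted across types.
#'
#' @param fractions samples x cell types matrix.
#' @param cluster_labels cluster label per sample (>= 2 clusters).
#' @return data.frame `cell_type`, `H`, `p`, `q`.
#' @export
compare_fractions <- function(fractions, cluster_labels) {
  if (length(unique(cluster_labels)) < 2L)
    stop_fmt("compare_fractions needs >= 2 clusters")
  stopifnot(nrow(fractions) == length(cluster_labels))
  res <- lapply(colnames(fractions), function(ct) {
    kw <- kruskal_wallis(fractions[, ct], cluster_labels)
    data.frame(cell_type = ct, H = kw$H, p = kw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
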