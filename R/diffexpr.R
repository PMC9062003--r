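#' Invert the trigamma function (Newton iteration)
#' @noRd
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1L))
}

#' Fit the variance prior (d0, s0^2) by method of moments on log variances
#'
#' Sample variances s_g^2 on d df are modelled as s0^2 * F(d, d0) scaled
#' chi-square mixtures; on the log scale, E log s^2 and Var log s^2 involve
#' digamma/trigamma terms, giving moment equations for d0 and s0^2.
#' Returns d0 = Inf (complete shrinkage to s0^2) when the observed spread of
#' log variances does not exceed its sampling expectation.
#' @noRd
fit_f_dist <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = stats::median(s2[s2 > 0], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Two-group moderated t-test with empirical-Bayes variance shrinkage
#'
#' Per-gene two-group comparison on log2 data. Residual (pooled) variances
#' are shrunk toward a common prior: the posterior variance is
#' `(d0*s0^2 + dg*sg^2) / (d0 + dg)` with prior df `d0` and prior variance
#' `s0^2` fitted by method of moments on the log sample variances; the
#' moderated t is referenced to a t distribution on `d0 + dg` df. A
#' zero-variance gene is handled through the shrunk variance (never a
#' division by zero). `logFC` is mean(group A) - mean(group B) in log2
#' units, so positive logFC means up in A.
#'
#' @param expr genes x samples [expr_matrix()] (log2 scale).
#' @param groups two-level factor/character over samples; the first level in
#'   sort order (or factor-level order) is "A".
#' @param method `"moderated"` (default) or `"welch"` (ordinary Welch t, no
#'   shrinkage — provided for cross-checking).
#' @return data.frame per gene: `gene`, `logFC`, `t`, `df`, `p`, `q`,
#'   `direction` (`up_A`/`up_B`); attributes `d0`, `s02`.
#' @export
moderated_ttest <- function(expr, groups, method = c("moderated", "welch")) {
  method <- match.arg(method)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop_fmt("moderated_ttest needs exactly 2 groups")
  ia <- groups == levels(groups)[1L]
  n1 <- sum(ia); n2 <- sum(!ia)
  if (n1 < 2L || n2 < 2L) stop_fmt("each group needs >= 2 samples (got %d, %d)", n1, n2)
  X <- unclass(expr)
  m1 <- rowMeans(X[, ia, drop = FALSE])
  m2 <- rowMeans(X[, !ia, drop = FALSE])
  v1 <- apply(X[, ia, drop = FALSE], 1L, stats::var)
  v2 <- apply(X[, !ia, drop = FALSE], 1L, stats::var)
  lfc <- m1 - m2
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- lfc / sqrt(pmax(se2, 1e-300))
    dfree <- se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)), 1e-300)
    p <- 2 * stats::pt(-abs(tt), dfree)
    d0 <- NA_real_; s02 <- NA_real_
  } else {
    dg <- n1 + n2 - 2
    sg2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
    prior <- fit_f_dist(sg2, dg)
    d0 <- prior$d0; s02 <- prior$s02
    post <- if (is.infinite(d0)) rep(s02, length(sg2)) else
      (d0 * s02 + dg * sg2) / (d0 + dg)
    tt <- lfc / sqrt(post * (1 / n1 + 1 / n2))
    dfree <- rep(if (is.infinite(d0)) Inf else d0 + dg, length(tt))
    p <- 2 * stats::pt(-abs(tt), dfree)
  }
  out <- data.frame(gene = rownames(X), logFC = lfc, t = tt, df = dfree, p = p,
                    q = bh_adjust(p),
                    direction = ifelse(lfc > 0, "up_A", "up_B"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "group_A") <- levels(groups)[1L]
  out
}

#' Flag significant differential genes
#'
#' Applies the joint filter: significant iff `q < q_max` and
#' `|logFC| > lfc_min` (defaults match the adjusted p < 0.05, |log2 FC| > 1
#' convention).
#'
#' @param table result of [moderated_ttest()].
#' @param q_max BH q-value ceiling.
#' @param lfc_min absolute log2 fold-change floor (strict).
#' @return The table with a `significant` column; counts of up_A/up_B flagged
#'   genes in `attr(, "counts")`.
#' @export
filter_degs <- function(table, q_max = 0.05, lfc_min = 1.0) {
  stopifnot(all(c("q", "logFC") %in% colnames(table)))
  table$significant <- !is.na(table$q) & table$q < q_max & abs(table$logFC) > lfc_min
  attr(table, "counts") <- c(
    up_A = sum(table$significant & table$direction == "up_A"),
    up_B = sum(table$significant & table$direction == "up_B"))
  table
}
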