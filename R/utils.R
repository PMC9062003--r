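#' Derive a named random substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; each stage draws
#' from a named substream so stages can be re-simulated independently without
#' perturbing one another. The substream seed is a deterministic 31-bit hash
#' of the root seed and the stream name.
#'
#' @param seed integer root seed.
#' @param name character stream name, e.g. `"expression"`.
#' @return An integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' Rank-based AUC of a score for a binary label
#'
#' Equivalent to the Wilcoxon/Mann-Whitney statistic divided by n1*n0, with
#' ties counted 1/2.
#'
#' @param score numeric score vector.
#' @param label logical or 0/1 vector, `TRUE`/1 = positive.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label))
  ok <- is.finite(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop_fmt("rank_auc: need both positive and negative labels")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)

#' @noRd
hash_config <- function(x) {
  # order-stable structural hash for provenance stamping
  raw <- serialize(x, connection = NULL, version = 2L)
  # fold bytes into a 16-hex-digit string (FNV-1a style, 2 x 32-bit lanes)
  b <- as.integer(raw)
  h1 <- 2166136261; h2 <- 40389
  for (i in seq_along(b)) {
    if (i %% 2L == 1L) h1 <- ((bitwXor(as.integer(h1 %% 2147483647), b[i])) * 16777619) %% 2147483647
    else h2 <- ((bitwXor(as.integer(h2 %% 2147483647), b[i])) * 31) %% 2147483647
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' @noRd
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
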