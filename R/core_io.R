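#' Construct and validate an expression matrix
#'
#' The canonical expression container is a numeric genes x samples matrix on
#' log2 scale (TPM/RMA-normalised upstream), wrapped with class
#' `"expr_matrix"`. Gene and sample identifiers live in `dimnames`.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames sample ids.
#' @return The validated matrix with class `"expr_matrix"`.
#' @export
expr_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_fmt("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_fmt("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_fmt("duplicate gene ids: %s", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_fmt("duplicate sample ids: %s", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop_fmt("expression matrix contains %d missing/non-finite values", sum(!is.finite(values)))
  if (nrow(values) < 2L || ncol(values) < 3L)
    stop_fmt("need at least 2 genes and 3 samples (got %d x %d)", nrow(values), ncol(values))
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene ids, header row holds sample ids. Duplicate gene
#' rows are collapsed by keeping the row with the highest mean expression
#' (with a warning); any non-numeric cell is a parse error naming its
#' coordinates.
#'
#' @param path path to a TSV (or CSV with `sep = ","`).
#' @param sep field separator, tab by default.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_fmt("expression file not found: %s", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "",
                          na.strings = NULL)
  if (ncol(df) < 2L) stop_fmt("expression file %s: missing header or sample columns", path)
  hdr <- colnames(df)[-1L]
  if (anyDuplicated(hdr))
    stop_fmt("duplicate sample id in header: %s",
             paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  genes <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat), dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_fmt("non-numeric cell '%s' at gene row %d (%s), sample column '%s'",
             mat[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], genes[bad[1L, 1L]],
             colnames(mat)[bad[1L, 2L]])
  if (any(is.na(mat)))
    stop_fmt("missing cell at gene '%s'", genes[which(rowSums(is.na(mat)) > 0)[1L]])
  colnames(num) <- hdr
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn_fmt("collapsing %d duplicated gene id(s) by keeping the max-mean row: %s",
             length(dup), paste(utils::head(dup, 5L), collapse = ", "))
    keep <- vapply(split(seq_along(genes), genes), function(idx) {
      idx[which.max(rowMeans(num[idx, , drop = FALSE]))]
    }, integer(1L))
    keep <- sort(unname(keep))  # preserve file order
    num <- num[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(num) <- genes
  expr_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param expr an [expr_matrix()] (or plain named matrix).
#' @param path output path.
#' @param id_col name of the gene-id column in the written header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, id_col = "gene_id") {
  df <- data.frame(rownames(expr), unclass(expr), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write_tsv_table(df, path)
}

#' Read a clinical table
#'
#' Expected columns: `sample_id`, `time` (positive, units declared by the
#' caller's config), `event` (0/1), optional `response` (CR/PR/SD/PD), plus
#' any extra numeric covariates.
#'
#' @param path TSV path.
#' @param sep field separator.
#' @return A `data.frame` with class `"clinical_table"`.
#' @export
read_clinical <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_fmt("clinical file not found: %s", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  clinical_table(df)
}

#' Validate a clinical table
#'
#' @param df data.frame with at least `sample_id`, `time`, `event`.
#' @return The validated data.frame, classed `"clinical_table"`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) stop_fmt("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_fmt("duplicate sample ids in clinical table")
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    stop_fmt("clinical 'time' must be positive and finite")
  if (!all(df$event %in% c(0, 1))) stop_fmt("clinical 'event' must be 0/1")
  if ("response" %in% colnames(df)) {
    bad <- setdiff(stats::na.omit(unique(df$response)), c("CR", "PR", "SD", "PD"))
    if (length(bad) > 0L) stop_fmt("unknown response label(s): %s", paste(bad, collapse = ", "))
  }
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Write a clinical table to TSV
#' @param clin a clinical table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) write_tsv_table(as.data.frame(clin), path)

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are removed (order preserved).
#'
#' @param path GMT path.
#' @return A named list of character vectors with class `"gene_sets"`;
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fmt("GMT file %s: no sets", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1L)) < 3L)
  if (length(short) > 0L)
    stop_fmt("GMT line %d has fewer than 3 tab-separated fields", short[1L])
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names_)) stop_fmt("duplicate set name(s): %s",
                                      paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), names_)
  class(sets) <- "gene_sets"
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors (a `gene_sets` object).
#' @param path output path.
#' @param descriptions optional named character; defaults to the set names.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "description") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell-type signature matrix
#'
#' Genes x cell-types, linear scale, non-negative, every column with positive
#' variance.
#'
#' @param path TSV path; first column gene ids, header cell-type names.
#' @param sep field separator.
#' @return A numeric matrix classed `"signature_matrix"`.
#' @export
read_signature <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  signature_matrix(m)
}

#' Validate a signature matrix
#' @param m numeric genes x cell-types matrix, named dims.
#' @return The matrix, classed `"signature_matrix"`.
#' @export
signature_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_fmt("signature must be a numeric matrix")
  if (anyDuplicated(rownames(m))) stop_fmt("duplicate genes in signature matrix")
  if (any(!is.finite(m)) || any(m < 0)) stop_fmt("signature values must be finite and non-negative")
  v <- apply(m, 2L, stats::var)
  if (any(v <= 0)) stop_fmt("signature column(s) with zero variance: %s",
                            paste(colnames(m)[v <= 0], collapse = ", "))
  class(m) <- c("signature_matrix", class(m))
  m
}

#' Write a signature matrix to TSV
#' @param sig signature matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(gene_id = rownames(sig), unclass(sig), check.names = FALSE)
  write_tsv_table(df, path)
}

#' Align an expression matrix and a clinical table on shared samples
#'
#' Both objects are restricted to the intersection of sample ids, in the
#' expression matrix's order. Idempotent; the number of dropped samples per
#' side is reported via `message()`.
#'
#' @param expr an [expr_matrix()].
#' @param clin a clinical table.
#' @return list with elements `expr` and `clin`.
#' @export
align_samples <- function(expr, clin) {
  shared <- intersect(colnames(expr), clin$sample_id)
  if (length(shared) == 0L) stop_fmt("no shared samples between expression and clinical table")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  d_e <- ncol(expr) - length(shared)
  d_c <- nrow(clin) - length(shared)
  if (d_e + d_c > 0L)
    message(sprintf("align_samples: dropped %d expression, %d clinical sample(s)", d_e, d_c))
  expr2 <- expr[, shared, drop = FALSE]
  class(expr2) <- class(expr)
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr2, clin = clin2)
}
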