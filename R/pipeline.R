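#' Build (or read) a pipeline configuration
#'
#' A plain-YAML configuration with a frozen schema: input paths, clustering
#' settings, DEG thresholds, screening alpha, permutation counts,
#' dichotomisation method, root seed and output directory. Every output
#' carries the seed and a structural hash of the configuration as
#' provenance.
#'
#' @param path YAML file path, or `NULL` to build from arguments.
#' @param ... fields overriding the defaults (used when `path` is `NULL`,
#'   or to override file values).
#' @return A classed list of settings.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    expression = NULL, clinical = NULL, regulators = NULL,
    gene_sets = NULL, signature = NULL,
    time_unit = "months",
    k_range = c(2L, 5L), reps = 1000L, p_item = 0.8,
    deg_q_max = 0.05, deg_lfc_min = 1.0,
    cox_alpha = 0.05, cox_adjust = FALSE,
    n_perm = 1000L,
    dichotomize = "maxstat",
    score_mode = "separate",
    ssgsea_alpha = 0.25,
    auc_quantiles = c(0.25, 0.5, 0.75),
    seed = 1L, out_dir = "modpattern_out")
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop_fmt("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0L)
      stop_fmt("unknown config field(s): %s", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0L)
    stop_fmt("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (f in c("expression", "clinical", "regulators"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop_fmt("config: %s path does not exist: %s", f, cfg[[f]])
  stopifnot(cfg$p_item > 0, cfg$p_item <= 1, cfg$deg_q_max > 0,
            cfg$cox_alpha >= 0, cfg$reps >= 1, cfg$n_perm >= 1)
  cfg$k_range <- seq(min(cfg$k_range), max(cfg$k_range))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1fs)", stage, paste(..., collapse = " "),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full modification-pattern analysis
#'
#' Stages, in order: (1) consensus clustering of the regulator panel into
#' modification patterns; (2) Kaplan-Meier / log-rank between patterns;
#' (3) moderated-t differential genes between patterns; (4) consensus
#' clustering of the significant DEGs into gene clusters; (5) univariate
#' Cox screen of the DEGs; (6) m6Ascore and high/low dichotomisation;
#' (7) microenvironment: signature deconvolution, per-cell-type cluster
#' comparisons, immune/stromal scores, pattern-by-score stratified
#' survival; (8) GSEA between patterns and over-representation of the
#' DEGs; (9) IPCW time-dependent AUC of the score; (10) response summary
#' when a response column is present. Every stage writes its table under
#' `out_dir`; the returned report collects counts and p-values plus
#' provenance (seed, config hash), and cross-tabulations of pattern x gene
#' cluster x score group.
#'
#' A stage failure aborts with the stage name; tables already written are
#' left in place.
#'
#' @param config a [pipeline_config()]. Alternatively pass `cohort` to run
#'   on an in-memory [generate_cohort()] result (paths then unused).
#' @param cohort optional in-memory cohort (list with `expr`, `clin`,
#'   `signature`, `gene_sets`, `truth$regulators`).
#' @return A `"run_report"` list.
#' @export
run_pattern_analysis <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list(seed = seed, config_hash = hash_config(unclass(config)))
  stage <- "load"
  t0 <- as.numeric(Sys.time())
  out <- function(f) file.path(config$out_dir, f)

  run_stage <- function(name, fn) {
    stage <<- name
    tryCatch(fn(), error = function(e)
      stop_fmt("stage '%s' failed: %s (partial outputs kept in %s)",
               name, conditionMessage(e), config$out_dir))
  }

  # ---- inputs -------------------------------------------------------------
  dat <- run_stage("load", function() {
    if (!is.null(cohort)) {
      list(expr = cohort$expr, clin = cohort$clin, sig = cohort$signature,
           sets = cohort$gene_sets, regulators = cohort$truth$regulators)
    } else {
      expr <- read_expression(config$expression)
      clin <- read_clinical(config$clinical)
      regs <- readLines(config$regulators, warn = FALSE)
      sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets) else NULL
      sig <- if (!is.null(config$signature)) read_signature(config$signature) else NULL
      list(expr = expr, clin = clin, sig = sig, sets = sets, regulators = regs)
    }
  })
  al <- align_samples(dat$expr, dat$clin)
  expr <- al$expr; clin <- al$clin
  regs <- intersect(dat$regulators, rownames(expr))
  if (length(regs) < 2L) stop_fmt("stage 'load' failed: < 2 regulator genes in matrix")
  stage_log("load", t0, sprintf("%d genes x %d samples, %d regulators",
                                nrow(expr), ncol(expr), length(regs)))

  # ---- (1) patterns from the regulator panel ------------------------------
  t0 <- as.numeric(Sys.time())
  cons <- run_stage("consensus_patterns", function()
    run_consensus(expr[regs, , drop = FALSE], k_range = config$k_range,
                  reps = config$reps, p_item = config$p_item,
                  seed = substream_seed(seed, "consensus_patterns")))
  pattern <- LETTERS[cons$assignments[[paste0("k", cons$chosen_k)]]]
  names(pattern) <- colnames(expr)
  write_tsv_table(data.frame(sample_id = names(pattern), pattern = pattern),
                  out("patterns.tsv"))
  report$chosen_k <- cons$chosen_k
  report$cluster_sizes <- as.list(table(pattern))
  stage_log("consensus_patterns", t0, sprintf("chosen k = %d", cons$chosen_k))

  # ---- (2) survival between patterns --------------------------------------
  t0 <- as.numeric(Sys.time())
  lr <- run_stage("pattern_survival", function()
    logrank_test(clin$time, clin$event, pattern))
  report$pattern_logrank_p <- lr$p
  stage_log("pattern_survival", t0, sprintf("log-rank p = %.3g", lr$p))

  # ---- (3) differential genes ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  degs <- run_stage("diffexpr", function() {
    tab <- moderated_ttest(expr, pattern)
    filter_degs(tab, q_max = config$deg_q_max, lfc_min = config$deg_lfc_min)
  })
  write_tsv_table(degs, out("degs.tsv"))
  deg_genes <- degs$gene[degs$significant]
  report$deg_counts <- as.list(attr(degs, "counts"))
  report$n_deg <- length(deg_genes)
  stage_log("diffexpr", t0, sprintf("%d significant DEGs", length(deg_genes)))

  # ---- (4) gene clusters from the DEGs ------------------------------------
  t0 <- as.numeric(Sys.time())
  gene_cluster <- run_stage("consensus_gene_clusters", function() {
    if (length(deg_genes) < 2L) stop_fmt("fewer than 2 significant DEGs")
    gc <- run_consensus(expr[deg_genes, , drop = FALSE], k_range = config$k_range,
                        reps = config$reps, p_item = config$p_item,
                        seed = substream_seed(seed, "consensus_gene_clusters"))
    stats::setNames(LETTERS[gc$assignments[[paste0("k", gc$chosen_k)]]], colnames(expr))
  })
  write_tsv_table(data.frame(sample_id = names(gene_cluster), gene_cluster = gene_cluster),
                  out("gene_clusters.tsv"))
  report$gene_cluster_sizes <- as.list(table(gene_cluster))
  report$gene_cluster_logrank_p <- logrank_test(clin$time, clin$event, gene_cluster)$p
  stage_log("consensus_gene_clusters", t0, "done")

  # ---- (5) prognostic screen ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  screen <- run_stage("cox_screen", function()
    screen_prognostic(expr[deg_genes, , drop = FALSE], clin,
                      alpha = config$cox_alpha, adjust = config$cox_adjust))
  write_tsv_table(screen, out("cox_screen.tsv"))
  report$prognostic_counts <- list(
    protective = sum(screen$role == "protective"),
    risk = sum(screen$role == "risk"))
  stage_log("cox_screen", t0, sprintf("%d protective, %d risk",
                                      report$prognostic_counts$protective,
                                      report$prognostic_counts$risk))

  # ---- (6) score + dichotomisation ----------------------------------------
  t0 <- as.numeric(Sys.time())
  scores <- run_stage("m6ascore", function() {
    sc <- compute_m6ascore(expr, screen, mode = config$score_mode)
    dichotomize(sc, clin, method = config$dichotomize)
  })
  write_tsv_table(scores, out("scores.tsv"))
  report$score_group_sizes <- as.list(table(scores$group))
  report$score_logrank_p <- logrank_test(clin$time, clin$event, scores$group)$p
  stage_log("m6ascore", t0, sprintf("high/low log-rank p = %.3g", report$score_logrank_p))

  # ---- (7) microenvironment -----------------------------------------------
  if (!is.null(dat$sig)) {
    t0 <- as.numeric(Sys.time())
    tme <- run_stage("deconvolution", function() {
      dec <- deconvolve_matrix(expr, dat$sig)
      cmp <- compare_fractions(dec$fractions, pattern)
      list(dec = dec, cmp = cmp)
    })
    write_tsv_table(data.frame(sample_id = rownames(tme$dec$fractions),
                               tme$dec$fractions, check.names = FALSE),
                    out("fractions.tsv"))
    write_tsv_table(tme$cmp, out("fraction_tests.tsv"))
    report$tme_significant_types <- tme$cmp$cell_type[tme$cmp$q < 0.05]
    stage_log("deconvolution", t0, "done")
  }
  if (!is.null(dat$sets) &&
      all(c("immune_signature", "stromal_signature") %in% names(dat$sets))) {
    t0 <- as.numeric(Sys.time())
    est <- run_stage("estimate_scores", function()
      estimate_scores(expr, dat$sets$immune_signature, dat$sets$stromal_signature,
                      alpha = config$ssgsea_alpha))
    write_tsv_table(est, out("immune_stromal.tsv"))
    report$immune_score_by_pattern <- vapply(
      split(est$immune_score, pattern), mean, numeric(1L))
    strat <- run_stage("stratified_survival", function() {
      hi <- ifelse(est$immune_score > stats::median(est$immune_score), "HIS", "LIS")
      stratified_survival(clin, pattern, hi)
    })
    report$stratified_logrank_p <- strat$p
    stage_log("estimate_scores", t0, "done")
  }

  # ---- (8) enrichment ------------------------------------------------------
  if (!is.null(dat$sets)) {
    t0 <- as.numeric(Sys.time())
    gs <- run_stage("gsea", function()
      gsea(expr, pattern, dat$sets, n_perm = config$n_perm,
           seed = substream_seed(seed, "gsea")))
    write_tsv_table(gs, out("gsea.tsv"))
    report$gsea_significant <- gs$set[gs$q < 0.05]
    if (length(deg_genes) > 0L) {
      or <- run_stage("ora", function() ora(deg_genes, rownames(expr), dat$sets))
      write_tsv_table(or, out("ora.tsv"))
    }
    stage_log("gsea", t0, "done")
  }

  # ---- (9) time-dependent AUC ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  tauc <- run_stage("time_auc", function() {
    ev_t <- stats::quantile(clin$time[clin$event == 1], probs = config$auc_quantiles,
                            names = FALSE)
    # higher m6Ascore = better prognosis, so the risk marker is its negative
    time_dependent_auc(clin$time, clin$event, -scores$m6ascore, ev_t)
  })
  write_tsv_table(tauc, out("time_auc.tsv"))
  report$time_auc <- stats::setNames(tauc$auc, sprintf("t%.3g", tauc$time))
  stage_log("time_auc", t0, "done")

  # ---- (10) response -------------------------------------------------------
  if ("response" %in% colnames(clin) && any(!is.na(clin$response))) {
    t0 <- as.numeric(Sys.time())
    rs <- run_stage("response", function() response_summary(scores, clin))
    write_tsv_table(as.data.frame(rs$proportions), out("response_proportions.tsv"))
    report$response_auc <- rs$auc
    report$response_wilcox_p <- rs$wilcox_p
    stage_log("response", t0, sprintf("responder AUC = %.3f", rs$auc))
  }

  # ---- cross-tabulations (the alluvial quantities) -------------------------
  xt <- as.data.frame(table(pattern = pattern, gene_cluster = gene_cluster,
                            score_group = scores$group))
  write_tsv_table(xt, out("crosstab.tsv"))
  report$crosstab <- xt
  report$pattern <- pattern
  report$gene_cluster <- gene_cluster
  report$scores <- scores

  jsonlite::write_json(
    report[c("seed", "config_hash", "chosen_k", "cluster_sizes", "n_deg",
             "deg_counts", "prognostic_counts", "score_group_sizes",
             "pattern_logrank_p", "gene_cluster_logrank_p", "score_logrank_p")],
    out("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "run_report"
  report
}

#' Kaplan-Meier curves and global log-rank over combined strata
#'
#' Crosses two factors, drops empty strata with a warning, fits a KM curve
#' per stratum and a global log-rank test across all strata
#' (df = strata - 1). With a constant second factor this reduces exactly to
#' the two-group analysis of the first.
#'
#' @param clin clinical table.
#' @param factor1,factor2 per-sample labels.
#' @return list `strata` (named list of KM curves), `chi2`, `df`, `p`.
#' @export
stratified_survival <- function(clin, factor1, factor2) {
  stopifnot(nrow(clin) == length(factor1), nrow(clin) == length(factor2))
  if (length(unique(factor1)) < 2L) stop_fmt("factor1 needs >= 2 levels")
  combo <- factor(paste(factor1, factor2, sep = "/"))
  combo <- droplevels(combo)
  if (nlevels(combo) < 2L) stop_fmt("fewer than 2 nonempty strata")
  km <- lapply(levels(combo), function(l) {
    idx <- combo == l
    km_estimate(clin$time[idx], clin$event[idx])
  })
  names(km) <- levels(combo)
  lr <- logrank_test(clin$time, clin$event, combo)
  list(strata = km, chi2 = lr$chi2, df = lr$df, p = lr$p)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("modpattern run (seed %d, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("  patterns: k = %d, sizes %s, log-rank p = %.3g\n",
              x$chosen_k, paste(unlist(x$cluster_sizes), collapse = "/"),
              x$pattern_logrank_p))
  cat(sprintf("  DEGs: %d (up_A %d / up_B %d)\n", x$n_deg,
              x$deg_counts$up_A, x$deg_counts$up_B))
  cat(sprintf("  prognostic: %d protective / %d risk\n",
              x$prognostic_counts$protective, x$prognostic_counts$risk))
  cat(sprintf("  score groups: %s, log-rank p = %.3g\n",
              paste(unlist(x$score_group_sizes), collapse = "/"),
              x$score_logrank_p))
  invisible(x)
}
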