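#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: two latent sample clusters with differential expression of a
#' small regulator panel, up/down differential-gene blocks that double as
#' protective/risk prognostic genes, bulk expression built as a linear-scale
#' mixture of cell-type signatures with cluster-dependent mixing fractions,
#' exponential survival whose hazard decreases with a latent per-sample
#' score, uniform censoring calibrated to a target rate, and a response
#' label correlated with the latent score.
#'
#' @param n_samples total samples.
#' @param cluster_proportions length-2 positive vector summing to 1.
#' @param n_regulators size of the regulator panel clustered downstream.
#' @param regulator_effect log2 mean shift of regulators between clusters.
#' @param n_protective,n_risk,n_null counts of protective / risk / null genes.
#' @param deg_effect log2 shift of protective genes (up in cluster A) and
#'   risk genes (up in cluster B).
#' @param noise_sd Gaussian noise s.d. on the log2 scale.
#' @param baseline_hazard exponential event rate at latent score 0.
#' @param score_log_hr log hazard-ratio per unit latent score (positive value
#'   means higher score = lower hazard).
#' @param censoring_rate target censored fraction in \[0, 1).
#' @param weibull_shape shape of the event-time distribution; 1 = exponential.
#' @param n_cell_types number of cell types in the signature matrix.
#' @param markers_per_type marker genes per cell type.
#' @param fraction_shift multiplicative tilt of the immune/stromal Dirichlet
#'   weights in cluster B (0 = no tilt).
#' @param response_intercept,response_logit_slope logit model of
#'   P(responder = CR or PR) given latent score.
#' @param n_null_sets random gene sets added to the bundled collection.
#' @param seed root seed; named substreams derive from it.
#' @return A classed list of settings.
#' @export
cohort_config <- function(n_samples = 200L,
                          cluster_proportions = c(0.5, 0.5),
                          n_regulators = 25L,
                          regulator_effect = 1.5,
                          n_protective = 40L,
                          n_risk = 30L,
                          n_null = 200L,
                          deg_effect = 2,
                          noise_sd = 1,
                          baseline_hazard = 0.08,
                          score_log_hr = 0.8,
                          censoring_rate = 0.3,
                          weibull_shape = 1,
                          n_cell_types = 5L,
                          markers_per_type = 8L,
                          fraction_shift = 1,
                          response_intercept = -0.5,
                          response_logit_slope = 1.5,
                          n_null_sets = 5L,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$cluster_proportions) != 2L || any(cfg$cluster_proportions <= 0) ||
      abs(sum(cfg$cluster_proportions) - 1) > 1e-8)
    stop_fmt("cluster_proportions must be 2 positive values summing to 1")
  for (f in c("n_samples", "n_regulators", "n_protective", "n_risk", "n_null",
              "n_cell_types", "markers_per_type", "n_null_sets"))
    if (!is_count(cfg[[f]])) stop_fmt("%s must be a non-negative integer", f)
  if (cfg$noise_sd <= 0) stop_fmt("noise_sd must be positive")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop_fmt("censoring_rate must be in [0, 1)")
  if (cfg$n_samples < 6L) stop_fmt("need at least 6 samples")
  if (any(round(cfg$n_samples * cfg$cluster_proportions) < 1))
    stop_fmt("infeasible config: a cluster would get 0 samples")
  if (cfg$n_cell_types < 2L) stop_fmt("need at least 2 cell types")
  class(cfg) <- "cohort_config"
  cfg
}

#' Calibrate a uniform censoring window to a target censored fraction
#'
#' Censoring times are Uniform(0, b) independent of events. For event rates
#' `rates` (per subject), the expected censored fraction is
#' `mean((1 - exp(-rates*b)) / (rates*b))`, which decreases from 1 to 0 in
#' `b`; the window is found by root solving. A target of 0 returns `Inf`
#' (no censoring).
#'
#' @param rate_target target censored fraction in \[0, 1).
#' @param rates per-subject exponential event rates (or a single rate).
#' @return Upper bound `b` of the censoring window.
#' @export
censoring_calibration <- function(rate_target, rates) {
  if (rate_target >= 1 || rate_target < 0) stop_fmt("rate_target must be in [0, 1)")
  stopifnot(all(rates > 0))
  if (rate_target == 0) return(Inf)
  cens_frac <- function(b) mean((1 - exp(-rates * b)) / (rates * b))
  hi <- 1 / min(rates)
  while (cens_frac(hi) > rate_target) hi <- hi * 2
  stats::uniroot(function(b) cens_frac(b) - rate_target,
                 lower = 1e-9, upper = hi, tol = 1e-10)$root
}

#' @noRd
rdirichlet_mat <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate a synthetic cohort with ground truth
#'
#' @param config a [cohort_config()].
#' @return A list with components `expr` ([expr_matrix()], log2 scale),
#'   `clin` (clinical table with `response`), `signature`
#'   ([signature_matrix()]), `gene_sets` (bundled collection: protective set,
#'   risk set, immune and stromal signatures, random null sets), and `truth`
#'   (cluster labels, latent score, gene roles, true mixing fractions).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples

  # --- cluster labels (balanced assignment, then shuffled) -----------------
  set.seed(substream_seed(config$seed, "clusters"))
  n_a <- round(n * config$cluster_proportions[1L])
  if (n_a < 1L || n - n_a < 1L) stop_fmt("infeasible config: empty cluster")
  cluster <- sample(rep(c("A", "B"), times = c(n_a, n - n_a)))
  samples <- sprintf("S%03d", seq_len(n))
  in_a <- cluster == "A"

  # --- cell types, signatures and mixing fractions -------------------------
  set.seed(substream_seed(config$seed, "signature"))
  base_types <- c("immune_T", "immune_myeloid", "stromal_fibroblast",
                  "endothelial", "tumor")
  types <- if (config$n_cell_types <= 5L) base_types[seq_len(config$n_cell_types)] else
    c(base_types, sprintf("type%d", seq_len(config$n_cell_types - 5L)))
  g_sig <- as.vector(vapply(types, function(t)
    sprintf("SIG_%s_%02d", t, seq_len(config$markers_per_type)), character(config$markers_per_type)))
  sig <- matrix(stats::runif(length(g_sig) * length(types), 1, 8),
                nrow = length(g_sig), dimnames = list(g_sig, types))
  for (j in seq_along(types)) {            # markers strongly up in their own type
    own <- ((j - 1L) * config$markers_per_type + 1L):(j * config$markers_per_type)
    sig[own, j] <- stats::runif(config$markers_per_type, 60, 140)
  }
  sig <- signature_matrix(sig)

  alpha <- rep(2, length(types))
  names(alpha) <- types
  tilt <- grepl("^immune|^stromal", types)
  alpha_b <- alpha
  alpha_b[tilt] <- alpha[tilt] * (1 + config$fraction_shift)
  set.seed(substream_seed(config$seed, "fractions"))
  frac <- matrix(NA_real_, n, length(types), dimnames = list(samples, types))
  frac[in_a, ] <- rdirichlet_mat(sum(in_a), alpha)
  frac[!in_a, ] <- rdirichlet_mat(sum(!in_a), alpha_b)

  # --- expression ----------------------------------------------------------
  set.seed(substream_seed(config$seed, "expression"))
  g_reg <- sprintf("REG%03d", seq_len(config$n_regulators))
  g_pro <- sprintf("PROT%03d", seq_len(config$n_protective))
  g_rsk <- sprintf("RISK%03d", seq_len(config$n_risk))
  g_nul <- sprintf("NULL%03d", seq_len(config$n_null))
  genes <- c(g_reg, g_pro, g_rsk, g_nul, g_sig)

  mu <- stats::runif(length(genes), 4, 9)           # per-gene log2 baseline
  names(mu) <- genes
  X <- matrix(mu, length(genes), n, dimnames = list(genes, samples))
  # regulator panel: half shifted up in A, half up in B
  if (length(g_reg) > 0L) {
    up_a <- g_reg[seq_len(ceiling(length(g_reg) / 2))]
    up_b <- setdiff(g_reg, up_a)
    X[up_a, in_a] <- X[up_a, in_a] + config$regulator_effect
    X[up_b, !in_a] <- X[up_b, !in_a] + config$regulator_effect
  }
  # differential blocks: protective up in A, risk up in B
  X[g_pro, in_a] <- X[g_pro, in_a] + config$deg_effect
  X[g_rsk, !in_a] <- X[g_rsk, !in_a] + config$deg_effect
  # signature genes carry the linear-scale mixture signal
  mix <- unclass(sig) %*% t(frac) * 30               # scale into a realistic TPM range
  X[g_sig, ] <- log2(mix + 1)
  X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X))

  roles <- stats::setNames(rep("null", length(genes)), genes)
  roles[g_reg] <- "regulator"
  roles[g_pro] <- "protective"
  roles[g_rsk] <- "risk"
  roles[g_sig] <- "signature"

  # --- latent score and survival ------------------------------------------
  zrow <- function(m) (m - rowMeans(m)) / apply(m, 1L, stats::sd)
  latent <- colMeans(zrow(X[g_pro, , drop = FALSE])) -
    colMeans(zrow(X[g_rsk, , drop = FALSE]))
  rate <- config$baseline_hazard * exp(-config$score_log_hr * latent)
  set.seed(substream_seed(config$seed, "survival"))
  if (config$weibull_shape == 1) {
    t_event <- stats::rexp(n, rate)
  } else {
    # proportional-hazards Weibull: S(t) = exp(-rate * t^shape)
    t_event <- (stats::rexp(n, 1) / rate)^(1 / config$weibull_shape)
  }
  b <- censoring_calibration(config$censoring_rate, rates = rate)
  t_cens <- if (is.finite(b)) stats::runif(n, 0, b) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, 1e-6)

  # --- response ------------------------------------------------------------
  set.seed(substream_seed(config$seed, "response"))
  p_resp <- stats::plogis(config$response_intercept + config$response_logit_slope * latent)
  responder <- stats::rbinom(n, 1L, p_resp) == 1L
  response <- ifelse(responder,
                     sample(c("CR", "PR"), n, replace = TRUE, prob = c(0.35, 0.65)),
                     sample(c("SD", "PD"), n, replace = TRUE, prob = c(0.4, 0.6)))

  clin <- clinical_table(data.frame(
    sample_id = samples, time = time, event = event, response = response,
    stringsAsFactors = FALSE))

  # --- bundled gene sets ----------------------------------------------------
  set.seed(substream_seed(config$seed, "gene_sets"))
  sets <- list(
    protective_block = g_pro,
    risk_block = g_rsk,
    immune_signature = g_sig[grepl("^SIG_immune", g_sig)],
    stromal_signature = g_sig[grepl("^SIG_stromal", g_sig)]
  )
  for (i in seq_len(config$n_null_sets))
    sets[[sprintf("null_set_%02d", i)]] <- sample(genes, 20L)
  sets <- sets[vapply(sets, length, integer(1L)) > 0L]
  attr(sets, "description") <- stats::setNames(names(sets), names(sets))
  class(sets) <- "gene_sets"

  list(
    expr = expr_matrix(X),
    clin = clin,
    signature = sig,
    gene_sets = sets,
    truth = list(
      cluster = stats::setNames(cluster, samples),
      latent_score = stats::setNames(latent, samples),
      gene_roles = roles,
      fractions = frac,
      regulators = g_reg,
      censoring_window = b
    ),
    config = config
  )
}

#' Write a generated cohort to a directory in the package's exchange formats
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clin, file.path(dir, "clinical.tsv"))
  write_signature(cohort$signature, file.path(dir, "signature.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  writeLines(cohort$truth$regulators, file.path(dir, "regulators.txt"))
  truth_df <- data.frame(sample_id = names(cohort$truth$cluster),
                         cluster = cohort$truth$cluster,
                         latent_score = cohort$truth$latent_score)
  write_tsv_table(truth_df, file.path(dir, "truth_samples.tsv"))
  invisible(dir)
}
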