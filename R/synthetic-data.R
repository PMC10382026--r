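# Synthetic cohorts with known ground truth: planted response-signature
# genes in bulk cohorts, planted cluster markers in cell cohorts, and
# survival times whose hazard is tied to a panel score. Every downstream
# stage of the workflow is exercised against these generators.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generators. Expression is drawn
#' directly on the log scale (the convention the rest of the pipeline
#' consumes: library-size normalised, scaled, log-transformed values), so a
#' gene in a sample is Gaussian around `baseline_mean`, shifted by
#' `effect_size_delta` in nonresponders when the gene carries planted signal.
#' Defaults emulate a typical two-class chemotherapy cohort of the size such
#' signatures are evaluated on (50 responders, 38 nonresponders).
#'
#' @param n_genes Number of genes.
#' @param n_samples_R,n_samples_NR Samples per response class.
#' @param n_signal_genes Number of planted signature genes
#'   (`<= n_genes`).
#' @param effect_size_delta Mean log-expression shift of signal genes in
#'   nonresponders.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param baseline_mean Baseline log expression.
#' @param seed Integer seed; identical configurations reproduce cohorts
#'   bit-for-bit. Per-stage sub-seeds are derived by stable hashing so that,
#'   e.g., enlarging the gene space does not perturb survival draws.
#' @param survival_baseline_hazard Baseline hazard per month (> 0).
#' @param survival_beta Log-hazard per unit of the true panel score.
#' @param censor_rate Probability a subject is censored, in \[0, 1\].
#'   Censoring is administrative: a censored subject is observed for a
#'   uniform fraction of its drawn event time.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_samples_R = 50, n_samples_NR = 38,
                              n_signal_genes = 20, effect_size_delta = 1,
                              noise_sd = 1, baseline_mean = 2, seed = 1L,
                              survival_baseline_hazard = 0.03,
                              survival_beta = 1, censor_rate = 0.3) {
  n_genes <- .assert_count(n_genes, "n_genes", 1L)
  n_samples_R <- .assert_count(n_samples_R, "n_samples_R", 1L)
  n_samples_NR <- .assert_count(n_samples_NR, "n_samples_NR", 1L)
  n_signal_genes <- .assert_count(n_signal_genes, "n_signal_genes", 0L)
  if (n_signal_genes > n_genes) {
    stop("n_signal_genes must not exceed n_genes", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate > 1) {
    stop("censor_rate must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(survival_baseline_hazard) || survival_baseline_hazard <= 0) {
    stop("survival_baseline_hazard must be > 0", call. = FALSE)
  }
  seed <- .assert_count(seed, "seed", 0L)
  structure(list(
    n_genes = n_genes, n_samples_R = n_samples_R, n_samples_NR = n_samples_NR,
    n_signal_genes = n_signal_genes,
    effect_size_delta = as.numeric(effect_size_delta),
    noise_sd = as.numeric(noise_sd), baseline_mean = as.numeric(baseline_mean),
    seed = seed,
    survival_baseline_hazard = as.numeric(survival_baseline_hazard),
    survival_beta = as.numeric(survival_beta),
    censor_rate = as.numeric(censor_rate)
  ), class = "simulation_config")
}

.gene_ids <- function(n) sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))

#' Simulate a bulk two-class expression cohort
#'
#' Draws a gene-by-sample log-expression matrix with `n_signal_genes` genes
#' up-shifted by `effect_size_delta` in nonresponders, assigns R/NR labels,
#' and attaches exponential survival times whose hazard follows the true
#' panel score (the standardized mean expression of the planted genes).
#' The single-gene discrimination of a planted gene converges to
#' `pnorm(delta / (noise_sd * sqrt(2)))` in AUC, which anchors the
#' generator's effect-size calibration.
#'
#' @param config A [simulation_config()].
#' @param replicate Replicate index (default 1). Replicates share the same
#'   planted signal genes -- the population is fixed by `seed` -- but draw
#'   fresh samples, noise, and survival, which is what an independent
#'   validation cohort from the same population means.
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   (matrix), `phenotype` (data frame: `sample_id`, `response`,
#'   `time_months`, `event`), `truth` (planted gene ids), and
#'   `panel_score_true` (named per-sample score, variance 1).
#' @export
simulate_bulk_cohort <- function(config, replicate = 1L) {
  replicate <- .assert_count(replicate, "replicate", 1L)
  stopifnot(inherits(config, "simulation_config"))
  genes <- .gene_ids(config$n_genes)
  samples <- c(sprintf("R_%03d", seq_len(config$n_samples_R)),
               sprintf("NR_%03d", seq_len(config$n_samples_NR)))
  response <- rep(c("R", "NR"), c(config$n_samples_R, config$n_samples_NR))

  set.seed(.stage_seed(config$seed, "signal_genes"))
  truth <- if (config$n_signal_genes > 0) {
    .lex_sort(sample(genes, config$n_signal_genes))
  } else {
    character(0)
  }

  set.seed(.stage_seed(config$seed, paste0("expression_", replicate)))
  expr <- matrix(
    stats::rnorm(config$n_genes * length(samples),
                 mean = config$baseline_mean, sd = config$noise_sd),
    nrow = config$n_genes, dimnames = list(genes, samples)
  )
  if (length(truth)) {
    expr[truth, response == "NR"] <- expr[truth, response == "NR"] +
      config$effect_size_delta
  }

  score <- if (length(truth)) {
    m <- colMeans(expr[truth, , drop = FALSE])
    as.numeric(scale(m))[seq_along(m)]
  } else {
    rep(0, length(samples))
  }
  names(score) <- samples

  surv <- simulate_survival(score, config, replicate = replicate)
  phenotype <- data.frame(sample_id = samples, response = response,
                          time_months = surv$time_months, event = surv$event,
                          stringsAsFactors = FALSE)
  structure(list(expression = expr, phenotype = phenotype, truth = truth,
                 panel_score_true = score, config = config),
            class = "synthetic_cohort")
}

#' Simulate clustered single-cell-like expression
#'
#' Each cluster receives its own block of marker genes, up-shifted by
#' `effect_size_delta` only in cells of that cluster. Cells carry an R/NR
#' origin label drawn per cluster with probability `nr_fraction`, so a
#' cluster can be made arbitrarily nonresponder-enriched.
#'
#' @param config A [simulation_config()] (gene count, shift, noise, seed).
#' @param n_clusters Number of clusters.
#' @param cells_per_cluster Cells in each cluster.
#' @param markers_per_cluster Planted marker genes per cluster; requires
#'   `n_clusters * markers_per_cluster <= n_genes`.
#' @param nr_fraction Probability a cell is labeled NR; scalar or one value
#'   per cluster.
#' @return A `synthetic_cohort` whose phenotype has columns `sample_id`,
#'   `response`, `cluster`, and whose `truth` is a per-cluster list of
#'   planted markers.
#' @export
simulate_cell_clusters <- function(config, n_clusters, cells_per_cluster,
                                   markers_per_cluster, nr_fraction = 0.5) {
  stopifnot(inherits(config, "simulation_config"))
  n_clusters <- .assert_count(n_clusters, "n_clusters", 1L)
  cells_per_cluster <- .assert_count(cells_per_cluster, "cells_per_cluster", 1L)
  markers_per_cluster <- .assert_count(markers_per_cluster, "markers_per_cluster", 0L)
  if (n_clusters * markers_per_cluster > config$n_genes) {
    stop("insufficient genes: n_clusters * markers_per_cluster exceeds n_genes",
         call. = FALSE)
  }
  if (!length(nr_fraction) %in% c(1L, n_clusters) ||
      any(nr_fraction < 0 | nr_fraction > 1)) {
    stop("nr_fraction must be a scalar or per-cluster vector in [0, 1]",
         call. = FALSE)
  }
  nr_fraction <- rep_len(nr_fraction, n_clusters)

  genes <- .gene_ids(config$n_genes)
  cluster_names <- paste0("C", seq_len(n_clusters) - 1L)
  truth <- lapply(seq_len(n_clusters), function(c) {
    genes[((c - 1L) * markers_per_cluster + 1L):((c - 1L) * markers_per_cluster + markers_per_cluster)]
  })
  names(truth) <- cluster_names
  if (markers_per_cluster == 0L) truth <- lapply(truth, function(x) character(0))

  n_cells <- n_clusters * cells_per_cluster
  cluster <- rep(cluster_names, each = cells_per_cluster)
  cells <- sprintf("%s_cell%04d", cluster, sequence(rep(cells_per_cluster, n_clusters)))

  set.seed(.stage_seed(config$seed, "cell_labels"))
  response <- unlist(lapply(seq_len(n_clusters), function(c) {
    ifelse(stats::runif(cells_per_cluster) < nr_fraction[c], "NR", "R")
  }), use.names = FALSE)

  set.seed(.stage_seed(config$seed, "cell_expression"))
  expr <- matrix(
    stats::rnorm(config$n_genes * n_cells, mean = config$baseline_mean,
                 sd = config$noise_sd),
    nrow = config$n_genes, dimnames = list(genes, cells)
  )
  for (c in seq_len(n_clusters)) {
    if (length(truth[[c]])) {
      in_cluster <- cluster == cluster_names[c]
      expr[truth[[c]], in_cluster] <- expr[truth[[c]], in_cluster] +
        config$effect_size_delta
    }
  }
  phenotype <- data.frame(sample_id = cells, response = response,
                          cluster = cluster, stringsAsFactors = FALSE)
  structure(list(expression = expr, phenotype = phenotype, truth = truth,
                 panel_score_true = NULL, config = config),
            class = "synthetic_cohort")
}

#' Simulate survival linked to a per-sample score
#'
#' Event times are exponential with rate
#' `survival_baseline_hazard * exp(survival_beta * score)`. Censoring is
#' independent: with probability `censor_rate` a subject is administratively
#' censored at a uniform fraction of its drawn event time.
#'
#' @param scores Named (or unnamed) finite numeric vector of per-sample scores.
#' @param config A [simulation_config()] supplying the hazard parameters and
#'   seed.
#' @param replicate Replicate index; fresh draws per replicate under one seed.
#' @return Data frame with `sample_id`, `time_months`, `event` (1 = event,
#'   0 = censored), and attribute `censoring = "administrative-uniform"`.
#' @export
simulate_survival <- function(scores, config, replicate = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  replicate <- .assert_count(replicate, "replicate", 1L)
  if (!is.numeric(scores) || length(scores) == 0L || any(!is.finite(scores))) {
    stop("scores must be finite numeric values", call. = FALSE)
  }
  ids <- names(scores)
  if (is.null(ids)) ids <- sprintf("s_%03d", seq_along(scores))
  set.seed(.stage_seed(config$seed, paste0("survival_", replicate)))
  rate <- config$survival_baseline_hazard * exp(config$survival_beta * scores)
  t_event <- stats::rexp(length(scores), rate = rate)
  censored <- stats::runif(length(scores)) < config$censor_rate
  time <- ifelse(censored, t_event * stats::runif(length(scores)), t_event)
  out <- data.frame(sample_id = ids, time_months = time,
                    event = as.integer(!censored), stringsAsFactors = FALSE)
  attr(out, "censoring") <- "administrative-uniform"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  if (!is.null(x$phenotype$response)) {
    print(table(x$phenotype$response))
  }
  n_truth <- if (is.list(x$truth)) sum(lengths(x$truth)) else length(x$truth)
  cat(sprintf("planted signal genes: %d\n", n_truth))
  invisible(x)
}
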