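# Independent oracles used across the suite. These deliberately re-derive
# each quantity by the most naive route available (enumeration, brute
# force, direct formula transcription) and never call the package paths
# they are checking.

# AUC as pairwise concordance, ties counted one half, O(n^2).
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Tie-corrected normal approximation for the two-sided Wilcoxon rank sum
# p-value, transcribed directly from the textbook formula.
oracle_wilcoxon_normal <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  2 * pnorm(-abs((U - nx * ny / 2) / sigma))
}

# GSEA enrichment score by explicit step-by-step accumulation over the
# ranked list (no cumsum), extremum by absolute deviation.
oracle_es <- function(stats_sorted, is_hit, weight) {
  n <- length(stats_sorted)
  nh <- sum(is_hit)
  denom_hit <- sum(abs(stats_sorted[is_hit])^weight)
  running <- 0
  vmax <- 0
  vmin <- 0
  for (i in seq_len(n)) {
    running <- running + if (is_hit[i]) {
      abs(stats_sorted[i])^weight / denom_hit
    } else {
      -1 / (n - nh)
    }
    vmax <- max(vmax, running)
    vmin <- min(vmin, running)
  }
  unname(if (vmax + vmin > 1e-12) vmax else vmin)
}

# GSVA score for one set in one sample, following the published recipe
# step by step on raw numbers: kernel CDF, cross-gene ranks, symmetric
# rank statistic, weighted KS walk, max.pos + max.neg deviation.
oracle_gsva_one_sample <- function(expr, set_rows, j, tau = 1) {
  p <- nrow(expr); n <- ncol(expr)
  z <- numeric(p)
  for (i in seq_len(p)) {
    h <- sd(expr[i, ]) / 4
    z[i] <- mean(pnorm((expr[i, j] - expr[i, ]) / h))
  }
  r <- rank(-z, ties.method = "first")
  stat <- abs(p / 2 - r)
  ord <- order(r)
  member <- seq_len(p) %in% set_rows
  v <- 0; vmax <- 0; vmin <- 0
  sw <- sum(stat[set_rows]^tau)
  n_out <- p - length(set_rows)
  for (pos in ord) {
    v <- v + if (member[pos]) stat[pos]^tau / sw else -1 / n_out
    vmax <- max(vmax, v)
    vmin <- min(vmin, v)
  }
  vmax + vmin
}

# Log-rank chi-square from the 2x2 risk tables at each event time,
# hypergeometric variance, transcribed from the definition.
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  obs_minus_exp <- 0
  var_sum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    obs_minus_exp <- obs_minus_exp + (d1 - d * n1 / n)
    if (n > 1) {
      var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  obs_minus_exp^2 / var_sum
}

# Small labeled cohort for classifier tests: planted separators + noise.
make_toy_cohort <- function(n_per_class = 6, n_genes = 8, n_signal = 2,
                            delta = 4, seed = 42) {
  set.seed(seed)
  genes <- sprintf("t%02d", seq_len(n_genes))
  samples <- c(sprintf("R%02d", seq_len(n_per_class)),
               sprintf("N%02d", seq_len(n_per_class)))
  response <- rep(c("R", "NR"), each = n_per_class)
  expr <- matrix(rnorm(n_genes * 2 * n_per_class, mean = 2),
                 nrow = n_genes, dimnames = list(genes, samples))
  if (n_signal > 0) {
    expr[seq_len(n_signal), response == "NR"] <-
      expr[seq_len(n_signal), response == "NR"] + delta
  }
  list(expression = expr,
       phenotype = data.frame(sample_id = samples, response = response,
                              stringsAsFactors = FALSE),
       signal = genes[seq_len(n_signal)])
}

# Brute-force recursive elimination using only the public fit/evaluate
# path: at each cycle evaluate every leave-one-out subpanel by fitting a
# fresh model and measuring resubstitution AUC.
oracle_elimination_cycle <- function(panel, expr, phenotype) {
  aucs <- vapply(seq_along(panel), function(i) {
    sub <- panel[-i]
    res <- tryCatch({
      m <- fit_centroid(expr, phenotype, sub)
      suppressWarnings(evaluate_centroid(m, expr, phenotype)$auc)
    }, error = function(e) 0)
    res
  }, numeric(1))
  best <- max(aucs)
  cand <- which(aucs >= best - 1e-9)
  drop_i <- cand[order(panel[cand], method = "radix")[length(cand)]]
  list(removed = panel[drop_i], best_auc = aucs[drop_i], aucs = aucs)
}
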