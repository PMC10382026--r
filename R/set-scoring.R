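# Single-sample gene-set activity scores (GSVA-style rank statistic with a
# weighted Kolmogorov-Smirnov random walk) and preranked GSEA with a
# gene-label permutation null. Both are used to localize subtype signatures
# to cell clusters and to refine a signature to its response-associated
# leading edge.

# Gene-wise cumulative density across samples. "Gaussian": kernel CDF with
# bandwidth sd/4 (exactly invariant under affine per-gene maps); "ecdf":
# the empirical CDF, a pure rank transform (exactly invariant under any
# monotone per-gene map).
.gene_cdf <- function(expr, kcdf) {
  n <- ncol(expr)
  t(apply(expr, 1L, function(x) {
    if (kcdf == "ecdf") {
      rank(x, ties.method = "average") / n
    } else {
      h <- stats::sd(x) / 4
      rowMeans(stats::pnorm(outer(x, x, "-") / h))
    }
  }))
}

# Weighted KS walk over genes ordered by decreasing per-sample statistic.
# tau weights the symmetric rank statistic |p/2 - r|; the "mx.diff" score is
# the maximum positive plus the maximum negative deviation.
.gsva_walk <- function(stat_ranked, in_set, tau) {
  w <- abs(stat_ranked)^tau
  pos <- w * in_set
  sp <- sum(pos)
  n_out <- length(in_set) - sum(in_set)
  if (sp == 0 || n_out == 0) return(NA_real_)
  v <- cumsum(pos / sp - (!in_set) / n_out)
  max(c(0, v)) + min(c(0, v))
}

#' GSVA-style single-sample gene-set activity scores
#'
#' For each gene, expression is mapped through a cumulative density across
#' samples (`kcdf = "Gaussian"`, kernel bandwidth sd/4, or `"ecdf"`). Within
#' each sample the density values are ranked across genes, converted to the
#' symmetric rank statistic `|p/2 - r|`, and a weighted Kolmogorov-Smirnov
#' random walk (`tau = 1`) over the rank-ordered genes yields each set's
#' score as the maximum positive plus the maximum negative deviation.
#' Constant genes cannot enter the kernel step and are excluded with a
#' warning; sets with fewer than two usable genes are skipped.
#'
#' @param expr Numeric gene-by-sample matrix, at least two samples.
#' @param sets Named list of gene-id vectors.
#' @param kcdf `"Gaussian"` (default) or `"ecdf"`.
#' @param tau Rank-statistic weight exponent (default 1).
#' @param min_size Minimum usable genes per set (default 2).
#' @return Matrix of scores, sets as rows, samples as columns.
#' @export
gsva_scores <- function(expr, sets, kcdf = c("Gaussian", "ecdf"), tau = 1,
                        min_size = 2) {
  kcdf <- match.arg(kcdf)
  .check_expression(expr)
  if (ncol(expr) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (!length(sets) || is.null(names(sets))) {
    stop("sets must be a named list", call. = FALSE)
  }
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from scoring")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  p <- nrow(expr)
  if (p < 2L) stop("fewer than 2 variable genes", call. = FALSE)
  z <- .gene_cdf(expr, kcdf)

  usable <- lapply(sets, function(s) intersect(unique(s), rownames(expr)))
  keep <- lengths(usable) >= min_size
  if (any(!keep)) {
    warning("set(s) skipped (< ", min_size, " usable genes): ",
            paste(utils::head(names(sets)[!keep], 5), collapse = ", "))
  }
  usable <- usable[keep]
  if (!length(usable)) stop("no scoreable gene sets", call. = FALSE)

  scores <- matrix(NA_real_, nrow = length(usable), ncol = ncol(expr),
                   dimnames = list(names(usable), colnames(expr)))
  member <- lapply(usable, function(s) rownames(expr) %in% s)
  for (j in seq_len(ncol(expr))) {
    # rank 1 = highest density value; symmetric statistic peaks at both ends
    r <- rank(-z[, j], ties.method = "first")
    stat <- p / 2 - r
    ord <- order(r)
    stat_ranked <- abs(stat)[ord]
    for (i in seq_along(usable)) {
      scores[i, j] <- .gsva_walk(stat_ranked, member[[i]][ord], tau)
    }
  }
  scores
}

# Enrichment score of one set against a ranked list: weighted KS running
# sum, extremum by absolute deviation. Returns the full walk for callers
# needing the leading edge.
.gsea_es <- function(stats_sorted, hit, weight) {
  n <- length(stats_sorted)
  nh <- sum(hit)
  w <- abs(stats_sorted)^weight
  sw <- sum(w[hit])
  inc <- numeric(n)
  if (sw > 0) inc[hit] <- w[hit] / sw else inc[hit] <- 1 / nh
  inc[!hit] <- -1 / (n - nh)
  v <- cumsum(inc)
  max_p <- max(c(0, v))
  min_p <- min(c(0, v))
  # extremum by absolute deviation; ties (within numerical noise) resolve
  # to the depletion side
  if (max_p + min_p > 1e-12) {
    list(es = max_p, peak = which.max(v), walk = v)
  } else {
    list(es = min_p, peak = which.min(v), walk = v)
  }
}

#' Preranked gene set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score of each set
#' against a ranked gene list, with a sign-stratified gene-label permutation
#' null: permuted scores of the same sign as the observed score form the
#' reference for the p-value and for the normalized score
#' (`nes = es / mean(|permuted es| of the same sign)`). Set p-values are
#' BH-adjusted across sets. The leading edge contains the set members at or
#' before the running-sum extremum (at or after it, for depletion).
#'
#' @param stats Named numeric vector of per-gene ranking scores (no
#'   duplicate names); sorted internally in decreasing order.
#' @param sets Named list of gene-id vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param weight Exponent on `|stats|` (default 1).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame with `set_name`, `size`, `es`, `nes`, `p_value`,
#'   `fdr`, and `leading_edge` (pipe-delimited). Sets with no ranked genes,
#'   or spanning the entire list, are skipped with a warning.
#' @export
gsea_preranked <- function(stats, sets, n_perm = 1000, weight = 1, seed = 1L) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("stats must be named with unique gene ids", call. = FALSE)
  }
  .assert_numeric(stats, "stats")
  n_perm <- .assert_count(n_perm, "n_perm", 100L)
  stats <- sort(stats, decreasing = TRUE)
  genes <- names(stats)
  n <- length(genes)

  rows <- list()
  leading <- list()
  set.seed(.stage_seed(seed, "gsea_permutation"))
  for (nm in names(sets)) {
    members <- intersect(unique(sets[[nm]]), genes)
    if (!length(members)) {
      warning("set '", nm, "' shares no genes with the ranked list; skipped")
      next
    }
    if (length(members) == n) {
      warning("set '", nm, "' spans the entire ranked list; skipped")
      next
    }
    hit <- genes %in% members
    obs <- .gsea_es(stats, hit, weight)
    perm <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, length(members))] <- TRUE
      .gsea_es(stats, h, weight)$es
    }, numeric(1))
    same_sign <- if (obs$es >= 0) perm[perm >= 0] else perm[perm < 0]
    p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    le <- if (obs$es >= 0) {
      genes[which(hit & seq_len(n) <= obs$peak)]
    } else {
      genes[which(hit & seq_len(n) >= obs$peak)]
    }
    leading[[nm]] <- le
    rows[[nm]] <- data.frame(set_name = nm, size = length(members),
                             es = obs$es, nes = nes, p_value = p,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable gene sets", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- adjust_pvalues(out$p_value, "BH")
  out$leading_edge <- vapply(out$set_name, function(nm) {
    paste(leading[[nm]], collapse = "|")
  }, character(1))
  out
}

#' Refine a signature panel to its response-associated leading edge
#'
#' Runs preranked GSEA of the panel against a ranked R-vs-NR gene list and,
#' when the enrichment is significant (`fdr < alpha`) in the requested
#' direction, returns the leading-edge genes as the refined panel. When not
#' significant, the empty vector is returned with a message.
#'
#' @param panel Character vector of signature genes.
#' @param stats Named ranking scores (see [gsea_preranked()]).
#' @param direction `"positive"` (enriched toward the top) or
#'   `"negative"`.
#' @param alpha FDR threshold.
#' @param n_perm,weight,seed Passed to [gsea_preranked()].
#' @return Character vector of leading-edge genes (possibly empty).
#' @export
refine_panel_leading_edge <- function(panel, stats, direction = c("positive", "negative"),
                                      alpha = 0.05, n_perm = 1000, weight = 1,
                                      seed = 1L) {
  direction <- match.arg(direction)
  res <- gsea_preranked(stats, list(panel = panel), n_perm = n_perm,
                        weight = weight, seed = seed)
  ok <- res$fdr[1] < alpha &&
    ((direction == "positive" && res$es[1] > 0) ||
     (direction == "negative" && res$es[1] < 0))
  if (!ok) {
    message("panel not significantly enriched (es = ", signif(res$es[1], 3),
            ", fdr = ", signif(res$fdr[1], 3), "); returning empty refinement")
    return(character(0))
  }
  strsplit(res$leading_edge[1], "|", fixed = TRUE)[[1]]
}
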