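# Differential expression between response classes, one-vs-rest cluster
# markers, and the predictive screening rule that nominates cell subtypes:
# a DE gene list is called predictive when at least half of its top enriched
# gene sets separate responders from nonresponders as classifier panels.

# Fold change on de-logged means with pseudocount 1: expression is log2 of
# normalised counts, so 2^x - 1 undoes the log before averaging.
.avg_log2fc <- function(xa, xb) {
  log2((mean(2^xa - 1) + 1) / (mean(2^xb - 1) + 1))
}

#' Differential expression between two sample groups
#'
#' Per-gene two-sided Wilcoxon rank sum test of `group_a` versus `group_b`
#' with Bonferroni correction over all genes tested; fold changes are
#' computed on de-logged means with a pseudocount of one. Genes with
#' adjusted p below `alpha` are flagged DE.
#'
#' @param expr Numeric gene-by-sample matrix (log scale).
#' @param phenotype Data frame with `sample_id` and the grouping column.
#' @param group_a,group_b Labels to contrast (fold change is a over b).
#' @param group_col Phenotype column holding the labels (default
#'   `"response"`).
#' @param alpha Adjusted-p threshold for the DE flag.
#' @return Data frame with columns `gene`, `avg_log2FC`, `p_value`,
#'   `p_adjusted`, `pct_in`, `pct_out`, `direction`, `is_de`.
#' @export
de_between_conditions <- function(expr, phenotype, group_a = "R", group_b = "NR",
                                  group_col = "response", alpha = 0.05) {
  .check_expression(expr)
  phenotype <- .align_phenotype(expr, phenotype)
  if (!group_col %in% names(phenotype)) {
    stop("phenotype lacks column '", group_col, "'", call. = FALSE)
  }
  labels <- phenotype[[group_col]]
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop(sprintf("need >= 2 samples per group (got %d '%s', %d '%s')",
                 length(ia), group_a, length(ib), group_b), call. = FALSE)
  }
  res <- vapply(seq_len(nrow(expr)), function(g) {
    xa <- expr[g, ia]
    xb <- expr[g, ib]
    c(.avg_log2fc(xa, xb),
      wilcoxon_rank_sum(xa, xb)$p_value,
      mean(xa > 0), mean(xb > 0))
  }, numeric(4))
  out <- data.frame(
    gene = rownames(expr),
    avg_log2FC = res[1, ],
    p_value = res[2, ],
    p_adjusted = adjust_pvalues(res[2, ], "bonferroni"),
    pct_in = res[3, ],
    pct_out = res[4, ],
    stringsAsFactors = FALSE
  )
  out$direction <- ifelse(out$avg_log2FC >= 0, paste0("up_in_", group_a),
                          paste0("up_in_", group_b))
  out$is_de <- out$p_adjusted < alpha
  out
}

#' One-vs-rest cluster marker genes
#'
#' For each cluster, candidate genes must be detected in at least `min_pct`
#' of the cluster's cells and up-shifted by at least `logfc_threshold`
#' (log2) relative to all other cells before testing; surviving candidates
#' are tested by two-sided Wilcoxon rank sum with Bonferroni correction over
#' the candidates of that comparison. Clusters with fewer than three cells
#' are skipped with a warning.
#'
#' @param expr Numeric gene-by-cell matrix (log scale).
#' @param phenotype Data frame with `sample_id` and `cluster` columns.
#' @param min_pct Minimum detection fraction inside the cluster.
#' @param logfc_threshold Minimum `avg_log2FC` (cluster vs rest).
#' @param alpha Adjusted-p threshold for the marker flag.
#' @return Named list (one element per tested cluster) of data frames with
#'   the same columns as [de_between_conditions()] plus `cluster`;
#'   `direction` is `"up_in_cluster"` and `is_marker` flags markers.
#' @export
find_cluster_markers <- function(expr, phenotype, min_pct = 0.1,
                                 logfc_threshold = 0.25, alpha = 0.05) {
  .check_expression(expr)
  phenotype <- .align_phenotype(expr, phenotype)
  if (!"cluster" %in% names(phenotype)) {
    stop("phenotype lacks a 'cluster' column", call. = FALSE)
  }
  clusters <- unique(phenotype$cluster)
  if (length(clusters) < 2L) stop("need >= 2 clusters", call. = FALSE)
  out <- list()
  for (cl in clusters) {
    ic <- which(phenotype$cluster == cl)
    ir <- which(phenotype$cluster != cl)
    if (length(ic) < 3L) {
      warning("cluster '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    pct_in <- rowMeans(expr[, ic, drop = FALSE] > 0)
    lfc <- vapply(seq_len(nrow(expr)), function(g) {
      .avg_log2fc(expr[g, ic], expr[g, ir])
    }, numeric(1))
    cand <- which(pct_in >= min_pct & lfc >= logfc_threshold)
    if (!length(cand)) {
      out[[cl]] <- data.frame(gene = character(0), avg_log2FC = numeric(0),
                              p_value = numeric(0), p_adjusted = numeric(0),
                              pct_in = numeric(0), pct_out = numeric(0),
                              direction = character(0), is_marker = logical(0),
                              cluster = character(0), stringsAsFactors = FALSE)
      next
    }
    p <- vapply(cand, function(g) {
      wilcoxon_rank_sum(expr[g, ic], expr[g, ir])$p_value
    }, numeric(1))
    df <- data.frame(
      gene = rownames(expr)[cand],
      avg_log2FC = lfc[cand],
      p_value = p,
      p_adjusted = adjust_pvalues(p, "bonferroni"),
      pct_in = pct_in[cand],
      pct_out = rowMeans(expr[cand, ir, drop = FALSE] > 0),
      direction = "up_in_cluster",
      cluster = cl,
      stringsAsFactors = FALSE
    )
    df$is_marker <- df$p_adjusted < alpha
    out[[cl]] <- df[order(df$p_adjusted, df$p_value, df$gene), , drop = FALSE]
  }
  out
}

#' Build an ordered gene list from a DE table
#'
#' @param de A data frame from [de_between_conditions()].
#' @param name Name for the list.
#' @param ordering_key `"abs_logFC_desc"` (default, the ordering used when
#'   submitting lists for set enrichment) or `"p_adjusted_asc"`.
#' @return An object of class `gene_list`: list with `name`, `genes`,
#'   `ordering_key`.
#' @export
make_gene_list <- function(de, name,
                           ordering_key = c("abs_logFC_desc", "p_adjusted_asc")) {
  ordering_key <- match.arg(ordering_key)
  ord <- switch(ordering_key,
    abs_logFC_desc = order(-abs(de$avg_log2FC), de$gene, method = "radix"),
    p_adjusted_asc = order(de$p_adjusted, de$p_value, de$gene, method = "radix")
  )
  genes <- de$gene[ord]
  if (anyDuplicated(genes)) stop("duplicate genes in DE table", call. = FALSE)
  structure(list(name = name, genes = genes, ordering_key = ordering_key),
            class = "gene_list")
}

#' Screen DE gene lists for predictive cell subtypes
#'
#' Implements the subtype nomination rule: for each ordered DE gene list,
#' its top `top_genes` genes are tested for over-representation against the
#' collection (hypergeometric, BH-adjusted over sets); sets with fewer than
#' `min_set_size` genes present in the cohort are excluded. The `top_n`
#' enriched sets with adjusted p below `enrich_alpha` are then each
#' evaluated as a nearest-centroid classifier panel on the evaluation
#' cohort, and the gene list is flagged predictive when at least half of its
#' top sets achieve a classification AUC p-value below `auc_alpha`.
#'
#' @param gene_lists A list of [make_gene_list()] objects.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param expr,phenotype Evaluation cohort with R/NR labels.
#' @param top_genes Genes submitted per list (all, if fewer).
#' @param top_n Number of enriched sets retained per list.
#' @param enrich_alpha BH-adjusted enrichment threshold.
#' @param auc_alpha AUC p-value threshold.
#' @param min_set_size Minimum genes a set must have in the cohort.
#' @return Data frame with one row per gene list: `gene_list_name`,
#'   `n_top_sets`, `n_significant`, `is_predictive`; the per-list set tables
#'   are in the `details` attribute.
#' @export
screen_gene_lists <- function(gene_lists, collection, expr, phenotype,
                              top_genes = 500, top_n = 10,
                              enrich_alpha = 0.05, auc_alpha = 0.05,
                              min_set_size = 3) {
  .check_expression(expr)
  phenotype <- .align_phenotype(expr, phenotype)
  if (!length(collection)) stop("empty gene-set collection", call. = FALSE)
  universe <- rownames(expr)
  present_sets <- lapply(collection, function(s) intersect(s, universe))
  keep <- lengths(present_sets) >= min_set_size
  if (any(!keep)) {
    message(sum(!keep), " set(s) with < ", min_set_size,
            " genes in the cohort excluded: ",
            paste(utils::head(names(collection)[!keep], 5), collapse = ", "))
  }
  present_sets <- present_sets[keep]
  if (!length(present_sets)) stop("no gene set has enough cohort genes", call. = FALSE)

  details <- list()
  rows <- lapply(gene_lists, function(gl) {
    stopifnot(inherits(gl, "gene_list"))
    top <- intersect(utils::head(gl$genes, top_genes), universe)
    p_enrich <- vapply(present_sets, function(s) {
      hypergeometric_enrichment(top, s, universe)$p_value
    }, numeric(1))
    p_adj <- adjust_pvalues(p_enrich, "BH")
    ord <- order(p_adj, p_enrich, names(present_sets), method = "radix")
    sig <- ord[p_adj[ord] < enrich_alpha]
    top_sets <- utils::head(sig, top_n)
    auc <- rep(NA_real_, length(top_sets))
    auc_p <- rep(NA_real_, length(top_sets))
    for (i in seq_along(top_sets)) {
      s <- present_sets[[top_sets[i]]]
      ev <- tryCatch({
        fit <- fit_centroid(expr, phenotype, s)
        evaluate_centroid(fit, expr, phenotype)
      }, error = function(e) NULL)
      if (is.null(ev)) {
        message("set '", names(present_sets)[top_sets[i]],
                "' skipped during classifier evaluation")
      } else {
        auc[i] <- ev$auc
        auc_p[i] <- ev$p_value
      }
    }
    tab <- data.frame(
      set_name = names(present_sets)[top_sets],
      enrichment_p = p_enrich[top_sets],
      enrichment_p_adjusted = p_adj[top_sets],
      auc = auc, auc_p = auc_p,
      stringsAsFactors = FALSE
    )
    details[[gl$name]] <<- tab
    n_sig <- sum(auc_p < auc_alpha, na.rm = TRUE)
    data.frame(
      gene_list_name = gl$name,
      n_top_sets = nrow(tab),
      n_significant = n_sig,
      is_predictive = nrow(tab) > 0 && n_sig >= ceiling(nrow(tab) / 2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
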