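# Candidate panel assembly (union of significant gene sets intersected with
# per-subtype fold-change gates and the cohort's genes) followed by
# recursive backward gene elimination: at each cycle every leave-one-out
# subpanel is scored as a nearest-centroid classifier and the subpanel with
# the highest AUC survives, down to a minimum of three genes; the signature
# is the panel with the global maximum AUC across cycles.

#' Assemble the candidate signature panel
#'
#' `union_genelist` is the union of all significant gene sets;
#' `intersect_genelist` is the intersection over subtypes of the genes
#' passing that subtype's fold-change gate; the starting panel is the
#' three-way intersection with the cohort's genes, ordered
#' lexicographically for reproducibility.
#'
#' @param significant_sets Named list of gene sets already deemed
#'   predictive.
#' @param de_by_subtype Named list of DE tables (one per subtype, columns
#'   `gene` and `avg_log2FC`).
#' @param gates Data frame with columns `subtype`, `direction`
#'   (`"greater"`/`"less"`), `threshold`; every subtype must appear in
#'   `de_by_subtype`.
#' @param cohort_genes Genes available in the evaluation cohort.
#' @return An object of class `candidate_assembly` with `union_genelist`,
#'   `intersect_genelist`, `panel0`, and per-stage counts.
#' @export
assemble_candidates <- function(significant_sets, de_by_subtype, gates,
                                cohort_genes) {
  stopifnot(is.list(significant_sets), is.list(de_by_subtype),
            is.data.frame(gates),
            all(c("subtype", "direction", "threshold") %in% names(gates)))
  if (nrow(gates) == 0L) {
    stop("gates must contain at least one row", call. = FALSE)
  }
  missing_st <- setdiff(gates$subtype, names(de_by_subtype))
  if (length(missing_st)) {
    stop("gate subtype(s) absent from de_by_subtype: ",
         paste(missing_st, collapse = ", "), call. = FALSE)
  }
  union_genelist <- .lex_sort(unique(unlist(significant_sets, use.names = FALSE)))
  kept <- lapply(seq_len(nrow(gates)), function(i) {
    de <- de_by_subtype[[gates$subtype[i]]]
    pass <- switch(gates$direction[i],
      greater = de$avg_log2FC > gates$threshold[i],
      less = de$avg_log2FC < gates$threshold[i],
      stop("gate direction must be 'greater' or 'less'", call. = FALSE)
    )
    de$gene[pass]
  })
  intersect_genelist <- .lex_sort(Reduce(intersect, kept))
  panel0 <- .lex_sort(intersect(intersect(union_genelist, intersect_genelist),
                                cohort_genes))
  counts <- c(union = length(union_genelist),
              intersect = length(intersect_genelist),
              cohort = length(cohort_genes), panel0 = length(panel0))
  if (!length(panel0)) {
    stop("empty candidate panel; stage counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  structure(list(union_genelist = union_genelist,
                 intersect_genelist = intersect_genelist,
                 panel0 = panel0, counts = counts),
            class = "candidate_assembly")
}

# AUC only (ties one half), positive scores expected higher.
.auc_only <- function(pos, neg) {
  n1 <- length(pos)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(neg))
}

# Fast leave-one-out classifier AUCs for one elimination cycle. Gene
# standardization and class centroids do not depend on the panel, so each
# subpanel's correlation scores are obtained from running sums in O(samples)
# per left-out gene; this is algebraically the fit_centroid/evaluate path.
# Degenerate subpanels (zero-variance correlations, < 3 usable genes) score
# 0, so one bad gene cannot abort the search.
.cycle_loo_aucs <- function(Z, cR, cNR, good, idx, pos, neg,
                            method = "correlation") {
  if (method == "euclidean") {
    # distance-difference score is linear in the profile: t = sum(z * w),
    # w = cNR - cR, up to a subset-constant shift that cannot change AUC
    w <- cNR - cR
    t_full <- as.numeric(crossprod(Z[idx, , drop = FALSE], w[idx]))
    kgood <- sum(good[idx])
    return(vapply(seq_along(idx), function(ii) {
      g <- idx[ii]
      if (kgood - good[g] < 3L) return(0)
      score <- t_full - Z[g, ] * w[g]
      if (stats::sd(score) == 0) return(0)
      .auc_only(score[pos], score[neg])
    }, numeric(1)))
  }
  Zi <- Z[idx, , drop = FALSE]
  sx <- colSums(Zi)
  sxx <- colSums(Zi^2)
  sxcR <- as.numeric(crossprod(Zi, cR[idx]))
  sxcN <- as.numeric(crossprod(Zi, cNR[idx]))
  ScR <- sum(cR[idx]); SccR <- sum(cR[idx]^2)
  ScN <- sum(cNR[idx]); SccN <- sum(cNR[idx]^2)
  kgood <- sum(good[idx])
  vapply(seq_along(idx), function(ii) {
    g <- idx[ii]
    k2 <- kgood - good[g]
    if (k2 < 3L) return(0)
    zx <- Z[g, ]
    sx2 <- sx - zx
    vx <- (sxx - zx^2) - sx2^2 / k2
    vcR <- (SccR - cR[g]^2) - (ScR - cR[g])^2 / k2
    vcN <- (SccN - cNR[g]^2) - (ScN - cNR[g])^2 / k2
    if (vcR <= 0 || vcN <= 0 || any(vx <= 0)) return(0)
    covR <- (sxcR - zx * cR[g]) - sx2 * (ScR - cR[g]) / k2
    covN <- (sxcN - zx * cNR[g]) - sx2 * (ScN - cNR[g]) / k2
    score <- covN / sqrt(vx * vcN) - covR / sqrt(vx * vcR)
    if (any(!is.finite(score))) return(0)
    .auc_only(score[pos], score[neg])
  }, numeric(1))
}

# Full-panel AUC under the same conventions (used for the first trace row).
.panel_auc <- function(Z, cR, cNR, good, idx, pos, neg,
                       method = "correlation") {
  idx <- idx[good[idx]]
  if (length(idx) < 3L) return(0)
  Zi <- Z[idx, , drop = FALSE]
  score <- tryCatch(
    .raw_scores(Zi, cR[idx], cNR[idx], method),
    error = function(e) NULL
  )
  if (is.null(score) || any(!is.finite(score)) || stats::sd(score) == 0) {
    return(0)
  }
  .auc_only(score[pos], score[neg])
}

#' Recursive backward gene elimination maximizing classification AUC
#'
#' Starting from the full candidate panel, each cycle fits and evaluates a
#' nearest-centroid classifier for every subpanel obtained by removing one
#' gene, retains the subpanel with the highest training AUC (among AUC ties
#' within 1e-9, the lexicographically last gene is removed), and repeats
#' until `min_size` genes remain. The selected signature is the panel with
#' the global maximum AUC over all cycles; when several cycles tie within
#' 1e-9 the earliest (largest) tied panel is selected. Under a saturated
#' criterion (training AUC exactly 1) removals beyond the first attainment
#' carry no evidence and are decided only by the tie-break, so the first
#' attainment is the conservative stop; smaller panels inside the plateau
#' remain available through `size_override` in [build_signature()].
#'
#' By default each subpanel is scored by resubstitution on the training
#' cohort, the protocol under which the per-cycle AUCs are interpreted.
#' With `holdout_fraction > 0` the cohort is split once (stratified by
#' class, deterministically from `split_seed`): centroids and gene scaling
#' come from the fitting portion and every subpanel's AUC is measured on
#' the held-out portion. The split mode is the recommended guard against
#' the selection overfitting that resubstitution invites when the search
#' saturates at AUC 1; the final reported signature model is always refit
#' on the full cohort by [build_signature()].
#'
#' @param panel0 Character vector of starting genes (`length > min_size`),
#'   all present in `expr`.
#' @param expr,phenotype Training cohort (two classes, >= 2 samples each).
#' @param min_size Smallest panel size explored (default 3).
#' @param positive_class,negative_class,group_col Class labels, as in
#'   [fit_centroid()].
#' @param method Classifier score variant, as in [fit_centroid()].
#' @param holdout_fraction Fraction of each class held out for subpanel
#'   scoring (0 = resubstitution).
#' @param split_seed Seed fixing the inner split.
#' @return An object of class `elimination_trace`: `cycles` data frame
#'   (`cycle`, `panel_size`, `removed_gene`, `best_auc`), `panels` (the
#'   surviving panel per cycle), `selected`, `selected_auc`,
#'   `n_evaluations`.
#' @export
recursive_elimination <- function(panel0, expr, phenotype, min_size = 3,
                                  positive_class = "NR", negative_class = "R",
                                  group_col = "response",
                                  method = c("correlation", "euclidean"),
                                  holdout_fraction = 0, split_seed = 1L) {
  method <- match.arg(method)
  if (holdout_fraction < 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie in [0, 1)", call. = FALSE)
  }
  .check_expression(expr)
  phenotype <- .align_phenotype(expr, phenotype)
  min_size <- .assert_count(min_size, "min_size", 3L)
  panel0 <- unique(as.character(panel0))
  if (length(panel0) <= min_size) {
    stop("panel0 must contain more than min_size genes", call. = FALSE)
  }
  absent <- setdiff(panel0, rownames(expr))
  if (length(absent)) {
    stop("panel0 gene(s) absent from expression: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  labels <- phenotype[[group_col]]
  pos <- which(labels == positive_class)
  neg <- which(labels == negative_class)
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need >= 2 samples per class", call. = FALSE)
  }

  fit_pos <- pos
  fit_neg <- neg
  eval_cols <- seq_len(ncol(expr))
  if (holdout_fraction > 0) {
    set.seed(.stage_seed(split_seed, "elimination_split"))
    hold_pos <- sample(pos, max(2L, floor(holdout_fraction * length(pos))))
    hold_neg <- sample(neg, max(2L, floor(holdout_fraction * length(neg))))
    fit_pos <- setdiff(pos, hold_pos)
    fit_neg <- setdiff(neg, hold_neg)
    if (length(fit_pos) < 2L || length(fit_neg) < 2L) {
      stop("holdout split leaves fewer than 2 samples per class", call. = FALSE)
    }
    eval_cols <- sort(c(hold_pos, hold_neg))
  }
  fit_cols <- sort(c(fit_pos, fit_neg))

  X <- expr[panel0, , drop = FALSE]
  mu <- rowMeans(X[, fit_cols, drop = FALSE])
  sdv <- apply(X[, fit_cols, drop = FALSE], 1L, stats::sd)
  good <- sdv > 0
  Z <- X
  Z[good, ] <- (X[good, , drop = FALSE] - mu[good]) / sdv[good]
  Z[!good, ] <- 0
  cNR <- rowMeans(Z[, fit_pos, drop = FALSE])
  cR <- rowMeans(Z[, fit_neg, drop = FALSE])
  cNR[!good] <- 0
  cR[!good] <- 0
  Z_eval <- Z[, eval_cols, drop = FALSE]
  pos_eval <- which(eval_cols %in% pos)
  neg_eval <- which(eval_cols %in% neg)

  current <- seq_along(panel0)
  cycles <- list()
  panels <- list()
  n_eval <- 1L
  auc0 <- .panel_auc(Z_eval, cR, cNR, good, current, pos_eval, neg_eval, method)
  cycles[[1]] <- data.frame(cycle = 1L, panel_size = length(current),
                            removed_gene = NA_character_, best_auc = auc0,
                            stringsAsFactors = FALSE)
  panels[[1]] <- panel0
  cyc <- 1L
  while (length(current) > min_size) {
    aucs <- .cycle_loo_aucs(Z_eval, cR, cNR, good, current, pos_eval, neg_eval, method)
    n_eval <- n_eval + length(current)
    best <- max(aucs)
    cand <- which(aucs >= best - 1e-9)
    # remove the lexicographically last gene among tied candidates
    drop_ii <- cand[order(panel0[current[cand]], method = "radix")[length(cand)]]
    removed <- panel0[current[drop_ii]]
    current <- current[-drop_ii]
    cyc <- cyc + 1L
    cycles[[cyc]] <- data.frame(cycle = cyc, panel_size = length(current),
                                removed_gene = removed,
                                best_auc = aucs[drop_ii],
                                stringsAsFactors = FALSE)
    panels[[cyc]] <- panel0[current]
  }
  trace <- do.call(rbind, cycles)
  best_overall <- max(trace$best_auc)
  tied <- which(trace$best_auc >= best_overall - 1e-9)
  sel <- tied[which.max(trace$panel_size[tied])]
  structure(list(cycles = trace, panels = panels,
                 selected = panels[[sel]],
                 selected_auc = trace$best_auc[sel],
                 selected_cycle = sel,
                 n_evaluations = n_eval, min_size = min_size,
                 method = method, holdout_fraction = holdout_fraction),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("elimination trace: %d cycles (%d -> %d genes), %d classifier evaluations\n",
              nrow(x$cycles), x$cycles$panel_size[1],
              x$cycles$panel_size[nrow(x$cycles)], x$n_evaluations))
  cat(sprintf("selected: %d genes at AUC %.4f (cycle %d)\n",
              length(x$selected), x$selected_auc, x$selected_cycle))
  invisible(x)
}

#' Write an elimination trace as TSV
#' @param trace An `elimination_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "elimination_trace"))
  utils::write.table(trace$cycles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build the response prediction signature
#'
#' Runs [recursive_elimination()] on the candidate panel and fits the final
#' nearest-centroid model on the training cohort with the selected panel.
#' `size_override` reproduces a manual pick of a specific panel size from
#' the trace (as when a plateau of near-equal AUCs makes several sizes
#' defensible); by default the global-max-AUC rule decides.
#'
#' @param x A `candidate_assembly` or a character vector of starting genes.
#' @param expr,phenotype Training cohort.
#' @param size_override Optional panel size in `[min_size, |panel0|]`.
#' @param min_size Smallest panel size explored.
#' @param ... Passed to [recursive_elimination()].
#' @return An object of class `signature_fit`: `panel` (list with `genes`,
#'   `size`, `auc`, `source`), `model` (a `centroid_model`), and `trace`.
#' @export
build_signature <- function(x, expr, phenotype, size_override = NULL,
                            min_size = 3, method = c("correlation", "euclidean"),
                            holdout_fraction = 0, split_seed = 1L, ...) {
  method <- match.arg(method)
  panel0 <- if (inherits(x, "candidate_assembly")) x$panel0 else unique(as.character(x))
  trace <- recursive_elimination(panel0, expr, phenotype, min_size = min_size,
                                 method = method,
                                 holdout_fraction = holdout_fraction,
                                 split_seed = split_seed, ...)
  if (!is.null(size_override)) {
    size_override <- .assert_count(size_override, "size_override", min_size)
    if (size_override > length(panel0)) {
      stop("size_override outside [min_size, |panel0|]", call. = FALSE)
    }
    i <- match(size_override, trace$cycles$panel_size)
    genes <- trace$panels[[i]]
    auc <- trace$cycles$best_auc[i]
  } else {
    genes <- trace$selected
    auc <- trace$selected_auc
  }
  model <- fit_centroid(expr, phenotype, genes, method = method, ...)
  structure(list(
    panel = list(genes = genes, size = length(genes), auc = auc,
                 source = if (inherits(x, "candidate_assembly")) "assembly" else "gene_vector",
                 size_override = size_override),
    model = model, trace = trace
  ), class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("signature: %d genes, training AUC %.4f\n",
              x$panel$size, x$panel$auc))
  print(x$model)
  invisible(x)
}
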