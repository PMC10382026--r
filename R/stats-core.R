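# Elementary statistics used throughout the signature workflow. These are
# deliberately small, explicit implementations so each one is checkable
# against exact enumeration or a closed form.

#' Two-sided Wilcoxon rank sum test
#'
#' Computes the Mann-Whitney U statistic for `x` versus `y` with a two-sided
#' p-value. The exact null distribution is used when the combined sample size
#' is at most 12 and there are no ties; otherwise the tie-corrected normal
#' approximation applies (no continuity correction).
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A list with `statistic` (U for the first sample), `p_value`, and
#'   `method` (`"wilcoxon_exact"` or `"wilcoxon_normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value # exact: 2/20
#' @export
wilcoxon_rank_sum <- function(x, y) {
  .assert_numeric(x, "x")
  .assert_numeric(y, "y")
  nx <- length(x)
  ny <- length(y)
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(z) > 0L
  if (nx + ny <= 12L && !ties) {
    p <- if (U > nx * ny / 2) {
      2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, nx, ny)
    }
    method <- "wilcoxon_exact"
  } else {
    n <- nx + ny
    tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- 2 * stats::pnorm(-abs((U - nx * ny / 2) / sqrt(sigma2)))
    }
    method <- "wilcoxon_normal"
  }
  list(statistic = U, p_value = min(1, p), method = method)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. When both groups have zero variance the p-value is 1 if
#' the means agree and 0 otherwise, by convention.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @return A list with `statistic`, `df`, `p_value`, and `method`.
#' @export
welch_t <- function(x, y) {
  .assert_numeric(x, "x", 2L)
  .assert_numeric(y, "y", 2L)
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(statistic = t_stat, df = n1 + n2 - 2,
                p_value = if (m1 == m2) 1 else 0, method = "welch_t"))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df), method = "welch_t")
}

#' Multiple testing adjustment
#'
#' Benjamini-Hochberg step-up or Bonferroni correction, order-preserving.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric `c(lo, hi)`, clipped to \[0, 1\].
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  n <- .assert_count(n, "n", min = 1L)
  successes <- .assert_count(successes, "successes", min = 0L)
  if (successes > n) stop("'successes' cannot exceed 'n'", call. = FALSE)
  if (length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' ROC curve area with Welch-based p-value and Wilson intervals
#'
#' The AUC is the Mann-Whitney U statistic divided by the number of class
#' pairs, counting ties as one half; the orientation is fixed so that higher
#' scores indicate the positive (nonresponder) class. The p-value is a Welch
#' t-test comparing the two score distributions. Sensitivity and specificity
#' are reported at the Youden-optimal threshold (a choice recorded in the
#' result, since no single threshold is canonical) with Wilson 95% intervals.
#'
#' @param scores_pos Scores of the positive class (higher expected).
#' @param scores_neg Scores of the negative class.
#' @param level Confidence level for the Wilson intervals.
#' @return An object of class `roc_result`: list with `auc`, `p_value`,
#'   `sensitivity`, `specificity`, `sens_ci`, `spec_ci`, `threshold`,
#'   `n_pos`, `n_neg`, and `threshold_rule = "youden"`.
#' @export
roc_auc <- function(scores_pos, scores_neg, level = 0.95) {
  .assert_numeric(scores_pos, "scores_pos")
  .assert_numeric(scores_neg, "scores_neg")
  n1 <- length(scores_pos)
  n2 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  p <- if (n1 >= 2L && n2 >= 2L) welch_t(scores_pos, scores_neg)$p_value else NA_real_

  # Youden-optimal threshold: call positive when score >= t.
  cand <- sort(unique(c(scores_pos, scores_neg)))
  sens <- vapply(cand, function(t) mean(scores_pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores_neg < t), numeric(1))
  best <- which.max(sens + spec - 1)
  thr <- cand[best]
  tp <- sum(scores_pos >= thr)
  tn <- sum(scores_neg < thr)
  structure(list(
    auc = auc, p_value = p,
    sensitivity = tp / n1, specificity = tn / n2,
    sens_ci = wilson_ci(tp, n1, level), spec_ci = wilson_ci(tn, n2, level),
    threshold = thr, threshold_rule = "youden",
    n_pos = n1, n_neg = n2
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (p = %.3g), n = %d pos / %d neg\n",
              x$auc, x$p_value, x$n_pos, x$n_neg))
  cat(sprintf("  sensitivity %.3f [%.3f, %.3f], specificity %.3f [%.3f, %.3f] at %s threshold %.4g\n",
              x$sensitivity, x$sens_ci[["lo"]], x$sens_ci[["hi"]],
              x$specificity, x$spec_ci[["lo"]], x$spec_ci[["hi"]],
              x$threshold_rule, x$threshold))
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the given overlap between a
#' query gene list and a gene set drawn from a common universe.
#'
#' @param list_genes,gene_set Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes (non-empty).
#' @return A list with `statistic` (the overlap count), `p_value`, and
#'   `method = "hypergeometric"`.
#' @export
hypergeometric_enrichment <- function(list_genes, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty", call. = FALSE)
  list_genes <- unique(as.character(list_genes))
  gene_set <- unique(as.character(gene_set))
  out1 <- setdiff(list_genes, universe)
  out2 <- setdiff(gene_set, universe)
  if (length(out1) || length(out2)) {
    stop("genes outside the universe: ",
         paste(utils::head(c(out1, out2), 5), collapse = ", "), call. = FALSE)
  }
  k <- length(intersect(list_genes, gene_set))
  p <- stats::phyper(k - 1, length(gene_set), length(universe) - length(gene_set),
                     length(list_genes), lower.tail = FALSE)
  list(statistic = k, p_value = p, method = "hypergeometric")
}
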