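# Internal validation and seeding helpers shared across modules.

# Deterministic per-stage sub-seed: a stable hash of the stage name folded
# into the user seed, kept inside 32-bit integer range. Adding genes or
# stages to a simulation therefore never perturbs the draws of other stages.
.stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483587
  as.integer((as.numeric(seed) %% 2147483587 * 69821 + h) %% 2147483587)
}

.assert_numeric <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop(sprintf("'%s' must be numeric with at least %d value(s)", name, min_len),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' contains missing or non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Expression matrices are numeric, genes as rows, unique dimnames.
.check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes as rows)", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression must have gene row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    dup <- unique(rownames(expr)[duplicated(rownames(expr))])
    stop("duplicate gene ids in expression: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(expr)
}

# Phenotype rows must cover exactly the expression columns; returns the
# phenotype reordered to match the expression columns.
.align_phenotype <- function(expr, phenotype) {
  if (!is.data.frame(phenotype) || !"sample_id" %in% names(phenotype)) {
    stop("phenotype must be a data frame with a 'sample_id' column", call. = FALSE)
  }
  missing_ph <- setdiff(colnames(expr), phenotype$sample_id)
  extra_ph <- setdiff(phenotype$sample_id, colnames(expr))
  if (length(missing_ph) || length(extra_ph)) {
    stop("expression/phenotype sample mismatch; missing from phenotype: [",
         paste(missing_ph, collapse = ", "), "]; absent from expression: [",
         paste(extra_ph, collapse = ", "), "]", call. = FALSE)
  }
  phenotype[match(colnames(expr), phenotype$sample_id), , drop = FALSE]
}

# Locale-independent lexicographic sort used for every deterministic ordering.
.lex_sort <- function(x) sort(x, method = "radix")
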