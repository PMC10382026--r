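# Plain-text interchange: TSV expression (genes as rows), CSV phenotype,
# GMT gene sets, one-column gene lists, JSON models and manifests.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (column name `gene`). Duplicate gene ids are rejected. A matrix whose
#' gene column matches sample ids in a companion phenotype is a sign the
#' file is transposed; it is rejected, never auto-fixed.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes as rows.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "gene") {
    stop("expression TSV must start with a 'gene' column followed by samples",
         call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    dup <- unique(df$gene[duplicated(df$gene)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(m) <- df$gene
  m
}

#' Write an expression matrix to TSV
#' @param expr Numeric matrix, genes as rows.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  .check_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' Requires a `sample_id` column; typical further columns are `response`
#' (R/NR), `time_months`, `event`, and `cluster`. When `expr` is supplied,
#' sample agreement is enforced and mismatching ids are named in the error.
#'
#' @param path Path to a CSV file.
#' @param expr Optional expression matrix to validate against.
#' @return Data frame.
#' @export
read_phenotype <- function(path, expr = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("phenotype CSV must contain a 'sample_id' column", call. = FALSE)
  }
  if (!is.null(expr)) df <- .align_phenotype(expr, df)
  df
}

#' Write a phenotype table to CSV
#' @param phenotype Data frame with a `sample_id` column.
#' @param path Output path.
#' @export
write_phenotype <- function(phenotype, path) {
  stopifnot(is.data.frame(phenotype), "sample_id" %in% names(phenotype))
  utils::write.csv(phenotype, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Sets of any size are read; downstream classifier steps
#' enforce their own minimum-size rule (three genes) and log exclusions.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s): ", paste(utils::head(which(bad), 5), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in GMT", call. = FALSE)
  }
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set descriptions (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a one-column gene list
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Serialize a synthetic cohort to a directory
#'
#' Writes `expression.tsv`, `phenotype.csv`, and `truth.json` so a cohort
#' round-trips through the standard readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_phenotype(cohort$phenotype, file.path(dir, "phenotype.csv"))
  jsonlite::write_json(list(truth = cohort$truth,
                            panel_score_true = cohort$panel_score_true),
                       file.path(dir, "truth.json"), digits = NA, auto_unbox = FALSE)
  invisible(dir)
}
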