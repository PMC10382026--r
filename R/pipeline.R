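# End-to-end wiring: simulate a training and a validation cohort, derive a
# candidate panel from differential expression, run the recursive
# elimination, freeze the model, validate it, and write every artifact plus
# a machine-readable run manifest so a run can be reproduced exactly.

#' Run the simulate / build-signature / validate pipeline
#'
#' Generates a training cohort and an independent validation cohort from the
#' same configuration (the validation cohort is replicate 2 of the same
#' population: same planted genes, fresh samples), takes the
#' `panel0_size` genes with the smallest
#' response-DE p-values as the candidate panel, runs
#' [recursive_elimination()] on the training cohort, fits the final model,
#' and evaluates it frozen on the validation cohort. All outputs are
#' written as plain text under `out_dir` together with `manifest.json`
#' (configuration, seeds, package version, and MD5 checksums of every
#' written file); rerunning with the same configuration reproduces the
#' files byte for byte.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param panel0_size Candidate panel size taken from the DE ranking.
#' @param min_size Smallest panel size explored by the elimination.
#' @return Invisibly, a list with `signature` (the `signature_fit`),
#'   `validation` (a `roc_result`), `predictions`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, panel0_size = 30, min_size = 3) {
  stopifnot(inherits(config, "simulation_config"))
  panel0_size <- .assert_count(panel0_size, "panel0_size", min_size + 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  train <- simulate_bulk_cohort(config)
  val <- simulate_bulk_cohort(config, replicate = 2L)

  de <- de_between_conditions(train$expression, train$phenotype,
                              group_a = "NR", group_b = "R")
  ord <- order(de$p_value, de$gene, method = "radix")
  panel0 <- .lex_sort(de$gene[utils::head(ord, panel0_size)])

  sig <- build_signature(panel0, train$expression, train$phenotype,
                         min_size = min_size)
  preds <- predict(sig$model, val$expression)
  roc <- evaluate_centroid(sig$model, val$expression, val$phenotype)

  write_cohort(train, file.path(out_dir, "train"))
  write_cohort(val, file.path(out_dir, "validation"))
  utils::write.table(de, file.path(out_dir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_trace(sig$trace, file.path(out_dir, "trace.tsv"))
  write_gene_list(sig$panel$genes, file.path(out_dir, "signature.txt"))
  write_model(sig$model, file.path(out_dir, "model.json"))
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(auc = roc$auc, p_value = roc$p_value,
         sensitivity = roc$sensitivity, specificity = roc$specificity,
         sens_ci = unname(roc$sens_ci), spec_ci = unname(roc$spec_ci),
         threshold = roc$threshold, threshold_rule = roc$threshold_rule),
    file.path(out_dir, "validation_roc.json"), digits = NA, auto_unbox = TRUE
  )

  files <- c("train/expression.tsv", "train/phenotype.csv", "train/truth.json",
             "validation/expression.tsv", "validation/phenotype.csv",
             "validation/truth.json", "de.tsv", "trace.tsv", "signature.txt",
             "model.json", "predictions.csv", "validation_roc.json")
  checksums <- vapply(files, function(f) {
    unname(tools::md5sum(file.path(out_dir, f)))
  }, character(1))
  manifest <- list(
    package = "chemosig",
    version = as.character(utils::packageVersion("chemosig")),
    config = unclass(config),
    validation_replicate = 2L,
    panel0_size = panel0_size,
    min_size = min_size,
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(signature = sig, validation = roc, predictions = preds,
                 manifest = manifest))
}

#' Re-run a pipeline from its manifest
#'
#' Reads `manifest.json` from a previous [run_pipeline()] output directory
#' and repeats the run into `out_dir` with the recorded configuration.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory for the re-run.
#' @return As [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(simulation_config, m$config)
  run_pipeline(cfg, out_dir, panel0_size = m$panel0_size, min_size = m$min_size)
}
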