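# Nearest-centroid response classifier. Panel genes are standardized with
# training statistics, class centroids are the standardized class means,
# and a sample's continuous score is the difference of its Pearson
# correlations with the nonresponder and responder centroids, z-scored
# against the training score distribution and calibrated to a nonresponse
# probability by logistic regression. Orientation is fixed: higher scores
# mean nonresponse.

# Correlation of each standardized sample column with a centroid vector.
.centroid_cor <- function(Z, centroid) {
  k <- nrow(Z)
  cs <- stats::sd(centroid)
  if (!is.finite(cs) || cs == 0) {
    stop("degenerate centroid (zero variance across panel genes)", call. = FALSE)
  }
  zc <- (centroid - mean(centroid)) / cs
  Zs <- scale(Z) # standardize each sample over panel genes
  as.numeric(crossprod(Zs, zc)) / (k - 1)
}

.raw_scores <- function(Z, centroid_R, centroid_NR, method = "correlation") {
  if (method == "euclidean") {
    # mean squared distance difference; linear in the sample profile, so it
    # preserves a homogeneous mean shift that correlation centering removes
    dR <- colMeans((Z - centroid_R)^2)
    dNR <- colMeans((Z - centroid_NR)^2)
    dR - dNR
  } else {
    .centroid_cor(Z, centroid_NR) - .centroid_cor(Z, centroid_R)
  }
}

#' Fit a nearest-centroid response classifier
#'
#' @param expr Gene-by-sample training matrix.
#' @param phenotype Data frame with `sample_id` and the class column.
#' @param panel Character vector of panel genes (at least three must be
#'   usable: present in `expr` with nonzero variance; others are dropped
#'   with a warning).
#' @param positive_class Label treated as the high-score class (default
#'   `"NR"`, nonresponders).
#' @param negative_class The other label (default `"R"`).
#' @param group_col Phenotype column with the labels.
#' @param method Distance underlying the continuous score:
#'   `"correlation"` (default; difference of Pearson correlations with the
#'   two centroids, scale-free) or `"euclidean"` (difference of mean squared
#'   distances, which preserves a homogeneous mean shift across the panel
#'   that correlation centering removes).
#' @return An object of class `centroid_model` holding the usable panel,
#'   per-gene training means/sds, the two class centroids, training score
#'   mean/sd, and the logistic calibration `(intercept, slope)`.
#' @export
fit_centroid <- function(expr, phenotype, panel, positive_class = "NR",
                         negative_class = "R", group_col = "response",
                         method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  .check_expression(expr)
  phenotype <- .align_phenotype(expr, phenotype)
  labels <- phenotype[[group_col]]
  ipos <- which(labels == positive_class)
  ineg <- which(labels == negative_class)
  if (length(ipos) < 2L || length(ineg) < 2L) {
    stop("need >= 2 samples per class", call. = FALSE)
  }
  panel <- unique(as.character(panel))
  present <- intersect(panel, rownames(expr))
  if (length(present) < length(panel)) {
    warning(length(panel) - length(present), " panel gene(s) missing from expression")
  }
  if (length(present) < 3L) {
    stop("fewer than 3 panel genes present in the cohort", call. = FALSE)
  }
  X <- expr[present, , drop = FALSE]
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance panel gene(s) dropped")
    keepg <- sdv > 0
    X <- X[keepg, , drop = FALSE]
    mu <- mu[keepg]
    sdv <- sdv[keepg]
  }
  if (nrow(X) < 3L) stop("fewer than 3 usable panel genes", call. = FALSE)
  Z <- (X - mu) / sdv
  centroid_NR <- rowMeans(Z[, ipos, drop = FALSE])
  centroid_R <- rowMeans(Z[, ineg, drop = FALSE])
  raw <- .raw_scores(Z, centroid_R, centroid_NR, method)
  if (any(!is.finite(raw))) {
    stop("non-finite training scores (constant sample over panel genes)",
         call. = FALSE)
  }
  s_mu <- mean(raw)
  s_sd <- stats::sd(raw)
  if (!is.finite(s_sd) || s_sd == 0) {
    stop("degenerate training scores (zero variance)", call. = FALSE)
  }
  z <- (raw - s_mu) / s_sd
  used <- sort(c(ipos, ineg))
  cal <- suppressWarnings(
    stats::glm(as.integer(labels[used] == positive_class) ~ z[used],
               family = stats::binomial())
  )
  coefs <- stats::coef(cal)
  structure(list(
    panel = rownames(X),
    gene_mean = mu, gene_sd = sdv,
    centroid_R = centroid_R, centroid_NR = centroid_NR,
    score_mean = s_mu, score_sd = s_sd,
    calibration = c(intercept = unname(coefs[1]), slope = unname(coefs[2])),
    classes = c(positive = positive_class, negative = negative_class),
    group_col = group_col, method = method
  ), class = "centroid_model")
}

# Shared scoring path for training diagnostics and prediction: uses the
# training-time gene scaling and score standardization, never refit.
.model_scores <- function(object, expr) {
  present <- intersect(object$panel, rownames(expr))
  if (length(present) < length(object$panel)) {
    warning(length(object$panel) - length(present),
            " model gene(s) missing from expression")
  }
  if (length(present) < 3L) {
    stop("fewer than 3 model panel genes present", call. = FALSE)
  }
  Z <- (expr[present, , drop = FALSE] - object$gene_mean[present]) /
    object$gene_sd[present]
  method <- if (is.null(object$method)) "correlation" else object$method
  raw <- .raw_scores(Z, object$centroid_R[present], object$centroid_NR[present],
                     method)
  (raw - object$score_mean) / object$score_sd
}

#' Predict response scores and nonresponse probabilities
#'
#' Applies a frozen [fit_centroid()] model: test expression is scaled with
#' the training gene statistics (never re-standardized on test data), scores
#' are z-scored with the training score mean/sd, and the logistic
#' calibration converts each score to a nonresponse probability.
#'
#' @param object A `centroid_model`.
#' @param expr Gene-by-sample matrix to score.
#' @param ... Unused.
#' @return Data frame with `sample_id`, `score_z`, `prob_nonresponse`, and
#'   `call` (the positive class when the probability exceeds one half).
#' @export
predict.centroid_model <- function(object, expr, ...) {
  .check_expression(expr)
  z <- .model_scores(object, expr)
  a <- object$calibration[["intercept"]]
  b <- object$calibration[["slope"]]
  prob <- stats::plogis(a + b * z)
  data.frame(
    sample_id = colnames(expr),
    score_z = z,
    prob_nonresponse = prob,
    call = ifelse(prob > 0.5, object$classes[["positive"]],
                  object$classes[["negative"]]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Evaluate a centroid model on a labeled cohort
#'
#' Scores the cohort with the frozen model and summarizes discrimination as
#' a [roc_auc()] result: AUC with ties counted one half, a Welch t-test
#' p-value on the class-wise scores, and Youden-threshold sensitivity and
#' specificity with Wilson 95% intervals.
#'
#' @param model A `centroid_model`.
#' @param expr,phenotype Evaluation cohort; both classes must be present.
#' @return A `roc_result`.
#' @export
evaluate_centroid <- function(model, expr, phenotype) {
  .check_expression(expr)
  phenotype <- .align_phenotype(expr, phenotype)
  labels <- phenotype[[model$group_col]]
  pos <- labels == model$classes[["positive"]]
  neg <- labels == model$classes[["negative"]]
  if (!any(pos) || !any(neg)) {
    stop("evaluation cohort must contain both classes", call. = FALSE)
  }
  z <- .model_scores(model, expr)
  roc_auc(z[pos], z[neg])
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("nearest-centroid model: %d panel genes, orientation higher => %s\n",
              length(x$panel), x$classes[["positive"]]))
  cat(sprintf("  calibration: logit(p) = %.3f + %.3f * z\n",
              x$calibration[["intercept"]], x$calibration[["slope"]]))
  invisible(x)
}

#' Serialize / restore a centroid model as JSON
#' @param model A `centroid_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the restored `centroid_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("gene_mean", "gene_sd", "centroid_R", "centroid_NR")) {
    x[[f]] <- stats::setNames(as.numeric(x[[f]]), x$panel)
  }
  x$calibration <- stats::setNames(as.numeric(x$calibration),
                                   c("intercept", "slope"))
  x$classes <- stats::setNames(as.character(x$classes),
                               c("positive", "negative"))
  x$score_mean <- as.numeric(x$score_mean)
  x$score_sd <- as.numeric(x$score_sd)
  x$group_col <- as.character(x$group_col)
  x$method <- as.character(x$method)
  structure(x, class = "centroid_model")
}
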