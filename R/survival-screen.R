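# Prognostic refinement: univariate Cox proportional-hazards screening of
# panel genes (Breslow tie handling) and Kaplan-Meier validation of a
# signature score dichotomized at the cohort median.

.check_surv <- function(surv) {
  if (!is.data.frame(surv) ||
      !all(c("sample_id", "time_months", "event") %in% names(surv))) {
    stop("survival table needs columns sample_id, time_months, event",
         call. = FALSE)
  }
  if (any(surv$time_months <= 0) || !all(surv$event %in% c(0, 1))) {
    stop("time_months must be > 0 and event must be 0/1", call. = FALSE)
  }
  invisible(surv)
}

#' Univariate Cox screening of genes or scores
#'
#' Fits one proportional-hazards model per gene (Breslow ties) against the
#' supplied survival table and retains genes that are significant at
#' `alpha` with the hazard ratio on the requested side of one: `"risk"`
#' keeps HR > 1 (higher expression, worse outcome), `"protective"` keeps
#' HR < 1. Genes whose fit fails or does not converge are skipped with a
#' message.
#'
#' @param expr Gene-by-sample matrix (rows may also be signature scores).
#' @param surv Data frame with `sample_id`, `time_months`, `event`;
#'   at least 10 samples and 3 events.
#' @param hr_direction `"risk"` or `"protective"`.
#' @param alpha Wald p-value threshold.
#' @return A list with `table` (per-gene `gene`, `beta`, `hazard_ratio`,
#'   `ci_lo`, `ci_hi`, `p_value`, `retained`) and `panel` (the retained
#'   gene ids, lexicographic).
#' @export
univariate_cox_screen <- function(expr, surv, hr_direction = c("risk", "protective"),
                                  alpha = 0.05) {
  hr_direction <- match.arg(hr_direction)
  .check_expression(expr)
  .check_surv(surv)
  surv <- .align_phenotype(expr, surv)
  if (nrow(surv) < 10L) stop("need >= 10 samples", call. = FALSE)
  if (sum(surv$event) < 3L) stop("need >= 3 events", call. = FALSE)
  y <- survival::Surv(surv$time_months, surv$event)
  rows <- lapply(rownames(expr), function(g) {
    x <- expr[g, ]
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x, ties = "breslow")),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(stats::coef(fit))) {
      message("gene '", g, "' skipped (Cox fit failed)")
      return(NULL)
    }
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(fit$var[1, 1]))
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
    p <- 2 * stats::pnorm(-abs(beta / se))
    data.frame(gene = g, beta = beta, hazard_ratio = exp(beta),
               ci_lo = ci[1], ci_hi = ci[2], p_value = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no gene could be fit", call. = FALSE)
  tab$retained <- tab$p_value < alpha &
    if (hr_direction == "risk") tab$hazard_ratio > 1 else tab$hazard_ratio < 1
  rownames(tab) <- NULL
  list(table = tab, panel = .lex_sort(tab$gene[tab$retained]),
       hr_direction = hr_direction, alpha = alpha)
}

#' Kaplan-Meier comparison of median-split score groups
#'
#' Splits samples at the median score (ties to the low group), estimates
#' Kaplan-Meier curves per group, and compares them with the two-group
#' log-rank test.
#'
#' @param scores Named per-sample numeric scores (names match
#'   `surv$sample_id`).
#' @param surv Survival table (`sample_id`, `time_months`, `event`).
#' @return An object of class `km_comparison`: `groups` (named
#'   high/low factor), `logrank_chi2`, `p_value`, `median_survival` (per
#'   group, NA when not reached), and `km` (per-group step-curve points
#'   `group`, `time`, `surv`, `n_risk`, `n_event`).
#' @export
km_median_split <- function(scores, surv) {
  .check_surv(surv)
  if (is.null(names(scores))) stop("scores must be named by sample id", call. = FALSE)
  missing_ids <- setdiff(surv$sample_id, names(scores))
  if (length(missing_ids)) {
    stop("scores missing for: ", paste(utils::head(missing_ids, 5), collapse = ", "),
         call. = FALSE)
  }
  s <- scores[surv$sample_id]
  if (length(unique(s)) < 2L) {
    stop("degenerate split: all scores equal", call. = FALSE)
  }
  group <- factor(ifelse(s > stats::median(s), "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) < 2L)) stop("need >= 2 samples per split group", call. = FALSE)
  if (sum(surv$event) < 1L) stop("need >= 1 event", call. = FALSE)
  y <- survival::Surv(surv$time_months, surv$event)
  sd_fit <- survival::survdiff(y ~ group)
  chi2 <- sd_fit$chisq
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(y ~ group)
  med <- summary(sf)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(sf)$table))
  strata <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  km <- data.frame(group = strata, time = sf$time, surv = sf$surv,
                   n_risk = sf$n.risk, n_event = sf$n.event,
                   stringsAsFactors = FALSE)
  structure(list(groups = stats::setNames(as.character(group), surv$sample_id),
                 logrank_chi2 = chi2, p_value = p,
                 median_survival = med, km = km),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat(sprintf("log-rank chi2 = %.3f, p = %.4g\n", x$logrank_chi2, x$p_value))
  cat("median survival:", paste(names(x$median_survival),
                                signif(x$median_survival, 4),
                                sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Multivariate Cox model over supplied covariates
#'
#' Thin wrapper over a standard proportional-hazards fit (Breslow ties)
#' for assessing whether a signature score remains prognostic alongside
#' other covariates.
#'
#' @param covariates Data frame of covariates with a `sample_id` column.
#' @param surv Survival table.
#' @return Data frame with one row per covariate: `term`, `beta`,
#'   `hazard_ratio`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
multivariate_cox <- function(covariates, surv) {
  .check_surv(surv)
  stopifnot(is.data.frame(covariates), "sample_id" %in% names(covariates))
  m <- merge(surv, covariates, by = "sample_id", sort = FALSE)
  terms <- setdiff(names(covariates), "sample_id")
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~", paste(terms, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = m, ties = "breslow")
  sm <- summary(fit)
  data.frame(term = rownames(sm$coefficients),
             beta = sm$coefficients[, "coef"],
             hazard_ratio = sm$coefficients[, "exp(coef)"],
             ci_lo = sm$conf.int[, "lower .95"],
             ci_hi = sm$conf.int[, "upper .95"],
             p_value = sm$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
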