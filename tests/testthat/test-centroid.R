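test_that("perfectly separating genes give training AUC 1 on a tiny cohort", {
  toy <- make_toy_cohort(n_per_class = 2, n_genes = 4, n_signal = 2, delta = 10,
                         seed = 2)
  m <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression))
  ev <- evaluate_centroid(m, toy$expression, toy$phenotype)
  expect_equal(ev$auc, 1.0)
})

test_that("a sample matching the NR centroid scores maximally and is called NR", {
  toy <- make_toy_cohort(n_per_class = 6, n_genes = 6, n_signal = 3, delta = 5)
  m <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression))
  # construct the de-standardized NR centroid as a synthetic test sample
  x <- m$centroid_NR * m$gene_sd + m$gene_mean
  test_expr <- cbind(toy$expression[m$panel, ], centroid_sample = x)
  pred <- predict(m, test_expr)
  i <- which(pred$sample_id == "centroid_sample")
  expect_gte(pred$score_z[i], max(pred$score_z[-i]) - 1e-9)
  expect_equal(pred$call[i], "NR")
})

test_that("label swap negates the z-score (orientation contract)", {
  toy <- make_toy_cohort(n_per_class = 5, n_genes = 8, n_signal = 2, delta = 3)
  m1 <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression),
                     positive_class = "NR", negative_class = "R")
  m2 <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression),
                     positive_class = "R", negative_class = "NR")
  p1 <- predict(m1, toy$expression)
  p2 <- predict(m2, toy$expression)
  expect_equal(p1$score_z, -p2$score_z, tolerance = 1e-12)
})

test_that("probabilities are monotone in the score and hit 0.5 at the boundary", {
  toy <- make_toy_cohort(n_per_class = 10, n_genes = 10, n_signal = 3, delta = 2)
  m <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression))
  pred <- predict(m, toy$expression)
  ord <- order(pred$score_z)
  expect_true(all(diff(pred$prob_nonresponse[ord]) >= 0))
  # logistic midpoint: p = 0.5 exactly where a + b z = 0
  a <- m$calibration[["intercept"]]; b <- m$calibration[["slope"]]
  z0 <- -a / b
  expect_equal(plogis(a + b * z0), 0.5)
})

test_that("prediction uses training statistics only (affine contract)", {
  toy <- make_toy_cohort(n_per_class = 8, n_genes = 8, n_signal = 2, delta = 2,
                         seed = 10)
  m <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression))
  fresh <- make_toy_cohort(n_per_class = 8, n_genes = 8, n_signal = 2, delta = 2,
                           seed = 11)
  p_ref <- predict(m, fresh$expression)
  # scoring a subset of samples must not change their scores (no test-side
  # re-standardization)
  p_sub <- predict(m, fresh$expression[, 1:4])
  expect_equal(p_sub$score_z, p_ref$score_z[1:4], tolerance = 1e-12)
})

test_that("held-out AUC approaches the analytic multi-gene bound", {
  # 20-gene panel, half planted at delta = 1.5: clearly above 0.9 held out
  cfg <- simulation_config(n_genes = 100, n_samples_R = 100, n_samples_NR = 100,
                           n_signal_genes = 10, effect_size_delta = 1.5,
                           seed = 5)
  train <- simulate_bulk_cohort(cfg)
  test <- simulate_bulk_cohort(cfg, replicate = 2L)
  panel <- c(train$truth, setdiff(rownames(train$expression), train$truth)[1:10])
  m <- fit_centroid(train$expression, train$phenotype, panel)
  ev <- evaluate_centroid(m, test$expression, test$phenotype)
  expect_gte(ev$auc, 0.9)
})

test_that("null cohorts evaluate near AUC one half", {
  cfg <- simulation_config(n_genes = 60, n_samples_R = 100, n_samples_NR = 100,
                           n_signal_genes = 10, effect_size_delta = 0, seed = 19)
  co <- simulate_bulk_cohort(cfg)
  m <- fit_centroid(co$expression, co$phenotype, co$truth)
  fresh <- simulate_bulk_cohort(cfg, replicate = 2L)
  ev <- evaluate_centroid(m, fresh$expression, fresh$phenotype)
  expect_gt(ev$auc, 0.4)
  expect_lt(ev$auc, 0.6)
})

test_that("evaluation is invariant to sample order", {
  toy <- make_toy_cohort(n_per_class = 6, n_genes = 8, n_signal = 2, delta = 2)
  m <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression))
  perm <- sample(ncol(toy$expression))
  ev1 <- evaluate_centroid(m, toy$expression, toy$phenotype)
  ev2 <- evaluate_centroid(m, toy$expression[, perm],
                           toy$phenotype[perm, ])
  expect_equal(ev1$auc, ev2$auc)
  expect_equal(ev1$p_value, ev2$p_value)
})

test_that("panel handling enforces the three-gene minimum and drops bad genes", {
  toy <- make_toy_cohort(n_per_class = 4, n_genes = 6, n_signal = 2, delta = 3)
  expect_error(fit_centroid(toy$expression, toy$phenotype, c("t01", "t02")),
               "fewer than 3")
  expect_warning(
    m <- fit_centroid(toy$expression, toy$phenotype,
                      c(rownames(toy$expression), "absent_gene")),
    "missing"
  )
  # zero-variance gene is dropped, model still fits
  expr <- toy$expression
  expr["t06", ] <- 7
  expect_warning(
    m2 <- fit_centroid(expr, toy$phenotype, rownames(expr)),
    "zero-variance"
  )
  expect_false("t06" %in% m2$panel)
  # all genes missing at prediction time
  expect_error(
    suppressWarnings(predict(m2, toy$expression[1:2, , drop = FALSE])),
    "fewer than 3"
  )
})

test_that("mean predicted nonresponse probability resolves the classes", {
  cfg <- simulation_config(n_genes = 80, n_samples_R = 150, n_samples_NR = 150,
                           n_signal_genes = 15, effect_size_delta = 1, seed = 27)
  co <- simulate_bulk_cohort(cfg)
  panel <- c(co$truth, setdiff(rownames(co$expression), co$truth)[1:15])
  m <- fit_centroid(co$expression, co$phenotype, panel)
  fresh <- simulate_bulk_cohort(cfg, replicate = 2L)
  pred <- predict(m, fresh$expression)
  nr <- fresh$phenotype$response == "NR"
  expect_gt(mean(pred$prob_nonresponse[nr]), mean(pred$prob_nonresponse[!nr]))
})

test_that("models round-trip through JSON serialization", {
  toy <- make_toy_cohort(n_per_class = 5, n_genes = 8, n_signal = 2, delta = 2)
  m <- fit_centroid(toy$expression, toy$phenotype, rownames(toy$expression))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict(m2, toy$expression)$score_z,
               predict(m, toy$expression)$score_z, tolerance = 1e-12)
  expect_equal(m2$method, m$method)
})

test_that("euclidean mode preserves homogeneous shifts that correlation removes", {
  cfg <- simulation_config(n_genes = 40, n_samples_R = 60, n_samples_NR = 60,
                           n_signal_genes = 8, effect_size_delta = 1.5, seed = 7)
  co <- simulate_bulk_cohort(cfg)
  m_eu <- fit_centroid(co$expression, co$phenotype, co$truth,
                       method = "euclidean")
  ev <- evaluate_centroid(m_eu, co$expression, co$phenotype)
  expect_gte(ev$auc, 0.95)
})
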