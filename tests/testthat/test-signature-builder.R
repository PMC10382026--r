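test_that("candidate assembly performs the documented set arithmetic", {
  sets <- list(s1 = c("A", "B"), s2 = c("B", "C"))
  de <- list(sub1 = data.frame(gene = c("A", "B", "C", "D"),
                               avg_log2FC = c(0, 0, 0, 0),
                               stringsAsFactors = FALSE))
  gates <- data.frame(subtype = "sub1", direction = "greater",
                      threshold = -0.1, stringsAsFactors = FALSE)
  # gate > -0.1 keeps all genes when logFC = 0
  asm <- assemble_candidates(sets, de, gates, cohort_genes = c("B", "D"))
  expect_equal(asm$union_genelist, c("A", "B", "C"))
  expect_equal(asm$intersect_genelist, c("A", "B", "C", "D"))
  expect_equal(asm$panel0, "B")
  # disjoint gate-passing genes across subtypes empty the intersection
  de2 <- list(x = data.frame(gene = c("A", "B"), avg_log2FC = c(1, -1)),
              y = data.frame(gene = c("A", "B"), avg_log2FC = c(-1, 1)))
  gates2 <- data.frame(subtype = c("x", "y"), direction = "greater",
                       threshold = 0, stringsAsFactors = FALSE)
  expect_error(assemble_candidates(sets, de2, gates2, c("A", "B")),
               "empty candidate panel")
  expect_error(assemble_candidates(sets, de, gates[0, ], c("B")), "at least one")
  gates3 <- data.frame(subtype = "nope", direction = "less", threshold = 0)
  expect_error(assemble_candidates(sets, de, gates3, c("B")), "absent")
})

test_that("a sub-minimum assembled panel fails at fit time", {
  toy <- make_toy_cohort(n_per_class = 4, n_genes = 6, n_signal = 2)
  expect_error(fit_centroid(toy$expression, toy$phenotype, "t01"),
               "fewer than 3")
})

test_that("elimination trace has the promised shape and evaluation count", {
  toy <- make_toy_cohort(n_per_class = 8, n_genes = 10, n_signal = 2,
                         delta = 2, seed = 3)
  for (p in c(5L, 7L, 10L)) {
    panel0 <- rownames(toy$expression)[seq_len(p)]
    tr <- recursive_elimination(panel0, toy$expression, toy$phenotype)
    expect_equal(nrow(tr$cycles), p - 3L + 1L)
    expect_equal(tr$cycles$panel_size, seq(p, 3L))
    expect_equal(tr$n_evaluations, p * (p + 1) / 2 - 5)
    expect_true(all(tr$cycles$best_auc >= 0 & tr$cycles$best_auc <= 1))
    # selected is the global max; ties resolve to the earliest attainment
    best <- max(tr$cycles$best_auc)
    tied <- which(tr$cycles$best_auc >= best - 1e-9)
    expect_equal(length(tr$selected),
                 max(tr$cycles$panel_size[tied]))
    expect_equal(tr$selected_auc, best, tolerance = 1e-9)
  }
})

test_that("greedy per-cycle winners match brute-force fit/evaluate", {
  # the invariant that justifies the fast leave-one-out path
  toy <- make_toy_cohort(n_per_class = 6, n_genes = 8, n_signal = 2,
                         delta = 1.5, seed = 21)
  for (p in 4:8) {
    panel <- rownames(toy$expression)[seq_len(p)]
    tr <- recursive_elimination(panel, toy$expression, toy$phenotype)
    current <- panel
    for (cyc in 2:nrow(tr$cycles)) {
      ref <- suppressWarnings(
        oracle_elimination_cycle(current, toy$expression, toy$phenotype)
      )
      expect_equal(tr$cycles$removed_gene[cyc], ref$removed)
      expect_equal(tr$cycles$best_auc[cyc], ref$best_auc, tolerance = 1e-9)
      current <- setdiff(current, ref$removed)
    }
  }
})

test_that("planted perfect separators are retained and reach AUC 1", {
  # A, B separate perfectly; C, D are noise; 12-sample toy
  set.seed(31)
  expr <- matrix(rnorm(4 * 12, mean = 2), nrow = 4,
                 dimnames = list(c("A", "B", "C", "D"), sprintf("s%02d", 1:12)))
  response <- rep(c("R", "NR"), each = 6)
  expr["A", response == "NR"] <- expr["A", response == "NR"] + 10
  expr["B", response == "NR"] <- expr["B", response == "NR"] - 10
  pheno <- data.frame(sample_id = colnames(expr), response = response,
                      stringsAsFactors = FALSE)
  tr <- recursive_elimination(c("A", "B", "C", "D"), expr, pheno)
  expect_equal(tr$selected_auc, 1.0)
  expect_true(any(c("A", "B") %in% tr$selected))
  # cross-check the winning AUC against every size-3 subset by brute force
  combos <- combn(c("A", "B", "C", "D"), 3, simplify = FALSE)
  brute <- vapply(combos, function(s) {
    suppressWarnings(evaluate_centroid(
      fit_centroid(expr, pheno, s), expr, pheno
    )$auc)
  }, numeric(1))
  expect_equal(tr$cycles$best_auc[2], max(brute), tolerance = 1e-9)
})

test_that("pure-noise panels do not inflate the selected AUC", {
  cfg <- simulation_config(n_genes = 5, n_samples_R = 200, n_samples_NR = 200,
                           n_signal_genes = 0, effect_size_delta = 0, seed = 101)
  co <- simulate_bulk_cohort(cfg)
  tr <- recursive_elimination(rownames(co$expression), co$expression,
                              co$phenotype)
  expect_lt(tr$selected_auc, 0.75)
})

test_that("build_signature honors size_override and determinism", {
  toy <- make_toy_cohort(n_per_class = 10, n_genes = 12, n_signal = 3,
                         delta = 2, seed = 77)
  panel0 <- rownames(toy$expression)
  fit1 <- build_signature(panel0, toy$expression, toy$phenotype)
  fit2 <- build_signature(panel0, toy$expression, toy$phenotype)
  expect_identical(fit1$panel, fit2$panel)
  expect_identical(fit1$trace$cycles, fit2$trace$cycles)
  # override reproduces a manual pick at a given size
  fit5 <- build_signature(panel0, toy$expression, toy$phenotype,
                          size_override = 5)
  expect_equal(fit5$panel$size, 5)
  i <- match(5, fit1$trace$cycles$panel_size)
  expect_equal(fit5$panel$genes, fit1$trace$panels[[i]])
  # degenerate override: the full panel itself
  fit_all <- build_signature(panel0, toy$expression, toy$phenotype,
                             size_override = length(panel0))
  expect_setequal(fit_all$panel$genes, panel0)
  expect_error(build_signature(panel0, toy$expression, toy$phenotype,
                               size_override = 2), "size_override")
  expect_error(build_signature(panel0, toy$expression, toy$phenotype,
                               size_override = 13), "size_override")
})

test_that("signature recovery on a planted cohort with held-out validation", {
  # scaled-down version of the full recovery study (one seed)
  cfg <- simulation_config(n_genes = 80, n_samples_R = 60, n_samples_NR = 60,
                           n_signal_genes = 12, effect_size_delta = 1, seed = 202)
  train <- simulate_bulk_cohort(cfg)
  fit <- build_signature(rownames(train$expression), train$expression,
                         train$phenotype)
  expect_gte(mean(train$truth %in% fit$panel$genes), 0.6)
  val <- simulate_bulk_cohort(cfg, replicate = 2L)
  ev <- evaluate_centroid(fit$model, val$expression, val$phenotype)
  expect_gte(ev$auc, 0.85)
})

test_that("a failed subset scores zero instead of aborting the search", {
  toy <- make_toy_cohort(n_per_class = 4, n_genes = 5, n_signal = 2, delta = 5,
                         seed = 12)
  expr <- toy$expression
  expr["t04", ] <- 1 # zero variance: unusable gene
  expr["t05", ] <- 2
  # panel of 4 with 2 dead genes: subsets dropping a live gene have < 3
  # usable genes and must score 0, not error
  tr <- recursive_elimination(c("t01", "t02", "t04", "t05"), expr,
                              toy$phenotype)
  expect_true(all(is.finite(tr$cycles$best_auc)))
})
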