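# tiny, well-separated cohort for fast classifier checks
tiny_sim <- function(seed = 51, ...) {
  small_sim(seed = seed, samples_per_type = 20,
            n_panel_genes = 25, n_expression_genes = 40,
            driver_genes = c("DRVA", "DRVB", "DRVC"),
            samples_per_driver = 10, tissue_shift_sd = 0.3,
            noise_sd = 0.3, ...)
}

test_that("balanced subsampling equalises class sizes deterministically", {
  labels <- stats::setNames(
    rep(c("a", "b", "c"), times = c(15, 40, 22)),
    sprintf("s%02d", 1:77))
  ids <- balanced_subsample(labels, seed = 1)
  expect_length(ids, 45)
  expect_true(all(table(labels[ids]) == 15))
  expect_identical(ids, balanced_subsample(labels, seed = 1))
  expect_false(identical(balanced_subsample(labels, seed = 0),
                         balanced_subsample(labels, seed = 1)))
  # all classes already minimal: identity set
  eq <- stats::setNames(rep(c("a", "b"), each = 3), paste0("t", 1:6))
  expect_setequal(balanced_subsample(eq, seed = 9), names(eq))
})

test_that("AUROC follows the Mann-Whitney pair formulation", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auroc(c(0.7, 0.3, 0.5, 0.2),
                     c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(auroc(c(1, 2), c(TRUE, TRUE)), "positive")
  # invariant under strictly monotone transforms
  set.seed(4)
  for (i in 1:10) {
    sc <- round(runif(12), 1)   # induce ties
    lab <- sample(c(TRUE, FALSE), 12, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (!any(lab) || all(lab)) next
    a <- auroc(sc, lab)
    expect_equal(auroc(exp(3 * sc) + 2, lab), a)
    expect_equal(a, bf_auroc(sc, lab))
  }
})

test_that("multiclass accuracy averages repeats, ties break canonically", {
  pred <- data.frame(
    repeat_idx = c(1L, 1L, 2L, 2L),
    sample_id = c("s1", "s2", "s1", "s2"),
    true_label = c("a", "b", "a", "b"),
    a = c(0.6, 0.5, 0.2, 0.5), b = c(0.4, 0.5, 0.8, 0.5),
    stringsAsFactors = FALSE)
  # repeat 1: s1 correct, s2 tie -> argmax "a" (first canonical) -> wrong
  # repeat 2: s1 wrong, s2 tie -> "a" -> wrong
  expect_equal(multiclass_accuracy(pred, genes = c("a", "b")),
               mean(c(0.5, 0)))
})

test_that("cross-validation is deterministic and probabilistically valid", {
  sim <- tiny_sim()
  prep <- suppressWarnings(prepare_cohort(sim, adjust = FALSE))
  cv1 <- mex_cv(prep$expr_panel, prep$design, k = 5, n_repeats = 2,
                classifier = rf_classifier(num_trees = 100), seed = 7)
  cv2 <- mex_cv(prep$expr_panel, prep$design, k = 5, n_repeats = 2,
                classifier = rf_classifier(num_trees = 100), seed = 7)
  expect_identical(cv1$predictions, cv2$predictions)

  probs <- as.matrix(cv1$predictions[, cv1$genes])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  # each subsampled sample appears exactly once per repeat
  for (r in 1:2) {
    ids <- cv1$predictions$sample_id[cv1$predictions$repeat_idx == r]
    expect_false(anyDuplicated(ids) > 0)
  }
  # well-separated synthetic classes are recovered perfectly
  s <- summary(cv1)
  expect_equal(s$accuracy, 1)
  expect_true(all(s$gene_auroc$auroc == 1))
  expect_equal(s$chance_accuracy, 1 / 3)

  # a class smaller than k is rejected
  bad <- prep$design$training[1:12]
  expect_error(mex_cv(prep$expr_panel, bad, k = 5, n_repeats = 1), "fewer")
})

test_that("label shuffling drives accuracy to chance", {
  sim <- tiny_sim(seed = 52)
  prep <- suppressWarnings(prepare_cohort(sim, adjust = FALSE))
  labels <- prep$design$training
  set.seed(8)
  shuffled <- stats::setNames(sample(unname(labels)), names(labels))
  cv <- mex_cv(prep$expr_panel, shuffled, k = 5, n_repeats = 2,
               classifier = rf_classifier(num_trees = 100), seed = 9)
  acc <- multiclass_accuracy(cv)
  n <- length(labels)
  sigma <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(acc - 1 / 3), 3 * sigma + 0.05)
})

test_that("test-set projection recovers a planted rare-gene match", {
  sim <- small_sim(seed = 53, rare_drivers = c(RAREX = "DRV2"),
                   rare_samples_per_driver = 6)
  prep <- prepare_cohort(sim, adjust = FALSE)
  expect_identical(prep$design$test_genes, "RAREX")
  tp <- predict_test_set(prep$expr_panel, prep$design,
                         classifier = rf_classifier(num_trees = 100),
                         n_repeats = 3, seed = 11)
  probs <- as.matrix(tp[, prep$design$training_genes])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  mean_by_class <- colMeans(probs[tp$true_label == "RAREX", , drop = FALSE])
  expect_identical(names(which.max(mean_by_class)), "DRV2")

  empty <- prep$design
  empty$test <- character(0)
  expect_error(predict_test_set(prep$expr_panel, empty), "empty test set")
})

test_that("cancer type is predictable from expression when shifts exist", {
  sim <- tiny_sim(seed = 54, tissue_shift_sd = 2)
  expr_log <- log_transform(average_replicates(sim$expression))
  expr_adj <- batch_adjust(expr_log, sim$annotation)
  acc <- predict_cancer_type(expr_log, expr_adj, sim$annotation, k = 5,
                             classifier = rf_classifier(num_trees = 100),
                             seed = 3)
  expect_gt(acc[["raw"]], 0.9)
  expect_true(all(acc >= 0 & acc <= 1))
})

test_that("mutation-from-type accuracy tracks the label-type association", {
  # labels perfectly determined by type
  ann <- data.frame(sample_id = sprintf("s%02d", 1:60),
                    cancer_type = rep(c("T1", "T2", "T3"), each = 20),
                    stringsAsFactors = FALSE)
  labels <- stats::setNames(rep(c("gA", "gB", "gC"), each = 20),
                            ann$sample_id)
  acc <- predict_mutation_from_type(ann, labels, k = 5, n_repeats = 2,
                                    classifier =
                                      rf_classifier(num_trees = 100),
                                    seed = 5)
  expect_gt(acc, 0.95)
  # labels independent of type
  set.seed(6)
  rnd <- stats::setNames(sample(rep(c("gA", "gB", "gC"), each = 20)),
                         ann$sample_id)
  acc0 <- predict_mutation_from_type(ann, rnd, k = 5, n_repeats = 2,
                                     classifier =
                                       rf_classifier(num_trees = 100),
                                     seed = 5)
  expect_lt(abs(acc0 - 1 / 3), 0.2)
})
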