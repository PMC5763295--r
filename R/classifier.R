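#' Probabilistic random-forest classifier (pluggable contract)
#'
#' The cross-validation engine accepts any classifier object implementing
#' the contract: `$fit(x, y, seed)` returns a fitted model from a numeric
#' feature matrix `x` (samples in rows) and a factor `y`; `$predict(model,
#' x)` returns a samples-by-classes matrix of class probabilities with class
#' colnames, rows summing to 1. The reference classifier is a random forest
#' with conventional defaults: 500 trees, `floor(sqrt(p))` candidate
#' features per split, probabilities from the forest's per-class vote/leaf
#' frequencies (ranger probability forest), single-threaded and seeded for
#' reproducibility.
#'
#' @param num_trees Number of trees (default 500).
#' @param mtry Candidate features per split; `NULL` for `floor(sqrt(p))`.
#' @return An object of class `"mutexpr_classifier"`.
#' @export
rf_classifier <- function(num_trees = 500, mtry = NULL) {
  structure(list(
    name = sprintf("random forest (%d trees)", num_trees),
    fit = function(x, y, seed) {
      y <- droplevels(as.factor(y))
      ranger::ranger(x = x, y = y, probability = TRUE,
                     num.trees = num_trees, mtry = mtry,
                     num.threads = 1, seed = seed)
    },
    predict = function(model, x) {
      p <- stats::predict(model, data = x, num.threads = 1)$predictions
      p[, order(colnames(p)), drop = FALSE]
    }
  ), class = "mutexpr_classifier")
}

#' Balanced subsample of a labeled cohort
#'
#' Down-samples every class, without replacement, to the minimum class size
#' so that class imbalance cannot bias the classifier. Deterministic given
#' the seed; the analysis protocol repeats this several times with different
#' seeds and averages the results.
#'
#' @param labels Named character vector, sample ID -> class label.
#' @param seed Integer seed.
#' @return Character vector of retained sample IDs (class-major order).
#' @export
balanced_subsample <- function(labels, seed) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  m <- min(table(labels))
  set.seed(seed)
  unlist(lapply(classes, function(cl) {
    ids <- names(labels)[labels == cl]
    if (length(ids) == m) ids else sample(ids, m)
  }), use.names = FALSE)
}

# Stratified fold assignment: within each class, samples are permuted and
# dealt into folds round-robin, so every fold sees every class.
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has ", length(idx), " samples; fewer than k = ", k)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# One repeat of balanced subsampling + stratified k-fold CV; returns the
# out-of-fold probabilistic predictions for the subsampled samples.
.cv_one_repeat <- function(features, labels, k, classifier, seed) {
  ids <- balanced_subsample(labels, seed)
  y <- labels[ids]
  x <- features[ids, , drop = FALSE]
  fold <- .stratified_folds(y, k, seed + 1L)
  classes <- sort(unique(labels))
  probs <- matrix(NA_real_, nrow = length(ids), ncol = length(classes),
                  dimnames = list(ids, classes))
  for (f in seq_len(k)) {
    held <- fold == f
    model <- classifier$fit(x[!held, , drop = FALSE], y[!held],
                            seed = seed + f)
    p <- classifier$predict(model, x[held, , drop = FALSE])
    probs[held, colnames(p)] <- p
  }
  data.frame(repeat_idx = NA_integer_, fold = fold, sample_id = ids,
             true_label = unname(y), probs,
             stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
}

.cv_predictions <- function(features, labels, k, n_repeats, classifier,
                            seed) {
  reps <- lapply(seq_len(n_repeats), function(r) {
    out <- .cv_one_repeat(features, labels, k, classifier,
                          seed = seed + 1000L * r)
    out$repeat_idx <- r
    out
  })
  do.call(rbind, reps)
}

#' Cross-validated prediction of mutated-gene identity from expression
#'
#' The core fitting function: balanced-subsampled, stratified k-fold
#' cross-validated probabilistic classification of which training gene is
#' aberrant in each tumor, from (batch-adjusted) expression of the panel
#' genes. For each of `n_repeats` repeats, every class is down-sampled to
#' the minimum class size, the subsample is partitioned into `k` stratified
#' folds, and out-of-fold class probabilities are collected. High
#' out-of-fold performance for a gene indicates that its aberrations leave a
#' distinct transcriptional footprint.
#'
#' @param expr [expression_matrix()] (log2 or batch-adjusted) whose rows
#'   should already be restricted to the gene panel.
#' @param design `"cohort_design"` from [build_training_cohort()], or a
#'   named character vector of labels.
#' @param k Folds (default 5).
#' @param n_repeats Balanced-subsampling repeats (default 10).
#' @param classifier A [rf_classifier()]-style contract object.
#' @param seed Integer seed controlling subsamples, folds and forests.
#' @return Object of class `"mex_cv"`: `predictions` (one row per repeat and
#'   subsampled sample: `repeat_idx`, `fold`, `sample_id`, `true_label`, one
#'   probability column per class), `genes`, `k`, `n_repeats`, `seed`,
#'   `classifier`.
#' @seealso [summary.mex_cv()], [prediction_similarity()],
#'   [predict_test_set()]
#' @export
mex_cv <- function(expr, design, k = 5, n_repeats = 10,
                   classifier = rf_classifier(), seed = 1) {
  labels <- if (inherits(design, "cohort_design")) design$training else design
  stopifnot(length(labels) > 0, !is.null(names(labels)))
  features <- .features_for(expr, names(labels))
  preds <- .cv_predictions(features, labels, k, n_repeats, classifier, seed)
  structure(list(
    predictions = preds,
    genes = sort(unique(labels)),
    k = k, n_repeats = n_repeats, seed = seed,
    classifier = classifier$name,
    call = match.call()
  ), class = "mex_cv")
}

.features_for <- function(expr, sample_ids) {
  stopifnot(inherits(expr, "expr_matrix"))
  missing <- setdiff(sample_ids, colnames(expr$values))
  if (length(missing) > 0) {
    stop("samples absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  t(expr$values[, sample_ids, drop = FALSE])
}

#' @export
print.mex_cv <- function(x, ...) {
  cat("<mex_cv> ", length(x$genes), " classes, ", x$n_repeats, " repeats x ",
      x$k, "-fold CV, ", x$classifier, "\n", sep = "")
  cat("  classes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with half credit for ties:
#' `(#\{score_pos > score_neg\} + 0.5 * #ties) / (n_pos * n_neg)`, computed
#' via the rank-sum identity.
#'
#' @param scores Numeric scores.
#' @param is_positive Logical vector, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive), !anyNA(scores),
            is.logical(is_positive))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC undefined: need at least one positive and one negative")
  }
  r <- rank(scores)
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Multiclass accuracy of a prediction table
#'
#' Fraction of predictions whose arg-max class equals the true label,
#' computed per repeat and averaged. Ties in the arg-max are broken by the
#' first class in canonical (alphabetical) order.
#'
#' @param predictions Prediction `data.frame` (as in a `mex_cv` object) or a
#'   `mex_cv` object.
#' @param genes Class columns; defaults to the object's classes.
#' @return Mean accuracy over repeats.
#' @export
multiclass_accuracy <- function(predictions, genes = NULL) {
  if (inherits(predictions, "mex_cv")) {
    genes <- predictions$genes
    predictions <- predictions$predictions
  }
  if (is.null(genes)) {
    genes <- sort(setdiff(names(predictions),
                          c("repeat_idx", "fold", "sample_id", "true_label")))
  }
  p <- as.matrix(predictions[, genes, drop = FALSE])
  hit <- genes[max.col(p, ties.method = "first")] == predictions$true_label
  mean(tapply(hit, predictions$repeat_idx, mean))
}

.per_gene_auroc <- function(predictions, genes) {
  reps <- sort(unique(predictions$repeat_idx))
  per_rep <- vapply(reps, function(r) {
    sub <- predictions[predictions$repeat_idx == r, , drop = FALSE]
    vapply(genes, function(g) {
      auroc(sub[[g]], sub$true_label == g)
    }, numeric(1))
  }, numeric(length(genes)))
  per_rep <- matrix(per_rep, nrow = length(genes),
                    dimnames = list(genes, paste0("rep", reps)))
  per_rep
}

#' Summarise cross-validated predictions
#'
#' Per-gene one-vs-rest AUROC (computed within each repeat on that gene's
#' probability column, then averaged over repeats), multiclass accuracy, and
#' the corresponding chance levels (1/K accuracy, 0.5 AUROC).
#'
#' @param object A `"mex_cv"` object.
#' @param ... Unused.
#' @return Object of class `"mex_cv_summary"` with elements `gene_auroc`
#'   (data.frame gene/auroc), `auroc_by_repeat` (genes x repeats matrix),
#'   `accuracy`, `accuracy_by_repeat`, `chance_accuracy`, `chance_auroc`,
#'   `n_classes`.
#' @export
summary.mex_cv <- function(object, ...) {
  genes <- object$genes
  per_rep <- .per_gene_auroc(object$predictions, genes)
  p <- as.matrix(object$predictions[, genes, drop = FALSE])
  hit <- genes[max.col(p, ties.method = "first")] ==
    object$predictions$true_label
  acc_rep <- tapply(hit, object$predictions$repeat_idx, mean)
  structure(list(
    gene_auroc = data.frame(gene = genes, auroc = rowMeans(per_rep),
                            row.names = NULL, stringsAsFactors = FALSE),
    auroc_by_repeat = per_rep,
    accuracy = mean(acc_rep),
    accuracy_by_repeat = as.numeric(acc_rep),
    chance_accuracy = 1 / length(genes),
    chance_auroc = 0.5,
    n_classes = length(genes)
  ), class = "mex_cv_summary")
}

#' @export
print.mex_cv_summary <- function(x, digits = 3, ...) {
  cat("Cross-validated mutation-status prediction\n")
  cat(sprintf("  accuracy: %.3f (chance %.2f, K = %d)\n",
              x$accuracy, x$chance_accuracy, x$n_classes))
  cat("  per-gene AUROC (chance 0.50):\n")
  df <- x$gene_auroc
  for (i in seq_len(nrow(df))) {
    cat(sprintf("    %-12s %.*f\n", df$gene[i], digits, df$auroc[i]))
  }
  invisible(x)
}

#' Plot per-gene AUROC values
#'
#' @param x A `"mex_cv"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mex_cv <- function(x, ...) {
  s <- summary(x)
  graphics::barplot(stats::setNames(s$gene_auroc$auroc, s$gene_auroc$gene),
                    ylim = c(0, 1), ylab = "AUROC (one-vs-rest)",
                    las = 2, ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Project the test set through models trained on the full training set
#'
#' For each of `n_repeats` balanced subsamples of the full training set, a
#' model is trained on the whole subsample and class probabilities are
#' predicted for every test sample; per-sample probabilities are averaged
#' over the repeat models. This relates rarely mutated (test) genes to the
#' common (training) gene classes.
#'
#' @param expr [expression_matrix()] covering training and test samples
#'   (panel genes).
#' @param design `"cohort_design"` with a non-empty test set.
#' @param classifier Classifier contract object.
#' @param n_repeats Balanced-subsampling repeats (default 10).
#' @param seed Integer seed.
#' @return `data.frame`: `sample_id`, `true_label` (test gene), one averaged
#'   probability column per training gene.
#' @export
predict_test_set <- function(expr, design, classifier = rf_classifier(),
                             n_repeats = 10, seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  if (length(design$test) == 0) stop("empty test set")
  labels <- design$training
  x_train_all <- .features_for(expr, names(labels))
  x_test <- .features_for(expr, names(design$test))
  classes <- sort(unique(labels))
  acc <- matrix(0, nrow = nrow(x_test), ncol = length(classes),
                dimnames = list(rownames(x_test), classes))
  for (r in seq_len(n_repeats)) {
    ids <- balanced_subsample(labels, seed + 1000L * r)
    model <- classifier$fit(x_train_all[ids, , drop = FALSE], labels[ids],
                            seed = seed + r)
    acc <- acc + classifier$predict(model, x_test)[, classes, drop = FALSE]
  }
  probs <- acc / n_repeats
  data.frame(sample_id = rownames(x_test),
             true_label = unname(design$test),
             probs, stringsAsFactors = FALSE, row.names = NULL,
             check.names = FALSE)
}

# Plain stratified k-fold CV accuracy (no subsampling), used for the
# tissue-confounding follow-up analyses.
.cv_accuracy <- function(features, labels, k, classifier, seed) {
  y <- labels
  fold <- .stratified_folds(y, k, seed)
  classes <- sort(unique(y))
  correct <- logical(length(y))
  for (f in seq_len(k)) {
    held <- fold == f
    model <- classifier$fit(features[!held, , drop = FALSE], y[!held],
                            seed = seed + f)
    p <- classifier$predict(model, features[held, , drop = FALSE])
    correct[held] <- colnames(p)[max.col(p, ties.method = "first")] == y[held]
  }
  mean(correct)
}

#' Predict cancer type from expression, before and after batch adjustment
#'
#' Follow-up confounding check: stratified k-fold CV accuracy for
#' cancer-type labels on the unadjusted and the batch-adjusted expression
#' matrices. A high accuracy on the adjusted matrix shows that a detectable
#' tissue footprint survives the adjustment.
#'
#' @param expr_raw,expr_adjusted [expression_matrix()] objects sharing
#'   sample columns.
#' @param annotation Sample annotation `data.frame`.
#' @param k Folds (default 5).
#' @param classifier Classifier contract object.
#' @param seed Integer seed.
#' @return Named numeric vector `c(raw = ..., adjusted = ...)`.
#' @export
predict_cancer_type <- function(expr_raw, expr_adjusted, annotation, k = 5,
                                classifier = rf_classifier(), seed = 1) {
  ids <- colnames(expr_raw$values)
  idx <- match(ids, annotation$sample_id)
  stopifnot(!anyNA(idx))
  labels <- stats::setNames(annotation$cancer_type[idx], ids)
  c(raw = .cv_accuracy(.features_for(expr_raw, ids), labels, k,
                       classifier, seed),
    adjusted = .cv_accuracy(.features_for(expr_adjusted, ids), labels, k,
                            classifier, seed))
}

#' Predict mutation status from cancer type alone
#'
#' Second confounding check: the same balanced-subsampled CV protocol as
#' [mex_cv()], but with one-hot-encoded cancer type as the only features.
#' Accuracy near the expression-based accuracy indicates that tumor type is
#' confounded with mutation status.
#'
#' @param annotation Sample annotation `data.frame`.
#' @param labels Named character vector, sample -> training gene.
#' @param k Folds (default 5).
#' @param n_repeats Repeats (default 10).
#' @param classifier Classifier contract object.
#' @param seed Integer seed.
#' @return Mean multiclass accuracy over repeats.
#' @export
predict_mutation_from_type <- function(annotation, labels, k = 5,
                                       n_repeats = 10,
                                       classifier = rf_classifier(),
                                       seed = 1) {
  idx <- match(names(labels), annotation$sample_id)
  stopifnot(!anyNA(idx))
  ty <- factor(annotation$cancer_type[idx])
  onehot <- stats::model.matrix(~ 0 + ty)
  rownames(onehot) <- names(labels)
  colnames(onehot) <- levels(ty)
  preds <- .cv_predictions(onehot, labels, k, n_repeats, classifier, seed)
  multiclass_accuracy(preds, genes = sort(unique(labels)))
}
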