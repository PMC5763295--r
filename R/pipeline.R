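#' Run the full aberration-to-similarity pipeline
#'
#' Orchestrates every stage from raw inputs to tidy outputs:
#' read -> variant filtering and aberration merging -> expression
#' preparation (replicate averaging, log2, batch adjustment when the scope
#' spans several cancer types) -> mutually exclusive cohort construction ->
#' cross-validated prediction metrics -> prediction-correlation similarity
#' -> test-set projection and train/test association -> single-gene Welch
#' tests -> tissue-confounding checks. Row counts are logged per stage;
#' identical configuration and seed give identical outputs.
#'
#' The configuration is a named list (or a path to a YAML file with the
#' same structure) with either `input:` (paths `mutations`, `cnv`,
#' `expression`, `annotation`, `panel`, `evidence`) or `simulate:`
#' (arguments for [simulate_config()]), plus optional keys `scope`
#' (`"pan"`, the default, or a single cancer type), `min_train_count`
#' (default 10 for a single type, 50 pan-cancer), `min_test_count` (5),
#' `k_folds` (5), `n_repeats` (10), `seed` (1), `batch_adjust` (default:
#' `TRUE` iff the scope spans more than one cancer type), `num_trees`
#' (500), and `single_gene_pairs` (list of `c(gene_a, gene_b)`; default the
#' two most aberrant training genes).
#'
#' @param config Named list or YAML path.
#' @param outdir Output directory for tidy TSVs, or `NULL` to skip writing.
#' @return Invisibly, a list with every intermediate and final object
#'   (`aberrations`, `expression`, `design`, `cv`, `metrics`, `similarity`,
#'   `test_predictions`, `association`, `single_gene`, `confounding`,
#'   `attrition_pct`, ...).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$input) == is.null(config$simulate)) {
    stop("config must have exactly one of 'input' (paths) or 'simulate'")
  }
  seed <- config$seed %||% 1L

  if (!is.null(config$simulate)) {
    sim_args <- lapply(config$simulate, function(x) {
      if (is.list(x)) unlist(x) else x   # YAML maps -> named vectors
    })
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- simulate_cohort(do.call(simulate_config, sim_args))
    mutations <- sim$mutations
    cnv <- sim$cnv
    expr_raw <- sim$expression
    annotation <- sim$annotation
    panel <- sim$panel
    evidence <- sim$evidence
  } else {
    paths <- config$input
    for (key in c("mutations", "cnv", "expression", "annotation", "panel",
                  "evidence")) {
      if (is.null(paths[[key]])) stop("config$input missing path: ", key)
      if (!file.exists(paths[[key]])) {
        stop("input file does not exist: ", paths[[key]])
      }
    }
    mutations <- read_mutations(paths$mutations)
    cnv <- read_cnv_matrix(paths$cnv)
    expr_raw <- read_expression_matrix(paths$expression)
    annotation <- read_sample_annotation(paths$annotation)
    panel <- read_gene_panel(paths$panel)
    evidence <- read_evidence(paths$evidence)
    sim <- NULL
  }

  scope <- config$scope %||% "pan"
  if (!identical(scope, "pan")) {
    keep <- annotation$sample_id[annotation$cancer_type %in% scope]
    annotation <- annotation[annotation$sample_id %in% keep, , drop = FALSE]
  }
  multi_type <- length(unique(annotation$cancer_type)) > 1
  do_adjust <- config$batch_adjust %||% multi_type
  min_train <- config$min_train_count %||% (if (multi_type) 50L else 10L)
  min_test <- config$min_test_count %||% 5L
  k <- config$k_folds %||% 5L
  n_repeats <- config$n_repeats %||% 10L
  classifier <- rf_classifier(num_trees = config$num_trees %||% 500)

  message("stage read: ", nrow(mutations), " mutation records, ",
          nrow(cnv), "x", ncol(cnv), " CNV matrix, ",
          nrow(expr_raw$values), "x", ncol(expr_raw$values),
          " expression matrix")

  filtered <- filter_somatic(mutations)
  attrition <- filter_attrition(nrow(mutations), nrow(filtered))
  message(sprintf("stage filter: %d -> %d records (%.1f%% removed)",
                  nrow(mutations), nrow(filtered), attrition))

  expr_avg <- average_replicates(expr_raw)
  expr_log <- log_transform(expr_avg)
  # sample universe: all three molecular types present. A sample absent from
  # the variant table but present in the CNV and expression matrices still
  # counts as having mutation data (zero surviving somatic calls).
  samples <- Reduce(intersect, list(colnames(expr_log$values),
                                    colnames(cnv),
                                    annotation$sample_id))
  ab <- merge_aberrations(filtered, cnv, panel, samples)
  message("stage merge: ", nrow(ab), " panel genes x ", ncol(ab),
          " samples with all three data types, ", sum(ab), " aberrant cells")

  expr_use <- if (do_adjust) batch_adjust(expr_log, annotation) else expr_log
  expr_panel_vals <- expr_use$values[intersect(panel,
                                               rownames(expr_use$values)), ,
                                     drop = FALSE]
  expr_panel <- expression_matrix(expr_panel_vals, expr_use$state)
  pca <- pca_coords(expr_use, k = 2)
  message("stage expression: state ", expr_use$state, ", ",
          nrow(expr_panel$values), " panel genes")

  design <- build_training_cohort(ab, min_count = min_train)
  design <- build_test_cohort(ab, design, evidence, min_count = min_test)
  message("stage cohort: ", length(design$training_genes), " classes, ",
          length(design$training), " training / ", length(design$test),
          " test samples")

  cv <- mex_cv(expr_panel, design, k = k, n_repeats = n_repeats,
               classifier = classifier, seed = seed)
  metrics <- summary(cv)
  message(sprintf("stage cv: accuracy %.3f (chance %.2f)", metrics$accuracy,
                  metrics$chance_accuracy))

  sim_mat <- prediction_similarity(cv)

  test_pred <- NULL
  assoc <- NULL
  if (length(design$test) > 0) {
    test_pred <- predict_test_set(expr_panel, design, classifier,
                                  n_repeats = n_repeats, seed = seed)
    assoc <- test_train_association(test_pred, design)
    message("stage projection: ", nrow(test_pred), " test samples, ",
            length(unique(assoc$test_gene)), " test genes associated")
  }

  pairs <- config$single_gene_pairs
  if (is.null(pairs)) {
    top <- names(sort(rowSums(ab[design$training_genes, , drop = FALSE]),
                      decreasing = TRUE))[1:2]
    pairs <- list(top)
  }
  single_gene <- do.call(rbind, lapply(pairs, function(pr) {
    rbind(compare_expression_groups(expr_panel, ab, pr[1], pr[2],
                                    expr_gene = pr[1]),
          compare_expression_groups(expr_panel, ab, pr[1], pr[2],
                                    expr_gene = pr[2]))
  }))

  confounding <- NULL
  if (multi_type) {
    shared <- intersect(colnames(expr_log$values), colnames(ab))
    raw_sub <- expression_matrix(expr_log$values[, shared, drop = FALSE],
                                 expr_log$state)
    adj_sub <- expression_matrix(expr_use$values[, shared, drop = FALSE],
                                 expr_use$state)
    type_acc <- predict_cancer_type(raw_sub, adj_sub, annotation, k = k,
                                    classifier = classifier, seed = seed)
    mut_from_type <- predict_mutation_from_type(annotation, design$training,
                                                k = k,
                                                n_repeats = n_repeats,
                                                classifier = classifier,
                                                seed = seed)
    confounding <- data.frame(
      check = c("cancer_type_from_raw_expression",
                "cancer_type_from_adjusted_expression",
                "mutation_from_cancer_type"),
      accuracy = c(type_acc["raw"], type_acc["adjusted"], mut_from_type),
      stringsAsFactors = FALSE)
    message(sprintf(
      "stage confounding: type accuracy raw %.2f / adjusted %.2f, mutation-from-type %.2f",
      type_acc["raw"], type_acc["adjusted"], mut_from_type))
  }

  result <- list(
    aberrations = ab, expression = expr_use, expression_panel = expr_panel,
    pca = pca, design = design, cv = cv, metrics = metrics,
    similarity = sim_mat, test_predictions = test_pred,
    association = assoc, single_gene = single_gene,
    confounding = confounding, attrition_pct = attrition,
    simulation = sim, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(ab * 1L, file.path(outdir, "aberration_matrix.tsv"))
    write_matrix_tsv(expr_use$values,
                     file.path(outdir, "expression_prepared.tsv"))
    write_tidy(pca, file.path(outdir, "pca_coords.tsv"))
    write_tidy(data.frame(sample_id = names(design$training),
                          gene = unname(design$training)),
               file.path(outdir, "cohort_training.tsv"))
    if (length(design$test) > 0) {
      write_tidy(data.frame(sample_id = names(design$test),
                            gene = unname(design$test)),
                 file.path(outdir, "cohort_test.tsv"))
    }
    write_tidy(cv$predictions, file.path(outdir, "cv_predictions.tsv"))
    write_tidy(metrics$gene_auroc, file.path(outdir, "gene_auroc.tsv"))
    write_tidy(data.frame(metric = c("accuracy", "chance_accuracy",
                                     "chance_auroc", "filter_attrition_pct"),
                          value = c(metrics$accuracy,
                                    metrics$chance_accuracy, 0.5, attrition)),
               file.path(outdir, "metrics.tsv"))
    write_tidy(as.data.frame(sim_mat),
               file.path(outdir, "similarity_tidy.tsv"))
    write_matrix_tsv(sim_mat$rho, file.path(outdir, "similarity_matrix.tsv"))
    if (!is.null(test_pred)) {
      write_tidy(test_pred, file.path(outdir, "test_predictions.tsv"))
      write_tidy(assoc, file.path(outdir, "test_train_association.tsv"))
    }
    write_tidy(single_gene, file.path(outdir, "single_gene_tests.tsv"))
    if (!is.null(confounding)) {
      write_tidy(confounding, file.path(outdir, "confounding.tsv"))
    }
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prepare an analysis-ready cohort from raw pipeline inputs
#'
#' Convenience wrapper around the preprocessing stages: variant filtering,
#' aberration merging, replicate averaging, log transform, optional batch
#' adjustment, panel restriction and cohort construction.
#'
#' @param inputs List with `mutations`, `cnv`, `expression`, `annotation`,
#'   `panel`, `evidence` (as returned by [simulate_cohort()]).
#' @param min_train_count,min_test_count Cohort thresholds.
#' @param adjust Apply [batch_adjust()] (default `TRUE`).
#' @return List with `ab` (aberration matrix), `expr` (prepared full
#'   matrix), `expr_panel` (panel-restricted [expression_matrix()]),
#'   `design` (`"cohort_design"`), `attrition_pct`.
#' @export
prepare_cohort <- function(inputs, min_train_count = 10, min_test_count = 5,
                           adjust = TRUE) {
  filtered <- filter_somatic(inputs$mutations)
  expr <- log_transform(average_replicates(inputs$expression))
  samples <- Reduce(intersect, list(colnames(expr$values),
                                    colnames(inputs$cnv),
                                    inputs$annotation$sample_id))
  ab <- merge_aberrations(filtered, inputs$cnv, inputs$panel, samples)
  if (adjust) expr <- batch_adjust(expr, inputs$annotation)
  expr_panel <- expression_matrix(
    expr$values[intersect(inputs$panel, rownames(expr$values)), ,
                drop = FALSE], expr$state)
  design <- build_training_cohort(ab, min_count = min_train_count)
  design <- build_test_cohort(ab, design, inputs$evidence,
                              min_count = min_test_count)
  list(ab = ab, expr = expr, expr_panel = expr_panel, design = design,
       attrition_pct = filter_attrition(nrow(inputs$mutations),
                                        nrow(filtered)))
}
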