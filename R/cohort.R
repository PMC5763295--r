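#' Build the mutually exclusive training cohort
#'
#' Three-step, single-pass construction of a mutually exclusive training set
#' from a Boolean aberration matrix:
#' \enumerate{
#'   \item select genes aberrant in at least `min_count` samples;
#'   \item keep only samples aberrant in exactly one of those genes;
#'   \item retain genes that still have at least `min_count` aberrant samples
#'     among the kept samples.
#' }
#' Each surviving sample is labeled by its unique aberrant gene. The
#' construction is deliberately not iterated to a fixpoint: samples dropped
#' in step 2 because of a gene later removed in step 3 are not re-admitted.
#'
#' @param ab Logical gene-by-sample matrix from [merge_aberrations()].
#' @param min_count Minimum aberrant-sample count per gene (default 10 for a
#'   single cancer type; 50 is the conventional pan-cancer threshold).
#' @return An object of class `"cohort_design"`: list with `training` (named
#'   character vector, sample -> gene), `training_genes` (sorted),
#'   `min_train_count`, and empty test-set slots.
#' @export
build_training_cohort <- function(ab, min_count = 10) {
  stopifnot(is.matrix(ab), is.logical(ab), min_count >= 1)
  counts <- rowSums(ab)
  g0 <- rownames(ab)[counts >= min_count]
  if (length(g0) < 2) {
    stop("insufficient mutually exclusive classes (",
         length(g0), " gene(s) reach min_count = ", min_count, ")")
  }
  sub <- ab[g0, , drop = FALSE]
  n_hit <- colSums(sub)
  s1 <- colnames(ab)[n_hit == 1]
  counts1 <- rowSums(sub[, s1, drop = FALSE])
  g1 <- g0[counts1 >= min_count]
  if (length(g1) < 2) {
    stop("insufficient mutually exclusive classes (",
         length(g1), " gene(s) survive the exclusivity pass)")
  }
  lab <- vapply(s1, function(s) g0[which(sub[, s])], character(1))
  training <- lab[lab %in% g1]
  structure(list(
    training = training,
    training_genes = sort(g1),
    min_train_count = min_count,
    test = character(0),
    test_genes = character(0),
    min_test_count = NA_integer_
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", length(x$training_genes), " training classes, ",
      length(x$training), " training samples", sep = "")
  if (length(x$test) > 0) {
    cat("; ", length(x$test_genes), " test genes, ",
        length(x$test), " test samples", sep = "")
  }
  cat("\n  classes:", paste(x$training_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Build the rare-gene test cohort
#'
#' Samples not used for training are candidates for a test set used to
#' project rarely mutated genes through the trained model. Candidate test
#' genes must (1) have `"Supported"` drug-gene evidence, (2) not be training
#' genes, and (3) be aberrant in at least `min_count` non-training samples.
#' A test sample must be aberrant in exactly one candidate gene (its label);
#' samples aberrant in several candidates are excluded (logged). Training
#' assignment takes precedence: a sample in the training set is never a test
#' sample.
#'
#' @param ab Logical aberration matrix.
#' @param design `"cohort_design"` from [build_training_cohort()].
#' @param evidence Drug-gene evidence `data.frame` (see [read_evidence()]).
#' @param min_count Minimum aberrant non-training samples per test gene
#'   (default 5).
#' @return The `design` with `test`, `test_genes`, `min_test_count` filled.
#' @export
build_test_cohort <- function(ab, design, evidence, min_count = 5) {
  stopifnot(inherits(design, "cohort_design"))
  supported <- unique(evidence$gene[evidence$evidence_status == "Supported"])
  free <- setdiff(colnames(ab), names(design$training))
  cand <- setdiff(intersect(supported, rownames(ab)), design$training_genes)
  if (length(cand) > 0) {
    cnt <- rowSums(ab[cand, free, drop = FALSE])
    cand <- cand[cnt >= min_count]
  }
  design$min_test_count <- as.integer(min_count)
  if (length(cand) == 0) {
    warning("no candidate test genes with Supported evidence reach min_count = ",
            min_count)
    return(design)
  }
  sub <- ab[cand, free, drop = FALSE]
  n_hit <- colSums(sub)
  multi <- sum(n_hit > 1)
  if (multi > 0) {
    message(multi, " sample(s) aberrant in >1 candidate test gene excluded")
  }
  keep <- free[n_hit == 1]
  lab <- vapply(keep, function(s) cand[which(sub[, s])], character(1))
  design$test <- lab
  design$test_genes <- sort(unique(lab))
  design
}

#' Cancer types eligible for per-type analysis
#'
#' A cancer type is eligible when its own aberration submatrix yields at
#' least `min_genes` mutually exclusive classes at `min_count` (i.e.
#' [build_training_cohort()] succeeds with that many classes).
#'
#' @param ab Logical aberration matrix (all types).
#' @param annotation Sample annotation `data.frame`.
#' @param min_genes Minimum surviving classes (default 3).
#' @param min_count Per-gene threshold (default 10).
#' @return Character vector of eligible cancer types.
#' @export
eligible_cancer_types <- function(ab, annotation, min_genes = 3,
                                  min_count = 10) {
  idx <- match(colnames(ab), annotation$sample_id)
  types <- unique(annotation$cancer_type[idx[!is.na(idx)]])
  ok <- vapply(types, function(ty) {
    cols <- colnames(ab)[!is.na(idx) & annotation$cancer_type[idx] == ty]
    n_classes <- tryCatch(
      length(build_training_cohort(ab[, cols, drop = FALSE],
                                   min_count)$training_genes),
      error = function(e) 0L)
    n_classes >= min_genes
  }, logical(1))
  types[ok]
}
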