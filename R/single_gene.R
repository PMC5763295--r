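#' Partition samples by aberration status of a gene pair
#'
#' Splits the cohort into three disjoint, exhaustive groups: aberrant in
#' `gene_a` (including samples also aberrant in `gene_b`), aberrant in
#' `gene_b` but not `gene_a`, and aberrant in neither. The asymmetric
#' precedence mirrors the usual "B-aberrant but no A aberration" contrast.
#'
#' @param ab Logical aberration matrix.
#' @param gene_a,gene_b Gene symbols present in `ab`.
#' @return Named factor over samples with levels `gene_a`, `gene_b`,
#'   `"neither"`.
#' @export
aberration_groups <- function(ab, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(ab)) stop("gene not in aberration matrix: ", g)
  }
  grp <- ifelse(ab[gene_a, ], gene_a,
                ifelse(ab[gene_b, ], gene_b, "neither"))
  factor(stats::setNames(grp, colnames(ab)),
         levels = c(gene_a, gene_b, "neither"))
}

#' Welch's unequal-variance t-test
#'
#' @param x,y Numeric vectors, each with >= 2 values and nonzero pooled
#'   variance.
#' @param var_equal Use the pooled-variance Student test instead (default
#'   `FALSE`, i.e. Welch with Satterthwaite degrees of freedom).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 samples")
  if (stats::var(x) + stats::var(y) == 0) {
    stop("zero pooled variance; t statistic undefined")
  }
  fit <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Bonferroni correction
#'
#' @param p Nominal p-value(s).
#' @param n_tests Number of tests; conventionally the number of unordered
#'   gene pairs in the panel (see [gene_pair_count()]).
#' @return `min(1, p * n_tests)`.
#' @export
bonferroni <- function(p, n_tests) {
  pmin(1, p * n_tests)
}

#' Number of unordered gene pairs in a panel
#'
#' @param panel Character vector of gene symbols (deduplicated).
#' @return `choose(length(unique(panel)), 2)`.
#' @export
gene_pair_count <- function(panel) {
  choose(length(unique(panel)), 2)
}

#' Expression differences across aberration-defined groups
#'
#' For one expression gene, compares its (log-scale) expression between the
#' three groups defined by [aberration_groups()] with Welch's t-test,
#' Bonferroni-corrected over all panel gene pairs by default.
#'
#' @param expr [expression_matrix()] (log2 or batch-adjusted).
#' @param ab Logical aberration matrix sharing samples with `expr`.
#' @param gene_a,gene_b Aberration genes defining the groups.
#' @param expr_gene Gene whose expression is compared (default `gene_a`).
#' @param n_tests Bonferroni denominator; default
#'   `gene_pair_count(rownames(ab))`.
#' @param var_equal Passed to [welch_t()].
#' @return Tidy `data.frame`: `expression_gene`, `group1`, `group2`, `n1`,
#'   `n2`, `t`, `df`, `p`, `p_adj`.
#' @export
compare_expression_groups <- function(expr, ab, gene_a, gene_b,
                                      expr_gene = gene_a,
                                      n_tests = gene_pair_count(rownames(ab)),
                                      var_equal = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr_gene %in% rownames(expr$values)) {
    stop("gene not in expression matrix: ", expr_gene)
  }
  shared <- intersect(colnames(ab), colnames(expr$values))
  grp <- aberration_groups(ab[, shared, drop = FALSE], gene_a, gene_b)
  vals <- expr$values[expr_gene, shared]
  combos <- utils::combn(levels(grp), 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    x <- vals[grp == g1]; y <- vals[grp == g2]
    res <- welch_t(x, y, var_equal = var_equal)
    data.frame(expression_gene = expr_gene, group1 = g1, group2 = g2,
               n1 = length(x), n2 = length(y),
               t = res$t, df = res$df, p = res$p,
               p_adj = bonferroni(res$p, n_tests),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
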