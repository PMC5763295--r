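#' Spearman rank correlation with significance
#'
#' Pearson correlation of average ranks. The default p-value uses the
#' t-approximation on rho with n - 2 degrees of freedom; a seeded
#' permutation alternative is available for small samples or heavy ties.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Permutations when `method = "permutation"` (default 10000).
#' @param seed Seed for the permutation mode.
#' @return List with `rho` and `p`. A zero-variance input yields `rho = NA`
#'   with a warning.
#' @export
spearman_cor <- function(x, y, method = c("t", "permutation"),
                         n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "t") {
    p <- .spearman_p(rho, n)
  } else {
    set.seed(seed)
    obs <- abs(rho)
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(x, sample(y), method = "spearman")) >= obs - 1e-12
    }, logical(1)))
    p <- (1 + hits) / (1 + n_perm)
  }
  list(rho = rho, p = p)
}

.spearman_p <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Gene-gene similarity from probabilistic predictions
#'
#' The headline statistic: for each unordered pair of training genes, the
#' Spearman correlation across samples between the two genes' predicted
#' class probabilities, computed within each balanced-subsampling repeat and
#' averaged over repeats. A high correlation means the classifier confuses
#' the two mutation classes in the same tumors, i.e. their aberrations have
#' similar downstream transcriptional effects. P-values use the
#' t-approximation on the repeat-averaged rho with the per-repeat sample
#' count, Bonferroni-corrected over the pairs tested in this analysis scope.
#'
#' @param cv A `"mex_cv"` object.
#' @return Object of class `"similarity_matrix"`: `genes`, `rho` (symmetric,
#'   unit diagonal), `p`, `p_adj`, `n_pairs`, `n_per_repeat`.
#' @export
prediction_similarity <- function(cv) {
  stopifnot(inherits(cv, "mex_cv"))
  genes <- cv$genes
  K <- length(genes)
  if (K < 2) stop("need at least two classes")
  preds <- cv$predictions
  reps <- sort(unique(preds$repeat_idx))
  pair_idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
  per_rep <- vapply(reps, function(r) {
    sub <- as.matrix(preds[preds$repeat_idx == r, genes, drop = FALSE])
    apply(pair_idx, 1, function(ij) {
      a <- sub[, ij[1]]
      b <- sub[, ij[2]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
      else stats::cor(a, b, method = "spearman")
    })
  }, numeric(nrow(pair_idx)))
  per_rep <- matrix(per_rep, nrow = nrow(pair_idx))
  if (anyNA(per_rep)) {
    warning("zero-variance probability column in some repeat; ",
            "affected pairs averaged over remaining repeats")
  }
  rho_pairs <- rowMeans(per_rep, na.rm = TRUE)
  n_rep_samples <- sum(preds$repeat_idx == reps[1])
  n_pairs <- nrow(pair_idx)
  p_pairs <- vapply(rho_pairs, .spearman_p, numeric(1), n = n_rep_samples)
  rho <- diag(1, K)
  p <- matrix(NA_real_, K, K)
  dimnames(rho) <- dimnames(p) <- list(genes, genes)
  rho[pair_idx] <- rho_pairs
  rho[pair_idx[, c(2, 1), drop = FALSE]] <- rho_pairs
  p[pair_idx] <- p_pairs
  p[pair_idx[, c(2, 1), drop = FALSE]] <- p_pairs
  p_adj <- p * n_pairs          # pmin(1, .) would drop the dim attribute
  p_adj[!is.na(p_adj) & p_adj > 1] <- 1
  structure(list(genes = genes, rho = rho, p = p, p_adj = p_adj,
                 n_pairs = n_pairs, n_per_repeat = n_rep_samples,
                 n_repeats = length(reps)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, digits = 2, ...) {
  cat("<similarity_matrix> ", length(x$genes), " genes, ", x$n_pairs,
      " pairs (Bonferroni n = ", x$n_pairs, ")\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}

#' Tidy one-row-per-pair view of a similarity matrix
#'
#' @param x A `"similarity_matrix"`.
#' @param ... Unused.
#' @return `data.frame` with `gene_a`, `gene_b` (unordered pairs,
#'   `gene_a < gene_b`), `rho`, `p`, `p_adj`.
#' @export
as.data.frame.similarity_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  data.frame(
    gene_a = x$genes[idx[, 1]],
    gene_b = x$genes[idx[, 2]],
    rho = x$rho[idx],
    p = x$p[idx],
    p_adj = x$p_adj[idx],
    stringsAsFactors = FALSE
  )
}

#' Heatmap of prediction-correlation similarities
#'
#' @param x A `"similarity_matrix"`.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot.similarity_matrix <- function(x, ...) {
  pal <- grDevices::hcl.colors(25, "RdBu", rev = TRUE)
  stats::heatmap(x$rho, symm = TRUE, zlim = c(-1, 1), col = pal,
                 scale = "none", ...)
  invisible(x)
}

#' Associate test (rare) genes with training-gene predictions
#'
#' For each test gene t and training gene c, the Spearman correlation across
#' test samples between the indicator "sample is labeled t" and the
#' predicted probability of class c. A strong association means tumors with
#' the rare aberration t look, transcriptionally, like the common class c.
#' Test genes with fewer than 3 samples are excluded (logged).
#'
#' @param test_pred `data.frame` from [predict_test_set()].
#' @param design `"cohort_design"` (supplies the training classes).
#' @return `data.frame`: `test_gene`, `train_gene`, `rho`, `p`.
#' @export
test_train_association <- function(test_pred, design) {
  stopifnot(nrow(test_pred) > 0)
  classes <- design$training_genes
  test_genes <- sort(unique(test_pred$true_label))
  counts <- table(test_pred$true_label)
  drop <- test_genes[counts[test_genes] < 3]
  if (length(drop) > 0) {
    message("excluding test gene(s) with <3 samples: ",
            paste(drop, collapse = ", "))
    test_genes <- setdiff(test_genes, drop)
  }
  rows <- list()
  for (tg in test_genes) {
    ind <- as.numeric(test_pred$true_label == tg)
    for (cl in classes) {
      s <- suppressWarnings(spearman_cor(ind, test_pred[[cl]]))
      rows[[length(rows) + 1]] <- data.frame(
        test_gene = tg, train_gene = cl, rho = s$rho, p = s$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
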