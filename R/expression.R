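.expr_states <- c("raw_tpm", "averaged", "log2", "batch_adjusted")

#' Expression matrix with a processing-state tag
#'
#' A light container for a gene-by-sample real matrix plus a state tag
#' recording where it sits in the preprocessing chain
#' `raw_tpm -> averaged -> log2 -> batch_adjusted`. State transitions move
#' only forward; each preprocessing function checks the incoming state.
#'
#' @param values Numeric matrix, genes in rows (named), samples in columns
#'   (named; duplicates allowed only in raw state, marking replicate groups).
#' @param state One of `"raw_tpm"`, `"averaged"`, `"log2"`,
#'   `"batch_adjusted"`.
#' @return An object of class `"expr_matrix"` with elements `values` and
#'   `state`.
#' @export
expression_matrix <- function(values, state = "raw_tpm") {
  stopifnot(is.matrix(values), is.numeric(values))
  state <- match.arg(state, .expr_states)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols")
  if (state != "raw_tpm" && anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs only allowed in raw_tpm state")
  }
  if (state == "raw_tpm" && any(values < 0)) {
    stop("raw TPM values must be non-negative")
  }
  structure(list(values = values, state = state), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples, state: ", x$state, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

.check_state <- function(expr, allowed) {
  if (!inherits(expr, "expr_matrix")) stop("expected an expr_matrix")
  if (!expr$state %in% allowed) {
    stop("expression matrix in state '", expr$state,
         "'; expected one of: ", paste(allowed, collapse = ", "))
  }
}

#' Average expression replicates
#'
#' Tumors sequenced multiple times appear as repeated sample columns; their
#' values are replaced by the arithmetic mean on the TPM scale, yielding one
#' column per unique sample (first-occurrence order).
#'
#' @param expr [expression_matrix()] in state `"raw_tpm"`.
#' @return [expression_matrix()] in state `"averaged"`.
#' @export
average_replicates <- function(expr) {
  .check_state(expr, "raw_tpm")
  v <- expr$values
  ids <- colnames(v)
  uniq <- unique(ids)
  if (length(uniq) == length(ids)) {
    return(expression_matrix(v, state = "averaged"))
  }
  out <- matrix(0, nrow(v), length(uniq),
                dimnames = list(rownames(v), uniq))
  for (s in uniq) {
    out[, s] <- rowMeans(v[, ids == s, drop = FALSE])
  }
  expression_matrix(out, state = "averaged")
}

#' Log-transform expression values
#'
#' Applies `log2(x + 1)`; the pseudocount of 1 maps TPM = 0 to 0 and keeps
#' the transform monotone, mitigating the influence of extremely high
#' expression values.
#'
#' @param expr [expression_matrix()] in state `"raw_tpm"` or `"averaged"`.
#' @return [expression_matrix()] in state `"log2"`.
#' @export
log_transform <- function(expr) {
  .check_state(expr, c("raw_tpm", "averaged"))
  if (any(expr$values < 0)) stop("negative values cannot be log-transformed")
  v <- log2(expr$values + 1)
  if (anyDuplicated(colnames(v))) {
    stop("average replicates before log-transforming")
  }
  expression_matrix(v, state = "log2")
}

# Iterative conditional estimation of the empirical-Bayes batch parameters
# (normal prior on locations, inverse-gamma on scales), as in the standard
# parametric location-scale adjustment.
.eb_solve <- function(z_batch, g_hat, d_hat, g_bar, t2, a, b,
                      tol = 1e-4, max_iter = 100) {
  n_b <- ncol(z_batch)
  g_old <- g_hat
  d_old <- d_hat
  for (i in seq_len(max_iter)) {
    g_new <- (n_b * t2 * g_hat + d_old * g_bar) / (n_b * t2 + d_old)
    sum2 <- rowSums((z_batch - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n_b / 2 + a - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    g_old <- g_new
    d_old <- d_new
    if (change < tol) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Empirical-Bayes batch adjustment (cancer type as batch)
#'
#' Parametric location-scale adjustment removing batch effects from a
#' log-scale expression matrix, used here with cancer type as the batch so
#' that tissue-of-origin differences do not dominate pan-cancer analyses.
#' Per gene, the data are standardised against the batch-size-weighted grand
#' mean and pooled variance; per batch, gene-wise location and scale
#' parameters are shrunk toward batch-level priors (normal prior on
#' locations, inverse-gamma on scales, moment-matched hyperparameters,
#' iterative conditional estimation); the data are then rescaled to the
#' pooled gene mean and variance. No biological covariates are protected. As
#' a final step each gene is re-centred so its pooled mean is preserved
#' exactly.
#'
#' Zero-variance genes are passed through unadjusted (with a message). A
#' single-batch input is returned unchanged apart from the state tag.
#'
#' @param expr [expression_matrix()] in state `"log2"` (no replicate
#'   columns).
#' @param annotation `data.frame` with `sample_id`, `cancer_type` covering
#'   every sample.
#' @param tol Relative-change convergence tolerance of the EB iteration.
#' @param max_iter Iteration cap.
#' @return [expression_matrix()] in state `"batch_adjusted"`.
#' @export
batch_adjust <- function(expr, annotation, tol = 1e-4, max_iter = 100) {
  .check_state(expr, "log2")
  v <- expr$values
  idx <- match(colnames(v), annotation$sample_id)
  if (anyNA(idx)) {
    stop("unannotated sample(s): ",
         paste(utils::head(colnames(v)[is.na(idx)], 3), collapse = ", "))
  }
  batch <- factor(annotation$cancer_type[idx])
  if (nlevels(batch) == 1L) {
    return(expression_matrix(v, state = "batch_adjusted"))
  }
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop("batch with a single sample: ", names(sizes)[sizes < 2][1])
  }
  n <- ncol(v)
  design <- stats::model.matrix(~ 0 + batch)
  ns <- colSums(design)

  keep <- apply(v, 1, stats::var) > 0
  b_hat <- solve(crossprod(design), t(design) %*% t(v[keep, , drop = FALSE]))
  grand_mean <- drop(crossprod(ns / n, b_hat))
  fitted <- t(design %*% b_hat)
  var_pooled <- rowMeans((v[keep, , drop = FALSE] - fitted)^2)
  kidx <- which(keep)
  keep[kidx[var_pooled == 0]] <- FALSE
  if (!all(keep)) {
    message("passing ", sum(!keep), " zero-variance gene(s) through unadjusted")
  }
  vk <- v[keep, , drop = FALSE]
  grand_mean <- grand_mean[rownames(vk)]
  var_pooled <- var_pooled[rownames(vk)]

  z <- (vk - grand_mean) / sqrt(var_pooled)
  z_adj <- z
  for (bi in levels(batch)) {
    cols <- which(batch == bi)
    zb <- z[, cols, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- apply(zb, 1, stats::var)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    dm <- mean(d_hat)
    ds2 <- stats::var(d_hat)
    if (is.na(t2) || t2 < 1e-12 || is.na(ds2) || ds2 < 1e-12) {
      gamma_star <- g_hat
      delta_star <- d_hat
    } else {
      a <- (2 * ds2 + dm^2) / ds2
      b <- (dm * ds2 + dm^3) / ds2
      sol <- .eb_solve(zb, g_hat, d_hat, g_bar, t2, a, b,
                       tol = tol, max_iter = max_iter)
      gamma_star <- sol$gamma_star
      delta_star <- sol$delta_star
    }
    z_adj[, cols] <- (zb - gamma_star) / sqrt(delta_star)
  }
  out_k <- z_adj * sqrt(var_pooled) + grand_mean
  # restore the pooled per-gene mean exactly
  out_k <- out_k - rowMeans(out_k) + rowMeans(vk)

  out <- v
  out[keep, ] <- out_k
  expression_matrix(out, state = "batch_adjusted")
}

#' Principal-component coordinates of samples
#'
#' Projects samples onto the top-k principal axes of the gene-centered
#' (unscaled) expression matrix, for tissue-effect QC plots. Deterministic up
#' to axis sign.
#'
#' @param expr An [expression_matrix()] (any state, typically log2 or
#'   batch-adjusted).
#' @param k Number of components (default 2).
#' @return `data.frame` with `sample_id` and columns `PC1..PCk`.
#' @export
pca_coords <- function(expr, k = 2) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  if (ncol(v) < k) stop("fewer samples than requested components")
  centered <- scale(t(v), center = TRUE, scale = FALSE)
  if (k > qr(centered)$rank) {
    stop("k exceeds the rank of the centered matrix")
  }
  pr <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  out <- data.frame(sample_id = colnames(v), pr$x[, seq_len(k), drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-1] <- paste0("PC", seq_len(k))
  out
}
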