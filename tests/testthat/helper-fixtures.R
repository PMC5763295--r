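# Shared fixtures and independent brute-force oracles.

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "mutexpr", mustWork = TRUE)
}

# 6-gene x 60-sample Boolean aberration matrix with a known mutually
# exclusive structure: at min_count = 10 the construction must keep
# G1/G2/G3 (15 + 13 + 10 = 38 training samples), drop G4 (12 total but only
# 8 exclusive after removing 4 samples shared with G1), and never consider
# G5 (6) or G6 (4).
cohort_fixture <- function() {
  genes <- paste0("G", 1:6)
  samples <- sprintf("T%02d", 1:60)
  ab <- matrix(FALSE, 6, 60, dimnames = list(genes, samples))
  ab["G1", 1:15] <- TRUE
  ab["G2", 16:28] <- TRUE
  ab["G3", 29:38] <- TRUE
  ab["G4", 39:46] <- TRUE
  ab["G1", 47:50] <- TRUE   # shared with G4
  ab["G4", 47:50] <- TRUE
  ab["G5", 51:56] <- TRUE
  ab["G6", 57:60] <- TRUE
  ab
}

# Independent re-implementation of the three-step cohort construction,
# with explicit loops.
bf_training_cohort <- function(ab, min_count) {
  g0 <- character(0)
  for (g in rownames(ab)) if (sum(ab[g, ]) >= min_count) g0 <- c(g0, g)
  s1 <- character(0)
  lab <- character(0)
  for (s in colnames(ab)) {
    hits <- g0[ab[g0, s]]
    if (length(hits) == 1) {
      s1 <- c(s1, s)
      lab <- c(lab, hits)
    }
  }
  g1 <- character(0)
  for (g in g0) if (sum(lab == g) >= min_count) g1 <- c(g1, g)
  keep <- lab %in% g1
  list(genes = sort(g1), labels = stats::setNames(lab[keep], s1[keep]))
}

# Exhaustive pairwise AUROC oracle.
bf_auroc <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Brute-force average ranks + explicit Pearson formula.
bf_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      less + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Closed-form Welch statistic.
bf_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

# Small, fast simulation used across tests.
small_sim <- function(seed = 5, ...) {
  args <- list(
    n_cancer_types = 2, samples_per_type = 45,
    n_panel_genes = 40, n_expression_genes = 60,
    driver_genes = paste0("DRV", 1:3), samples_per_driver = 20,
    replicate_fraction = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_cohort(do.call(simulate_config, args))
}

# Build a mex_cv-shaped object directly from a prediction table, so that
# similarity can be tested on constructed inputs.
fake_cv <- function(predictions, genes) {
  structure(list(predictions = predictions, genes = genes,
                 k = NA, n_repeats = length(unique(predictions$repeat_idx)),
                 seed = NA, classifier = "constructed"),
            class = "mex_cv")
}
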