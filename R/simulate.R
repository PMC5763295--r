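#' Configuration for a synthetic tumor cohort
#'
#' Defines the generative model for a synthetic cohort with known ground
#' truth. On the log2 scale, expression of gene g in sample s is
#' `baseline(g) + tissue_shift(type(s), g) + signature(driver(s), g) +
#' noise`, transformed to the TPM scale via `2^x - 1` (floored at 0) so the
#' pipeline's own `log2(x + 1)` recovers the latent scale. Driver
#' signatures are vectors over all expression genes with configurable
#' pairwise correlations; each is unit-normalised and then scaled by
#' `effect_size * sqrt(n_expression_genes)`, so `effect_size` is the
#' root-mean-square per-gene effect in log2 units. Each driver aberration
#' is emitted either as a passing deleterious variant record or as a +/-2
#' copy-number call (coin flip with probability `snv_probability`).
#' Passenger variant records are engineered so that each individual filter
#' rule removes some of them (non-PASS; ExAC frequency > 0.01;
#' LOW/MODIFIER impact; tolerated + benign).
#'
#' @param n_cancer_types Number of cancer types (tissues).
#' @param samples_per_type Samples per type (scalar or length
#'   `n_cancer_types`).
#' @param n_panel_genes Size of the cancer-gene panel (default 325).
#' @param n_expression_genes Genes in the expression matrix (>= panel size).
#' @param driver_genes Names of the common driver genes (training classes).
#' @param samples_per_driver Aberrant samples per driver in strict mode.
#' @param signature_overlap Target pairwise correlation between driver
#'   signatures: a scalar (all off-diagonal pairs) or a full correlation
#'   matrix. Must be positive semi-definite.
#' @param effect_size Per-gene RMS transcriptional effect of a driver
#'   aberration, log2 units.
#' @param tissue_shift_sd SD of per-type, per-gene baseline shifts (log2).
#' @param noise_sd SD of per-observation Gaussian noise (log2).
#' @param passenger_rate Probability, per sample and per engineered
#'   passenger category, of emitting a removable passenger record; also the
#'   rate of filter-surviving passengers in non-panel genes.
#' @param exclusivity_mode `"strict"` (no sample carries two driver
#'   aberrations; exact per-driver counts) or `"probabilistic"`
#'   (independent per-driver Bernoulli draws with rate
#'   `samples_per_driver / n_samples`).
#' @param replicate_fraction Fraction of samples emitted twice in the
#'   expression file (re-sequenced tumors; fresh noise, same signal).
#' @param rare_drivers Named character vector mapping each rare (test-set)
#'   driver gene to the training driver whose signature it shares exactly,
#'   or `NULL`.
#' @param rare_samples_per_driver Aberrant samples per rare driver.
#' @param snv_probability Probability a driver aberration is emitted as a
#'   variant record rather than a copy-number call.
#' @param baseline_mean,baseline_sd Distribution of per-gene log2 baselines.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `"sim_config"`.
#' @export
simulate_config <- function(n_cancer_types = 3,
                            samples_per_type = 100,
                            n_panel_genes = 325,
                            n_expression_genes = 500,
                            driver_genes = paste0("DRV", 1:5),
                            samples_per_driver = 50,
                            signature_overlap = 0,
                            effect_size = 1.0,
                            tissue_shift_sd = 1.0,
                            noise_sd = 1.0,
                            passenger_rate = 0.5,
                            exclusivity_mode = c("strict", "probabilistic"),
                            replicate_fraction = 0.1,
                            rare_drivers = NULL,
                            rare_samples_per_driver = 7,
                            snv_probability = 0.5,
                            baseline_mean = 4,
                            baseline_sd = 1.5,
                            seed = 1) {
  exclusivity_mode <- match.arg(exclusivity_mode)
  K <- length(driver_genes)
  stopifnot(K >= 2, !anyDuplicated(driver_genes))
  stopifnot(tissue_shift_sd >= 0, noise_sd >= 0, baseline_sd >= 0,
            effect_size >= 0)
  stopifnot(passenger_rate >= 0, passenger_rate <= 1,
            replicate_fraction >= 0, replicate_fraction <= 1,
            snv_probability >= 0, snv_probability <= 1)
  samples_per_type <- rep_len(samples_per_type, n_cancer_types)
  n_total <- sum(samples_per_type)
  n_rare <- length(rare_drivers)
  if (n_rare > 0) {
    stopifnot(!is.null(names(rare_drivers)),
              all(rare_drivers %in% driver_genes),
              !any(names(rare_drivers) %in% driver_genes))
  }
  if (K * samples_per_driver + n_rare * rare_samples_per_driver > n_total) {
    stop("driver sample demand exceeds cohort size")
  }
  if (n_panel_genes < K + n_rare) stop("panel smaller than driver set")
  if (n_expression_genes < n_panel_genes) {
    stop("expression gene set must contain the panel")
  }
  C <- .overlap_matrix(signature_overlap, K)
  structure(list(
    n_cancer_types = n_cancer_types, samples_per_type = samples_per_type,
    n_panel_genes = n_panel_genes, n_expression_genes = n_expression_genes,
    driver_genes = driver_genes, samples_per_driver = samples_per_driver,
    signature_overlap = C, effect_size = effect_size,
    tissue_shift_sd = tissue_shift_sd, noise_sd = noise_sd,
    passenger_rate = passenger_rate, exclusivity_mode = exclusivity_mode,
    replicate_fraction = replicate_fraction, rare_drivers = rare_drivers,
    rare_samples_per_driver = rare_samples_per_driver,
    snv_probability = snv_probability, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, seed = seed
  ), class = "sim_config")
}

.overlap_matrix <- function(overlap, K) {
  if (is.matrix(overlap)) {
    stopifnot(nrow(overlap) == K, ncol(overlap) == K,
              isTRUE(all.equal(overlap, t(overlap))),
              all(diag(overlap) == 1), all(abs(overlap) <= 1))
    C <- overlap
  } else {
    stopifnot(length(overlap) == 1, abs(overlap) <= 1)
    C <- matrix(overlap, K, K)
    diag(C) <- 1
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("signature_overlap targets are not positive semi-definite")
  }
  C
}

#' Configuration with one planted high-similarity driver pair
#'
#' Returns a default-scale configuration (5 drivers, 50 samples per driver,
#' 500 expression genes) in which the first two drivers' transcriptional
#' signatures have correlation exactly `rho_true` while every other pair is
#' orthogonal.
#'
#' @param rho_true Target signature correlation, in \[-1, 1\].
#' @param ... Overrides passed to [simulate_config()].
#' @return A `"sim_config"`.
#' @export
planted_pair_config <- function(rho_true, ...) {
  stopifnot(abs(rho_true) <= 1)
  defaults <- list(...)
  K <- if (!is.null(defaults$driver_genes)) length(defaults$driver_genes) else 5
  C <- diag(1, K)
  C[1, 2] <- C[2, 1] <- rho_true
  do.call(simulate_config, c(list(signature_overlap = C), defaults))
}

# Signature vectors with EXACT pairwise sample correlations: centered,
# orthonormalised Gaussian basis combined through an eigen square root of
# the target correlation matrix. Columns come out unit-norm; rho = +/-1
# (rank-deficient targets) is handled naturally.
.draw_signatures <- function(G, C) {
  K <- ncol(C)
  z <- matrix(stats::rnorm(G * K), G, K)
  z <- sweep(z, 2, colMeans(z))
  q <- qr.Q(qr(z))
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  a <- e$vectors %*% diag(sqrt(lam), K) %*% t(e$vectors)
  q %*% a
}

#' Generate a synthetic tumor cohort with known ground truth
#'
#' Draws a full synthetic cohort under `config` and optionally writes the
#' six pipeline input files (mutations, copy number, expression, sample
#' annotation, gene panel, drug-gene evidence) plus the ground truth as
#' TSVs. Generation is fully deterministic given `config$seed`: the same
#' configuration always produces byte-identical files.
#'
#' @param config A `"sim_config"` from [simulate_config()].
#' @param dir Output directory for TSV files, or `NULL` to skip writing.
#' @return Invisibly, a list with `mutations` (data.frame), `cnv` (integer
#'   matrix), `expression` ([expression_matrix()], raw TPM, possibly with
#'   replicate columns), `annotation`, `panel`, `evidence`, and `truth`
#'   (list: `assignments` data.frame with per-sample driver, cancer type;
#'   `signature_cor`, the exact correlation matrix of all emitted driver
#'   signatures; `signatures`). If `dir` is given, also `paths`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- length(config$driver_genes)
  rare <- names(config$rare_drivers)
  n_rare <- length(rare)
  types <- sprintf("TYPE%02d", seq_len(config$n_cancer_types))
  n <- sum(config$samples_per_type)
  ids <- sprintf("S%04d", seq_len(n))
  type_of <- sample(rep(types, times = config$samples_per_type))
  names(type_of) <- ids

  # gene universe: drivers + rare drivers + panel filler + non-panel filler
  panel <- c(config$driver_genes, rare,
             sprintf("PG%03d", seq_len(config$n_panel_genes - K - n_rare)))
  extra <- if (config$n_expression_genes > config$n_panel_genes) {
    sprintf("XG%03d",
            seq_len(config$n_expression_genes - config$n_panel_genes))
  } else character(0)
  genes <- c(panel, extra)
  G <- length(genes)

  # driver signatures over all expression genes, exact target correlations;
  # unit-norm vectors are kept for the ground truth so the true correlation
  # structure is defined even at effect_size = 0
  sig_unit <- .draw_signatures(G, config$signature_overlap)
  colnames(sig_unit) <- config$driver_genes
  if (n_rare > 0) {
    sig_rare <- sig_unit[, config$rare_drivers, drop = FALSE]
    colnames(sig_rare) <- rare
    sig_unit <- cbind(sig_unit, sig_rare)
  }
  rownames(sig_unit) <- genes
  sig <- sig_unit * config$effect_size * sqrt(G)
  all_drivers <- colnames(sig)

  # per-sample driver assignment; in strict mode exactly zero or one driver
  # per sample, in probabilistic mode independent draws (multi-hit allowed)
  hits <- matrix(FALSE, n, length(all_drivers),
                 dimnames = list(ids, all_drivers))
  if (config$exclusivity_mode == "strict") {
    pool <- sample(ids)
    counts <- c(rep(config$samples_per_driver, K),
                rep(config$rare_samples_per_driver, n_rare))
    offset <- 0
    for (j in seq_along(all_drivers)) {
      hits[pool[offset + seq_len(counts[j])], j] <- TRUE
      offset <- offset + counts[j]
    }
  } else {
    for (j in seq_along(all_drivers)) {
      rate <- if (j <= K) config$samples_per_driver / n
              else config$rare_samples_per_driver / n
      hits[stats::runif(n) < rate, j] <- TRUE
    }
  }

  # latent log2 expression
  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  shift <- matrix(stats::rnorm(G * length(types), 0, config$tissue_shift_sd),
                  G, length(types), dimnames = list(genes, types))
  latent <- baseline + shift[, type_of[ids]]
  colnames(latent) <- ids
  latent <- latent + sig %*% t(hits)

  emit_tpm <- function(latent_cols) {
    noise <- matrix(stats::rnorm(length(latent_cols), 0, config$noise_sd),
                    nrow = nrow(latent_cols))
    pmax(2^(latent_cols + noise) - 1, 0)
  }
  tpm <- emit_tpm(latent)
  dimnames(tpm) <- list(genes, ids)
  n_rep <- floor(config$replicate_fraction * n)
  if (n_rep > 0) {
    rep_ids <- sample(ids, n_rep)
    rep_cols <- emit_tpm(latent[, rep_ids, drop = FALSE])
    colnames(rep_cols) <- rep_ids
    tpm <- cbind(tpm, rep_cols)
  }

  # aberration emission: driver events as SNV or CNV (coin flip)
  cnv <- matrix(0L, G, n, dimnames = list(genes, ids))
  # background: low-level gains/losses (never counted as aberrant)
  bg <- matrix(stats::runif(G * n) < 0.05, G, n)
  cnv[bg] <- sample(c(-1L, 1L), sum(bg), replace = TRUE)
  # non-panel genes may carry high-level events; dropped by the panel filter
  if (length(extra) > 0) {
    xg <- matrix(stats::runif(length(extra) * n) < 0.01, length(extra), n)
    cnv[extra, ][xg] <- sample(c(-2L, 2L), sum(xg), replace = TRUE)
  }
  mut_rows <- list()
  passing_record <- function(s, g) {
    combo <- sample(4, 1)
    data.frame(
      sample_id = s, gene = g, filter_status = "PASS",
      exac_maf = c(NA, 0.001, 0.005, NA)[combo],
      impact = c("HIGH", "MODERATE", "HIGH", "MODERATE")[combo],
      sift = c("deleterious", "deleterious_low_confidence", NA, NA)[combo],
      polyphen = c("benign", "probably_damaging", "possibly_damaging",
                   NA)[combo],
      stringsAsFactors = FALSE)
  }
  hit_idx <- which(hits, arr.ind = TRUE)
  for (i in seq_len(nrow(hit_idx))) {
    s <- ids[hit_idx[i, 1]]
    g <- all_drivers[hit_idx[i, 2]]
    if (stats::runif(1) < config$snv_probability) {
      mut_rows[[length(mut_rows) + 1]] <- passing_record(s, g)
    } else {
      cnv[g, s] <- sample(c(-2L, 2L), 1)
    }
  }
  # passengers engineered to be removed, one category at a time
  removable <- list(
    function(s, g) data.frame(sample_id = s, gene = g,
      filter_status = "germline_risk", exac_maf = NA_real_, impact = "HIGH",
      sift = "deleterious", polyphen = "probably_damaging",
      stringsAsFactors = FALSE),
    function(s, g) data.frame(sample_id = s, gene = g,
      filter_status = "PASS", exac_maf = 0.05, impact = "HIGH",
      sift = "deleterious", polyphen = "probably_damaging",
      stringsAsFactors = FALSE),
    function(s, g) data.frame(sample_id = s, gene = g,
      filter_status = "PASS", exac_maf = NA_real_,
      impact = sample(c("LOW", "MODIFIER"), 1),
      sift = "deleterious", polyphen = "probably_damaging",
      stringsAsFactors = FALSE),
    function(s, g) data.frame(sample_id = s, gene = g,
      filter_status = "PASS", exac_maf = 0.001, impact = "MODERATE",
      sift = "tolerated", polyphen = "benign", stringsAsFactors = FALSE)
  )
  for (s in ids) {
    for (cat in seq_along(removable)) {
      if (stats::runif(1) < config$passenger_rate) {
        mut_rows[[length(mut_rows) + 1]] <-
          removable[[cat]](s, sample(panel, 1))
      }
    }
    # filter-surviving passengers land outside the panel
    if (length(extra) > 0 && stats::runif(1) < config$passenger_rate) {
      mut_rows[[length(mut_rows) + 1]] <- passing_record(s, sample(extra, 1))
    }
  }
  if (length(mut_rows) == 0) {
    mutations <- data.frame(sample_id = character(0), gene = character(0),
                            filter_status = character(0),
                            exac_maf = numeric(0), impact = character(0),
                            sift = character(0), polyphen = character(0),
                            stringsAsFactors = FALSE)
  } else {
    mutations <- do.call(rbind, mut_rows)
    mutations <- mutations[order(mutations$sample_id, mutations$gene), ,
                           drop = FALSE]
    rownames(mutations) <- NULL
  }

  annotation <- data.frame(sample_id = ids, cancer_type = unname(type_of),
                           stringsAsFactors = FALSE)
  evidence <- data.frame(
    gene = c(rare, config$driver_genes[1], panel[K + n_rare + 1]),
    drug = paste0("DRUG_", c(rare, config$driver_genes[1],
                             panel[K + n_rare + 1])),
    evidence_status = c(rep("Supported", n_rare), "Does not support",
                        "Supported"),
    stringsAsFactors = FALSE)
  driver_label <- apply(hits, 1, function(h) {
    if (!any(h)) "none" else paste(all_drivers[h], collapse = ";")
  })
  truth <- list(
    assignments = data.frame(
      sample_id = ids, cancer_type = unname(type_of),
      driver = unname(driver_label),
      stringsAsFactors = FALSE),
    signature_cor = stats::cor(sig_unit),
    signatures = sig
  )
  out <- list(mutations = mutations, cnv = cnv,
              expression = expression_matrix(tpm, "raw_tpm"),
              annotation = annotation, panel = panel, evidence = evidence,
              truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      mutations = file.path(dir, "mutations.tsv"),
      cnv = file.path(dir, "cnv.tsv"),
      expression = file.path(dir, "expression.tsv"),
      annotation = file.path(dir, "annotation.tsv"),
      panel = file.path(dir, "panel.tsv"),
      evidence = file.path(dir, "evidence.tsv"),
      ground_truth = file.path(dir, "ground_truth.tsv"),
      signature_cor = file.path(dir, "signature_correlation.tsv"))
    write_tidy(mutations, paths$mutations)
    write_matrix_tsv(cnv, paths$cnv)
    write_matrix_tsv(tpm, paths$expression)
    write_tidy(annotation, paths$annotation)
    write_tidy(data.frame(gene = panel, stringsAsFactors = FALSE),
               paths$panel)
    write_tidy(evidence, paths$evidence)
    write_tidy(truth$assignments, paths$ground_truth)
    write_matrix_tsv(truth$signature_cor, paths$signature_cor)
    out$paths <- paths
  }
  invisible(out)
}
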