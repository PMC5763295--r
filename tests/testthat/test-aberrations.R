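make_record <- function(filter_status = "PASS", exac_maf = NA_real_,
                        impact = "HIGH", sift = NA_character_,
                        polyphen = NA_character_) {
  data.frame(sample_id = "s1", gene = "G1", filter_status = filter_status,
             exac_maf = exac_maf, impact = impact, sift = sift,
             polyphen = polyphen, stringsAsFactors = FALSE)
}

test_that("somatic filter applies each retention rule", {
  cases <- list(
    # deleterious SIFT rescues a benign PolyPhen call
    list(rec = make_record(exac_maf = 0.005, sift = "deleterious",
                           polyphen = "benign"), keep = TRUE),
    # common variants are removed regardless of predictions
    list(rec = make_record(exac_maf = 0.02, sift = "deleterious",
                           polyphen = "probably_damaging"), keep = FALSE),
    # explicit double-negative predictions are removed
    list(rec = make_record(impact = "MODERATE", sift = "tolerated",
                           polyphen = "benign"), keep = FALSE),
    # no predictions at all: retained (err on the side of inclusion)
    list(rec = make_record(impact = "MODERATE"), keep = TRUE),
    # one-sided missingness with an explicit negative: removed
    list(rec = make_record(sift = "tolerated"), keep = FALSE),
    list(rec = make_record(polyphen = "possibly_damaging"), keep = TRUE),
    # non-PASS and low-impact records always removed
    list(rec = make_record(filter_status = "REJECT", sift = "deleterious"),
         keep = FALSE),
    list(rec = make_record(impact = "MODIFIER", sift = "deleterious"),
         keep = FALSE),
    # boundary: maf exactly 0.01 is retained
    list(rec = make_record(exac_maf = 0.01, sift = "deleterious"),
         keep = TRUE)
  )
  for (case in cases) {
    expect_equal(nrow(filter_somatic(case$rec)), as.integer(case$keep),
                 info = paste(unlist(case$rec), collapse = "|"))
  }
})

test_that("somatic filter is idempotent and monotone", {
  mut <- read_mutations(toy_path("mutations.tsv"))
  once <- filter_somatic(mut)
  expect_identical(filter_somatic(once), once)
  # filtering any subset yields a subset of the filtered full set
  set.seed(1)
  for (i in 1:5) {
    idx <- sort(sample(nrow(mut), 6))
    sub <- filter_somatic(mut[idx, ])
    expect_true(all(
      apply(sub, 1, paste, collapse = "\r") %in%
        apply(once, 1, paste, collapse = "\r")))
  }
  # order preserved: surviving rows keep their original relative order
  expect_false(is.unsorted(as.integer(rownames(once))))
})

test_that("only high-level copy-number events count as aberrant", {
  expect_identical(cnv_is_aberrant(c(-2L, -1L, 0L, 1L, 2L)),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_error(cnv_is_aberrant(3L))
})

test_that("merge matches the hand-enumerated toy fixture", {
  mut <- filter_somatic(read_mutations(toy_path("mutations.tsv")))
  cnv <- read_cnv_matrix(toy_path("cnv.tsv"))
  expr <- read_expression_matrix(toy_path("expression.tsv"))
  panel <- read_gene_panel(toy_path("panel.tsv"))
  manifest <- jsonlite::fromJSON(toy_path("manifest.json"))

  expect_equal(nrow(mut), manifest$n_surviving_records)
  samples <- intersect(colnames(cnv), colnames(expr$values))
  expect_setequal(samples, manifest$samples_with_all_data)

  ab <- merge_aberrations(mut, cnv, panel, samples)
  expect_identical(dim(ab), as.integer(manifest$matrix_shape))
  expect_equal(sum(ab), manifest$n_true_cells)
  for (i in seq_len(nrow(manifest$true_cells))) {
    expect_true(ab[manifest$true_cells[i, 1], manifest$true_cells[i, 2]])
  }
  # sample present in mutation/CNV data but lacking expression is excluded
  expect_false("S4" %in% colnames(ab))
  # row order of the inputs is irrelevant
  set.seed(2)
  ab2 <- merge_aberrations(mut[sample(nrow(mut)), ], cnv, panel, samples)
  expect_identical(ab, ab2)
  expect_error(merge_aberrations(mut, cnv, panel, character(0)), "sample")
})

test_that("synthetic driver aberrations reproduce the ground truth", {
  sim <- small_sim(seed = 31)
  prep <- suppressWarnings(
    prepare_cohort(sim, min_train_count = 10, adjust = FALSE))
  drivers <- sim$config$driver_genes
  truth <- sim$truth$assignments
  for (g in drivers) {
    expect_setequal(colnames(prep$ab)[prep$ab[g, ]],
                    truth$sample_id[truth$driver == g])
  }
  # strict exclusivity holds in the emitted data, not only the ground truth
  expect_true(all(colSums(prep$ab[drivers, ]) <= 1))
})

test_that("engineered passenger records are all removed by the filter", {
  sim <- small_sim(seed = 32, passenger_rate = 0.9)
  surv <- filter_somatic(sim$mutations)
  # every surviving record in a panel gene must be a true driver event
  in_panel <- surv[surv$gene %in% sim$panel, ]
  truth <- sim$truth$assignments
  expect_true(all(
    truth$driver[match(in_panel$sample_id, truth$sample_id)] ==
      in_panel$gene))
  # and passengers were actually present before filtering
  expect_gt(nrow(sim$mutations), nrow(surv))
})
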