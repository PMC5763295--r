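# Canonical annotation vocabularies. Input files may use the spaced/parenthesised
# VEP spellings; these are normalised to the underscore forms on read.
.impact_levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
.sift_levels <- c("deleterious", "deleterious_low_confidence",
                  "tolerated", "tolerated_low_confidence")
.polyphen_levels <- c("probably_damaging", "possibly_damaging",
                      "benign", "unknown")

.normalize_term <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ ()]+", "_", x)
  gsub("_+$|^_+", "", gsub("__+", "_", x))
}

.as_missing <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | x == "NA"] <- NA_character_
  x
}

#' Read annotated somatic mutation calls
#'
#' Reads a minimal MAF-like tab-separated table of somatic variant calls with
#' VEP-style annotation columns. Expected columns: `sample_id`, `gene`,
#' `filter_status`, `exac_maf`, `impact`, `sift`, `polyphen`. Additional
#' columns are ignored; missing annotation cells (empty or `"NA"`) become
#' `NA`. Only `sample_id` and `gene` are mandatory; an entirely absent
#' annotation column is treated as all-missing.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.frame` with one row per variant call and the seven
#'   canonical columns. `exac_maf` is numeric in \[0, 1\]; `sift` and
#'   `polyphen` values are normalised to underscore form (e.g.
#'   `"deleterious_low_confidence"`).
#' @export
read_mutations <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  for (col in c("sample_id", "gene")) {
    if (!col %in% names(raw)) {
      stop("mutation file is missing mandatory column '", col, "': ", path)
    }
  }
  n <- nrow(raw)
  get_col <- function(col) {
    if (col %in% names(raw)) .as_missing(raw[[col]]) else rep(NA_character_, n)
  }
  out <- data.frame(
    sample_id = .as_missing(raw[["sample_id"]]),
    gene = .as_missing(raw[["gene"]]),
    filter_status = get_col("filter_status"),
    exac_maf = rep(NA_real_, n),
    impact = toupper(get_col("impact")),
    sift = .normalize_term(get_col("sift")),
    polyphen = .normalize_term(get_col("polyphen")),
    stringsAsFactors = FALSE
  )
  if (n > 0 && anyNA(out$gene)) {
    stop("mutation file has empty 'gene' at row ",
         which(is.na(out$gene))[1])
  }
  maf_chr <- get_col("exac_maf")
  maf <- suppressWarnings(as.numeric(maf_chr))
  bad <- which(!is.na(maf_chr) & is.na(maf))
  if (length(bad) > 0) {
    stop("unparseable exac_maf value '", maf_chr[bad[1]], "' at row ", bad[1])
  }
  oob <- which(!is.na(maf) & (maf < 0 | maf > 1))
  if (length(oob) > 0) {
    stop("exac_maf outside [0, 1] at row ", oob[1])
  }
  out$exac_maf <- maf
  out$sift[is.na(out$sift) | !nzchar(out$sift)] <- NA_character_
  out$polyphen[is.na(out$polyphen) | !nzchar(out$polyphen)] <- NA_character_
  bad_sift <- which(!is.na(out$sift) & !out$sift %in% .sift_levels)
  if (length(bad_sift) > 0) {
    stop("unrecognised SIFT value '", out$sift[bad_sift[1]], "' at row ",
         bad_sift[1])
  }
  bad_pp <- which(!is.na(out$polyphen) & !out$polyphen %in% .polyphen_levels)
  if (length(bad_pp) > 0) {
    stop("unrecognised PolyPhen value '", out$polyphen[bad_pp[1]],
         "' at row ", bad_pp[1])
  }
  out
}

.read_gene_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs a gene column plus >=1 sample: ", path)
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol in matrix file: ",
         genes[duplicated(genes)][1])
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  # data.frame subsetting mangles duplicate sample names; restore them
  dimnames(m) <- list(genes, names(raw)[-1])
  m
}

#' Read a GISTIC-style thresholded copy-number matrix
#'
#' Gene-by-sample tab-separated matrix with a leading gene column. Values must
#' be the five thresholded copy-number levels -2 (homozygous deletion), -1,
#' 0, 1, 2 (high-level amplification).
#'
#' @param path Path to the TSV file.
#' @return An integer matrix (genes x samples).
#' @export
read_cnv_matrix <- function(path) {
  m <- .read_gene_matrix(path)
  bad <- which(!(m %in% c(-2, -1, 0, 1, 2)) | is.na(m))
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dim(m))
    stop("copy-number value outside {-2,...,2} at gene '",
         rownames(m)[idx[1]], "', sample '", colnames(m)[idx[2]], "'")
  }
  storage.mode(m) <- "integer"
  m
}

#' Convert a thresholded copy-number matrix to long form
#'
#' @param cnv Integer matrix as returned by [read_cnv_matrix()].
#' @param drop_zero Omit copy-neutral (0) entries (default `FALSE`).
#' @return A `data.frame` with columns `sample_id`, `gene`,
#'   `threshold_value`, one row per matrix entry.
#' @export
cnv_calls <- function(cnv, drop_zero = FALSE) {
  idx <- which(if (drop_zero) cnv != 0L else !is.na(cnv), arr.ind = TRUE)
  data.frame(
    sample_id = colnames(cnv)[idx[, 2]],
    gene = rownames(cnv)[idx[, 1]],
    threshold_value = cnv[idx],
    stringsAsFactors = FALSE
  )
}

#' Read a TPM expression matrix
#'
#' Gene-by-sample tab-separated matrix of non-negative TPM values. Repeated
#' sample column names are accepted and flagged as replicate groups (tumors
#' sequenced multiple times); they are collapsed later by
#' [average_replicates()].
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()] in state `"raw_tpm"`.
#' @export
read_expression_matrix <- function(path) {
  m <- .read_gene_matrix(path)
  bad <- which(is.na(m) | m < 0)
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dim(m))
    stop("negative or missing expression value at gene '",
         rownames(m)[idx[1]], "', sample '", colnames(m)[idx[2]], "'")
  }
  dups <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dups) > 0) {
    message("expression file contains ", length(dups),
            " replicated sample ID(s); will be averaged")
  }
  expression_matrix(m, state = "raw_tpm")
}

#' Read a sample-to-cancer-type annotation table
#'
#' @param path TSV with columns `sample_id` and `cancer_type`.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  for (col in c("sample_id", "cancer_type")) {
    if (!col %in% names(ann)) stop("annotation file missing column '", col, "'")
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("sample annotated with more than one cancer type: ",
         ann$sample_id[duplicated(ann$sample_id)][1])
  }
  ann[, c("sample_id", "cancer_type")]
}

#' Read a cancer-gene panel
#'
#' @param path TSV (or headerless list) with a `gene` column of symbols.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_panel <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  col <- if ("gene" %in% names(tab)) tab$gene else tab[[1]]
  genes <- unique(.as_missing(col))
  genes[!is.na(genes)]
}

#' Read a drug-gene evidence table
#'
#' CIViC-like TSV with columns `gene`, `drug`, `evidence_status`. Only rows
#' whose status is exactly `"Supported"` are used when restricting the test
#' set.
#'
#' @param path TSV path.
#' @return A `data.frame` with the three columns.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  for (col in c("gene", "drug", "evidence_status")) {
    if (!col %in% names(ev)) stop("evidence file missing column '", col, "'")
  }
  ev[, c("gene", "drug", "evidence_status")]
}

#' Write / read a tidy result table
#'
#' One observation per row, one variable per column, tab-separated with a
#' header. The pair round-trips losslessly: `read_tidy(write_tidy(x))`
#' equals `x` up to numeric printing precision (15 significant digits).
#'
#' @param table A `data.frame`.
#' @param path Output path.
#' @export
write_tidy <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tidy
#' @export
read_tidy <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
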