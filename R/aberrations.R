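#' Filter annotated somatic variants
#'
#' Applies the quality and functional-impact filter to annotated somatic
#' variant calls. A record survives iff all of the following hold:
#' \itemize{
#'   \item `filter_status == "PASS"` (caller quality control);
#'   \item `exac_maf` is missing or `<= maf_max` (common germline variants
#'     masquerading as somatic calls are removed; absence of a population
#'     frequency is not evidence of commonness, so missing values are kept);
#'   \item `impact` is not `"LOW"` or `"MODIFIER"`;
#'   \item the variant is predicted deleterious by SIFT
#'     (`deleterious`/`deleterious_low_confidence`) or damaging by PolyPhen-2
#'     (`probably_damaging`/`possibly_damaging`), or carries no prediction
#'     from either tool. A variant with one prediction missing and the other
#'     explicitly benign/tolerated is removed: a present negative call is an
#'     explicit prediction.
#' }
#' The filter is a pure subset: row order is preserved and it is idempotent.
#'
#' @param records `data.frame` from [read_mutations()].
#' @param maf_max Maximum ExAC minor-allele frequency (default 0.01).
#' @return The surviving subset of `records`.
#' @export
filter_somatic <- function(records, maf_max = 0.01) {
  if (nrow(records) == 0) return(records)
  pass <- !is.na(records$filter_status) & records$filter_status == "PASS"
  maf_ok <- is.na(records$exac_maf) | records$exac_maf <= maf_max
  impact_ok <- is.na(records$impact) |
    !records$impact %in% c("LOW", "MODIFIER")
  sift_del <- !is.na(records$sift) &
    records$sift %in% c("deleterious", "deleterious_low_confidence")
  pp_dam <- !is.na(records$polyphen) &
    records$polyphen %in% c("probably_damaging", "possibly_damaging")
  no_pred <- is.na(records$sift) & is.na(records$polyphen)
  keep <- pass & maf_ok & impact_ok & (sift_del | pp_dam | no_pred)
  records[keep, , drop = FALSE]
}

#' Percentage of variant records removed by filtering
#'
#' @param n_before,n_after Record counts before and after [filter_somatic()].
#' @return Percentage removed, on a 0-100 scale.
#' @export
filter_attrition <- function(n_before, n_after) {
  if (n_before == 0) return(0)
  100 * (n_before - n_after) / n_before
}

#' Is a thresholded copy-number value an aberration?
#'
#' Only homozygous deletions (-2) and high-level amplifications (+2) count as
#' aberrations; single-copy losses and low-level gains are treated as having
#' at most a modest transcriptional effect.
#'
#' @param threshold_value Integer vector of GISTIC-style levels in
#'   \{-2, -1, 0, 1, 2\}.
#' @return Logical vector.
#' @export
cnv_is_aberrant <- function(threshold_value) {
  stopifnot(all(threshold_value %in% c(-2L, -1L, 0L, 1L, 2L)))
  threshold_value == -2L | threshold_value == 2L
}

#' Merge mutations and copy-number calls into a Boolean aberration matrix
#'
#' Combines filtered somatic variant records and thresholded copy-number
#' values into a single Boolean gene-by-sample matrix over the gene panel:
#' entry (g, s) is `TRUE` iff gene g is in the panel, sample s is in
#' `samples`, and s carries at least one surviving variant or one aberrant
#' copy-number call (+/-2) in g. Genes outside the panel and samples outside
#' `samples` are dropped; multiple events per (gene, sample) collapse to one
#' Boolean. `samples` should be the set of samples with all three data types
#' (mutation, copy number, expression).
#'
#' @param mutations Filtered records from [filter_somatic()].
#' @param cnv Integer matrix from [read_cnv_matrix()].
#' @param panel Character vector of panel gene symbols.
#' @param samples Character vector of sample IDs to retain.
#' @return Logical matrix, rows = panel genes (panel order), columns =
#'   `samples` (given order).
#' @export
merge_aberrations <- function(mutations, cnv, panel, samples) {
  panel <- unique(panel)
  samples <- unique(samples)
  if (length(samples) == 0) {
    stop("no samples with all three data types; cannot build aberration matrix")
  }
  ab <- matrix(FALSE, nrow = length(panel), ncol = length(samples),
               dimnames = list(panel, samples))
  mut <- mutations[mutations$gene %in% panel &
                     mutations$sample_id %in% samples, , drop = FALSE]
  if (nrow(mut) > 0) {
    ab[cbind(mut$gene, mut$sample_id)] <- TRUE
  }
  cg <- intersect(rownames(cnv), panel)
  cs <- intersect(colnames(cnv), samples)
  if (length(cg) > 0 && length(cs) > 0) {
    sub <- cnv[cg, cs, drop = FALSE]
    hit <- which(abs(sub) == 2L, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ab[cbind(cg[hit[, 1]], cs[hit[, 2]])] <- TRUE
    }
  }
  ab
}
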