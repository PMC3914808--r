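#' Somatic-filter parameters
#'
#' @param prob_threshold Minimum caller posterior probability, inclusive.
#' @param damaging_mode `"either"` retains variants flagged damaging by
#'   at least one predictor; `"both"` requires both. Unknown predictor
#'   values never count as damaging.
#' @return List of class `filter_params`. The normal-evidence rule is
#'   fixed at zero tolerance: any variant-supporting read in the normal
#'   removes the call.
#' @export
filter_params <- function(prob_threshold = 0.8,
                          damaging_mode = c("either", "both")) {
  stopifnot(prob_threshold >= 0, prob_threshold <= 1)
  structure(list(prob_threshold = prob_threshold,
                 damaging_mode = match.arg(damaging_mode),
                 max_normal_alt_reads = 0L),
            class = "filter_params")
}

is_indel <- function(calls) nchar(calls$ref) != 1L | nchar(calls$alt) != 1L

#' Extract somatic SNVs from tumor calls
#'
#' Retains calls with posterior probability at or above the threshold,
#' no variant-supporting reads in the matched normal, and at least one
#' variant read in the tumor. Order-preserving and idempotent. Records
#' missing normal evidence are rejected with a reason code (available in
#' `attr(result, "rejections")`). Indels are outside the analytic scope:
#' they are split off with a warning and returned untouched in
#' `attr(result, "indels")`.
#'
#' @param calls Variant table: `chrom, pos, ref, alt, posterior_prob,
#'   tumor_alt_reads, tumor_total_reads, normal_alt_reads,
#'   normal_total_reads` (+ optional predictor/annotation columns).
#' @param params [filter_params()].
#' @return The somatic subset of `calls`.
#' @examples
#' v <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "G", alt = "A",
#'                 posterior_prob = c(0.95, 0.95),
#'                 tumor_alt_reads = 12, tumor_total_reads = 30,
#'                 normal_alt_reads = c(0, 2), normal_total_reads = 30)
#' filter_somatic(v)  # only the normal_alt = 0 call survives
#' @export
filter_somatic <- function(calls, params = filter_params()) {
  stopifnot_cols(calls, c("chrom", "pos", "ref", "alt", "posterior_prob",
                          "tumor_alt_reads", "normal_alt_reads"), "calls")
  if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  indel <- is_indel(calls)
  indels <- calls[indel, , drop = FALSE]
  snv <- calls[!indel, , drop = FALSE]
  if (nrow(indels))
    warning(nrow(indels), " indel record(s) set aside unfiltered; ",
            "see attr(result, 'indels')")
  missing_normal <- is.na(snv$normal_alt_reads)
  rejections <- data.frame(
    chrom = snv$chrom[missing_normal], pos = snv$pos[missing_normal],
    reason = rep("missing_normal_evidence", sum(missing_normal)),
    stringsAsFactors = FALSE)
  keep <- !missing_normal &
    !is.na(snv$posterior_prob) &
    snv$posterior_prob >= params$prob_threshold &
    snv$normal_alt_reads <= params$max_normal_alt_reads &
    snv$tumor_alt_reads >= 1
  out <- snv[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  attr(out, "indels") <- indels
  out
}

#' Select damaging somatic candidates
#'
#' Applies the functional-impact selection: variants predicted damaging
#' by SIFT and/or PolyPhen (per `damaging_mode`) are retained for
#' validation. Predictor outputs are consumed as input flags, never
#' computed; `NA` (unknown) counts as not damaging.
#'
#' @param somatic [filter_somatic()] output (needs logical columns
#'   `sift_damaging`, `polyphen_damaging`).
#' @param params [filter_params()].
#' @return The damaging subset.
#' @export
select_damaging <- function(somatic, params = filter_params()) {
  stopifnot_cols(somatic, c("sift_damaging", "polyphen_damaging"), "somatic")
  s <- !is.na(somatic$sift_damaging) & somatic$sift_damaging
  p <- !is.na(somatic$polyphen_damaging) & somatic$polyphen_damaging
  keep <- if (params$damaging_mode == "either") s | p else s & p
  out <- somatic[keep, , drop = FALSE]
  attr(out, "rejections") <- NULL
  attr(out, "indels") <- NULL
  out
}

#' Report table of damaging somatic variants
#'
#' Formats the validated-variant report: chromosome, 1-based position,
#' allele change (`R > A`), amino-acid change and gene.
#'
#' @param variants Damaging somatic variants ([select_damaging()]).
#' @return data.frame with columns `chrom, pos, allele_change,
#'   amino_acid_change, gene`.
#' @export
somatic_report <- function(variants) {
  data.frame(
    chrom = variants$chrom,
    pos = variants$pos,
    allele_change = paste(variants$ref, ">", variants$alt),
    amino_acid_change = if ("amino_acid_change" %in% names(variants))
      variants$amino_acid_change else "",
    gene = if ("gene" %in% names(variants)) variants$gene else "",
    stringsAsFactors = FALSE)
}
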