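#' Packaged validated tables from a well-differentiated liposarcoma case
#'
#' The package ships two small validated result tables from a
#' whole-genome study of a flow-sorted well-differentiated liposarcoma:
#' `"fusions"` -- 11 DNA-validated gene fusions (7 intrachromosomal
#' rearrangements, 4 translocations) with 1-based NCBI36 breakpoints and
#' read-orientation labels; `"snvs"` -- 7 capillary-validated, damaging
#' somatic single-nucleotide variants. They serve as worked-example
#' inputs for the partner filter, hotspot scan and somatic report.
#'
#' @param name `"fusions"` or `"snvs"`.
#' @return data.frame of the requested table. Unknown names are an
#'   error.
#' @examples
#' fus <- wdls_fixture("fusions")
#' hotspot_scan(fus, c("NAV3", "SYT1", "PAWR"))
#' @export
wdls_fixture <- function(name = c("fusions", "snvs")) {
  name <- match.arg(name)
  file <- system.file("extdata",
                      switch(name,
                             fusions = "wdls_validated_fusions.tsv",
                             snvs = "wdls_validated_snvs.tsv"),
                      package = "pairfuse", mustWork = TRUE)
  utils::read.delim(file, stringsAsFactors = FALSE, encoding = "UTF-8",
                    check.names = FALSE)
}

#' Interpret fixture tables as pipeline objects
#'
#' `fixture_as_candidates()` maps the validated-fusion table onto the
#' fusion-candidate schema (orientation classes recovered from the
#' printed labels; support unknown). `fixture_as_variants()` maps the
#' validated-SNV table onto the variant-record schema; read-count and
#' predictor columns are synthetic defaults chosen so every validated
#' record passes the somatic filter chain, since the published table
#' reports only locus, allele change, amino-acid change and gene.
#'
#' @param fixture A [wdls_fixture()] table.
#' @return data.frame in the corresponding pipeline schema.
#' @export
fixture_as_candidates <- function(fixture) {
  stopifnot_cols(fixture, c("chrom1", "breakpoint1", "gene1", "chrom2",
                            "breakpoint2", "gene2", "reads_label", "kind"),
                 "fixture")
  data.frame(
    gene1 = fixture$gene1, gene2 = fixture$gene2,
    chrom1 = as.character(fixture$chrom1),
    breakpoint1 = as.integer(fixture$breakpoint1),
    chrom2 = as.character(fixture$chrom2),
    breakpoint2 = as.integer(fixture$breakpoint2),
    orientation = orientation_from_label(fixture$reads_label),
    orientation_label = fixture$reads_label,
    support = NA_integer_, kind = fixture$kind,
    passes_partner_filter = NA, stringsAsFactors = FALSE)
}

#' @rdname fixture_as_candidates
#' @export
fixture_as_variants <- function(fixture) {
  stopifnot_cols(fixture, c("chrom", "pos", "allele_change",
                            "amino_acid_change", "gene"), "fixture")
  alleles <- strsplit(gsub("\\s", "", fixture$allele_change), ">")
  data.frame(
    chrom = as.character(fixture$chrom), pos = as.integer(fixture$pos),
    ref = vapply(alleles, `[`, character(1), 1),
    alt = vapply(alleles, `[`, character(1), 2),
    posterior_prob = 0.99,
    tumor_alt_reads = 15L, tumor_total_reads = 30L,
    normal_alt_reads = 0L, normal_total_reads = 30L,
    sift_damaging = TRUE, polyphen_damaging = TRUE,
    amino_acid_change = fixture$amino_acid_change,
    gene = fixture$gene, stringsAsFactors = FALSE)
}
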