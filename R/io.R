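#' Read and write pipeline text formats
#'
#' Plain-text readers and writers for every artifact the pipeline
#' produces or consumes: the 9-column read-pair TSV dialect, a minimal
#' SAM rendering of the same pairs, gene models as BED6 (score 1 marks a
#' coding gene), aCGH probes, copy-number segments, variant tables
#' (VCF-lite TSV), DNA-content histograms, fusion candidate tables,
#' junction BEDPE and truth sets as JSON. Every writer's output is
#' re-parseable by the matching reader. Interval formats (BED, BEDPE)
#' are 0-based half-open; all other positions are 1-based.
#'
#' @param pairs,genome,probes,segments,variants,hist,candidates,truth
#'   Objects produced by the corresponding pipeline stages.
#' @param path File path.
#' @param model An [insert_model()] (for SAM TLEN).
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

tsv_read <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  # chromosome names are labels even when they look numeric
  for (col in intersect(c("chrom", "chrom1", "chrom2"), names(df)))
    df[[col]] <- as.character(df[[col]])
  df
}

#' @rdname pipeline_io
#' @export
write_pairs <- function(pairs, path) tsv_write(pairs[, c(
  "pair_id", "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
  "mapq_min", "sample")], path)

#' @rdname pipeline_io
#' @export
read_pairs <- function(path) {
  p <- tsv_read(path)
  stopifnot_cols(p, c("pair_id", "chrom1", "pos1", "strand1", "chrom2",
                      "pos2", "strand2", "mapq_min", "sample"), path)
  p
}

#' @rdname pipeline_io
#' @export
write_sam_pairs <- function(pairs, genome, path, model = insert_model()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (cn in genome$chrom_names)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", cn,
                       as.integer(genome$chrom_lengths[[cn]])), con)
  if (!nrow(pairs)) return(invisible(path))
  L <- model$read_length
  flag <- function(strand, mate_strand, first) {
    1L + 2L * 0L + ifelse(strand == "-", 16L, 0L) +
      ifelse(mate_strand == "-", 32L, 0L) + if (first) 64L else 128L
  }
  tlen <- ifelse(pairs$chrom1 == pairs$chrom2,
                 pairs$pos2 - pairs$pos1 + L, 0L)
  line <- function(first) {
    if (first) {
      ch <- pairs$chrom1; po <- pairs$pos1; st <- pairs$strand1
      mch <- pairs$chrom2; mpo <- pairs$pos2; mst <- pairs$strand2
      tl <- tlen
    } else {
      ch <- pairs$chrom2; po <- pairs$pos2; st <- pairs$strand2
      mch <- pairs$chrom1; mpo <- pairs$pos1; mst <- pairs$strand1
      tl <- -tlen
    }
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t*\t*\tRG:Z:%s",
            pairs$pair_id, flag(st, mst, first), ch, po, pairs$mapq_min, L,
            ifelse(mch == ch, "=", mch), mpo, tl, pairs$sample)
  }
  writeLines(c(rbind(line(TRUE), line(FALSE))), con)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_sam_pairs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(pair_id = character(0), chrom1 = character(0),
                      pos1 = integer(0), strand1 = character(0),
                      chrom2 = character(0), pos2 = integer(0),
                      strand2 = character(0), mapq_min = integer(0),
                      sample = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, character(1), 1)
  flag <- as.integer(vapply(f, `[`, character(1), 2))
  first <- bitwAnd(flag, 64L) > 0L
  rec <- data.frame(
    pair_id = qname,
    chrom = vapply(f, `[`, character(1), 3),
    pos = as.integer(vapply(f, `[`, character(1), 4)),
    mapq = as.integer(vapply(f, `[`, character(1), 5)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    sample = sub("^RG:Z:", "",
                 vapply(f, function(x) {
                   rg <- grep("^RG:Z:", x, value = TRUE)
                   if (length(rg)) rg[1] else "RG:Z:tumor"
                 }, character(1))),
    first = first, stringsAsFactors = FALSE)
  m1 <- rec[rec$first, , drop = FALSE]
  m2 <- rec[!rec$first, , drop = FALSE]
  m2 <- m2[match(m1$pair_id, m2$pair_id), , drop = FALSE]
  canonicalize_pairs(data.frame(
    pair_id = m1$pair_id,
    chrom1 = m1$chrom, pos1 = m1$pos, strand1 = m1$strand,
    chrom2 = m2$chrom, pos2 = m2$pos, strand2 = m2$strand,
    mapq_min = pmin(m1$mapq, m2$mapq),
    sample = m1$sample, stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @export
write_gene_bed <- function(genome, path) {
  g <- genome$genes
  tsv <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                    name = g$gene, score = as.integer(g$is_coding),
                    strand = g$strand)
  utils::write.table(tsv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gene_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
  data.frame(gene = b$name, chrom = b$chrom, start = b$start, end = b$end,
             strand = b$strand, is_coding = b$score > 0,
             stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
write_probes <- function(probes, path)
  tsv_write(probes[, c("chrom", "start", "end", "log2ratio")], path)

#' @rdname pipeline_io
#' @export
read_probes <- function(path) {
  p <- tsv_read(path)
  stopifnot_cols(p, c("chrom", "start", "end", "log2ratio"), path)
  p
}

#' @rdname pipeline_io
#' @export
write_segments <- function(segments, path)
  tsv_write(as.data.frame(segments), path)

#' @rdname pipeline_io
#' @export
read_segments <- function(path) {
  s <- tsv_read(path)
  class(s) <- c("cn_segments", "data.frame")
  s
}

#' @rdname pipeline_io
#' @export
write_variants <- function(variants, path) tsv_write(variants, path)

#' @rdname pipeline_io
#' @export
read_variants <- function(path) {
  v <- tsv_read(path)
  stopifnot_cols(v, c("chrom", "pos", "ref", "alt", "posterior_prob"), path)
  v
}

#' @rdname pipeline_io
#' @export
write_histogram <- function(hist, path) {
  df <- if (inherits(hist, "dna_histogram"))
    data.frame(channel = hist$channel, count = hist$count) else hist
  tsv_write(df, path)
}

#' @rdname pipeline_io
#' @export
read_histogram <- function(path) {
  h <- tsv_read(path)
  stopifnot_cols(h, c("channel", "count"), path)
  structure(list(channel = h$channel, count = h$count,
                 n_events = sum(h$count), params = NULL,
                 unresolvable = NA), class = "dna_histogram")
}

#' @rdname pipeline_io
#' @export
write_fusion_table <- function(candidates, path) {
  if (inherits(candidates, "fusion_calls")) candidates <- candidates$candidates
  tsv_write(candidates, path)
}

#' @rdname pipeline_io
#' @export
read_fusion_table <- function(path) tsv_read(path)

#' @rdname pipeline_io
#' @export
write_bedpe <- function(candidates, path) {
  if (inherits(candidates, "fusion_calls")) candidates <- candidates$candidates
  df <- data.frame(
    chrom1 = candidates$chrom1,
    start1 = candidates$breakpoint1 - 1L, end1 = candidates$breakpoint1,
    chrom2 = candidates$chrom2,
    start2 = candidates$breakpoint2 - 1L, end2 = candidates$breakpoint2,
    name = paste(candidates$gene1, candidates$gene2, sep = "--"),
    score = candidates$support)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(junctions = truth$junctions,
                            copy_number = truth$copy_number,
                            somatic_variants = truth$somatic_variants),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(junctions = x$junctions, copy_number = x$copy_number,
                 somatic_variants = x$somatic_variants,
                 ploidy_truth = x$ploidy_truth),
            class = "truth_set")
}
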