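#' Build a toy reference genome with a gene model
#'
#' Generates a small multi-chromosome reference with non-overlapping genes,
#' standing in for a real assembly plus annotation when exercising the
#' pipeline on synthetic data. Coordinates are 0-based half-open
#' internally; serialized reports are 1-based.
#'
#' Optional `repeat_regions` declare repeat-like noisy intervals: read
#' simulation emits mapq-0 mates and clustered germline anomalous pairs
#' there (see [simulate_pairs()]), so germline-blacklist behavior can be
#' exercised with known truth.
#'
#' @param seed Integer seed; the genome is deterministic given the seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Total number of genes, distributed evenly.
#' @param gene_length Length range (min, max) for simulated genes.
#' @param coding_frac Fraction of genes flagged as coding.
#' @param repeat_regions Optional data.frame (chrom, start, end) of declared
#'   repeat-like regions.
#' @return An object of class `toy_genome`: chromosome names/lengths, a
#'   `genes` data.frame (gene, chrom, start, end, strand, is_coding) and
#'   the repeat regions.
#' @examples
#' g <- build_toy_genome(seed = 1, n_chroms = 3, chrom_length = 2e5, n_genes = 30)
#' g
#' @export
build_toy_genome <- function(seed, n_chroms = 3, chrom_length = 200000,
                             n_genes = 30, gene_length = c(2000, 6000),
                             coding_frac = 1, repeat_regions = NULL) {
  stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0)
  chrom_names <- paste0("chr", seq_len(n_chroms))
  chrom_lengths <- stats::setNames(rep(as.integer(chrom_length), n_chroms),
                                   chrom_names)
  per_chrom <- tabulate(rep_len(seq_len(n_chroms), n_genes), n_chroms)
  if (any(per_chrom * max(gene_length) > 0.9 * chrom_length))
    stop("infeasible gene packing: requested genes cannot fit in ",
         "chromosomes of length ", chrom_length)

  genes <- with_seed(seed, {
    rows <- vector("list", n_chroms)
    for (ci in seq_len(n_chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0) next
      placed_start <- integer(0); placed_end <- integer(0)
      for (gi in seq_len(ng)) {
        len <- as.integer(round(stats::runif(1, gene_length[1], gene_length[2])))
        ok <- FALSE
        for (try in seq_len(1000)) {
          st <- as.integer(floor(stats::runif(1, 0, chrom_length - len)))
          en <- st + len
          if (!any(st < placed_end & en > placed_start)) { ok <- TRUE; break }
        }
        if (!ok) stop("infeasible gene packing on ", chrom_names[ci])
        placed_start <- c(placed_start, st); placed_end <- c(placed_end, en)
      }
      o <- order(placed_start)
      rows[[ci]] <- data.frame(
        chrom = chrom_names[ci],
        start = placed_start[o], end = placed_end[o],
        strand = sample(c("+", "-"), ng, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows[lengths(rows) > 0])
    if (is.null(g)) {
      g <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
    }
    g$gene <- sprintf("g%03d", seq_len(nrow(g)))
    g$is_coding <- seq_len(nrow(g)) <= round(coding_frac * nrow(g))
    # shuffle which genes are non-coding so they are not all on one chrom
    g$is_coding <- sample(g$is_coding)
    g[, c("gene", "chrom", "start", "end", "strand", "is_coding")]
  })

  genome <- structure(
    list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
         genes = genes, repeat_regions = repeat_regions),
    class = "toy_genome")
  validate_genome(genome)
  genome
}

validate_genome <- function(genome) {
  g <- genome$genes
  if (anyDuplicated(g$gene)) stop("gene names must be unique")
  if (any(g$start >= g$end)) stop("gene start must be < end")
  bad <- !(g$chrom %in% genome$chrom_names) |
    g$start < 0 | g$end > genome$chrom_lengths[g$chrom]
  if (any(bad)) stop("gene interval(s) outside chromosome bounds: ",
                     paste(g$gene[bad], collapse = ", "))
  rr <- genome$repeat_regions
  if (!is.null(rr)) {
    stopifnot_cols(rr, c("chrom", "start", "end"), "repeat_regions")
    if (any(!(rr$chrom %in% genome$chrom_names)) ||
        any(rr$start < 0) || any(rr$end > genome$chrom_lengths[rr$chrom]))
      stop("repeat region outside chromosome bounds")
  }
  invisible(genome)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("Toy genome: %d chromosome(s), %s bp total, %d gene(s) (%d coding)\n",
              length(x$chrom_names),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ","),
              nrow(x$genes), sum(x$genes$is_coding)))
  if (!is.null(x$repeat_regions))
    cat(sprintf("  %d declared repeat-like region(s)\n", nrow(x$repeat_regions)))
  invisible(x)
}
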