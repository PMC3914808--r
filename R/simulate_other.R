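#' Simulate aCGH probe log2 ratios
#'
#' Lays probes at fixed spacing along the genome; each probe's log2 ratio
#' is `log2(total_copies / 2)` at its midpoint plus Gaussian noise.
#' Hybridization chemistry is not modeled -- only the log2-ratio
#' structure a two-channel array reports.
#'
#' @param genome A `toy_genome` (chromosome lengths).
#' @param copy_number data.frame `chrom, start, end, total_copies`
#'   (0-based half-open); `NULL` means diploid everywhere.
#' @param spacing Probe spacing in bases.
#' @param noise_sd Per-probe noise standard deviation in log2 units.
#' @param seed Integer seed or `NULL`.
#' @return data.frame `chrom, start, end, log2ratio`.
#' @examples
#' g <- build_toy_genome(seed = 1)
#' cn <- data.frame(chrom = "chr1", start = 50000, end = 80000, total_copies = 8)
#' pr <- simulate_probes(g, cn, spacing = 1000, noise_sd = 0, seed = 1)
#' range(pr$log2ratio)  # 0 outside, 2 inside the amplicon
#' @export
simulate_probes <- function(genome, copy_number = NULL, spacing = 1000,
                            noise_sd = 0.2, seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"), spacing > 0, noise_sd >= 0)
  rows <- lapply(genome$chrom_names, function(cn) {
    len <- genome$chrom_lengths[[cn]]
    starts <- seq.int(0L, len - spacing, by = spacing)
    data.frame(chrom = cn, start = as.integer(starts),
               end = as.integer(starts + spacing), stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, rows)
  copies <- rep(2, nrow(probes))
  if (!is.null(copy_number) && nrow(copy_number)) {
    stopifnot_cols(copy_number, c("chrom", "start", "end", "total_copies"),
                   "copy_number")
    if (any(copy_number$total_copies < 1))
      stop("total_copies must be >= 1")
    mid <- (probes$start + probes$end) / 2
    for (i in seq_len(nrow(copy_number))) {
      sel <- probes$chrom == copy_number$chrom[i] &
        mid >= copy_number$start[i] & mid < copy_number$end[i]
      copies[sel] <- copy_number$total_copies[i]
    }
  }
  probes$log2ratio <- with_seed(seed,
    log2(copies / 2) + stats::rnorm(nrow(probes), 0, noise_sd))
  probes
}

#' Simulate a DAPI DNA-content histogram
#'
#' DAPI binds stoichiometrically to DNA, so a sorted nuclei preparation
#' yields a fluorescence histogram whose peaks sit at DNA contents of the
#' populations present. The simulated mixture holds a diploid G0/G1
#' reference peak at `reference_channel`, an aneuploid G0/G1 peak at
#' `dna_index` times that, and an aneuploid G2/M peak at twice the
#' aneuploid G0/G1 position carrying `g2m_fraction` of aneuploid events.
#' Peak standard deviations are `cv * mean`. Defaults reproduce the
#' study-case preset: DNA index 1.15 (a 2.3N population), 14% G2/M
#' (4.6N), CV 4%, 50,000 events.
#'
#' @param dna_index Aneuploid G0/G1 DNA content relative to diploid.
#' @param g2m_fraction Fraction of aneuploid events in G2/M.
#' @param cv Peak coefficient of variation (0 < cv < 0.2).
#' @param n_events Total events; bin counts sum to this exactly.
#' @param diploid_fraction Fraction of events in the diploid reference
#'   population.
#' @param seed Integer seed or `NULL`.
#' @param n_channels Number of fluorescence channels (>= 1024).
#' @param reference_channel Channel of the diploid G0/G1 peak.
#' @return Object of class `dna_histogram`: `channel`, `count`,
#'   `n_events`, the generating parameters, and an `unresolvable` flag set
#'   when the aneuploid peak lies within `2 * cv` of the diploid peak.
#' @export
simulate_histogram <- function(dna_index = 1.15, g2m_fraction = 0.14,
                               cv = 0.04, n_events = 50000,
                               diploid_fraction = 0.4, seed = NULL,
                               n_channels = 1024, reference_channel = 200) {
  stopifnot(cv > 0, cv < 0.2, g2m_fraction >= 0, g2m_fraction < 1,
            diploid_fraction >= 0, diploid_fraction <= 1, n_events >= 0,
            n_channels >= 1024, dna_index > 0)
  n_dip <- round(diploid_fraction * n_events)
  n_aneu <- n_events - n_dip
  n_g2m <- round(g2m_fraction * n_aneu)
  n_g1 <- n_aneu - n_g2m
  means <- reference_channel * c(1, dna_index, 2 * dna_index)
  if (max(means) > 0.95 * n_channels)
    stop("peaks fall outside the channel range; increase n_channels")
  counts <- with_seed(seed, {
    v <- c(stats::rnorm(n_dip, means[1], cv * means[1]),
           stats::rnorm(n_g1, means[2], cv * means[2]),
           stats::rnorm(n_g2m, means[3], cv * means[3]))
    tabulate(pmin(pmax(round(v), 1), n_channels), n_channels)
  })
  unresolvable <- abs(dna_index - 1) < 2 * cv
  if (unresolvable)
    warning("diploid and aneuploid G0/G1 peaks are unresolvable at this CV")
  structure(list(channel = seq_len(n_channels), count = counts,
                 n_events = n_events,
                 params = list(dna_index = dna_index,
                               g2m_fraction = g2m_fraction, cv = cv,
                               diploid_fraction = diploid_fraction,
                               reference_channel = reference_channel),
                 unresolvable = unresolvable),
            class = "dna_histogram")
}

#' @export
print.dna_histogram <- function(x, ...) {
  cat(sprintf("DNA-content histogram: %d events in %d channels%s\n",
              x$n_events, length(x$channel),
              if (isTRUE(x$unresolvable)) " [unresolvable peaks]" else ""))
  invisible(x)
}

#' Simulate tumor/normal variant tables
#'
#' Builds the variant-call table consumed by [filter_somatic()]: truth
#' somatic variants present in the tumor only (zero variant reads in the
#' normal), plus germline polymorphisms present in both samples. A
#' configurable fraction of somatic records receives a posterior
#' probability below 0.8 (caller uncertainty) and a configurable fraction
#' carries damaging predictor flags.
#'
#' @param somatic data.frame `chrom, pos, ref, alt` of truth somatic
#'   variants (e.g. `truth$somatic_variants`), or `NULL`.
#' @param genome `toy_genome` used to place germline variants.
#' @param n_germline Number of germline variants.
#' @param prob_range Range the passing posterior probabilities are drawn
#'   from.
#' @param frac_lowprob Fraction of somatic records demoted below the 0.8
#'   probability threshold.
#' @param frac_damaging Fraction of somatic records flagged damaging by
#'   at least one predictor.
#' @param mean_depth Mean sequencing depth for read counts.
#' @param seed Integer seed or `NULL`.
#' @return Variant table (`chrom, pos, ref, alt, posterior_prob,
#'   tumor_alt_reads, tumor_total_reads, normal_alt_reads,
#'   normal_total_reads, sift_damaging, polyphen_damaging,
#'   amino_acid_change, gene, is_somatic_truth`).
#' @export
simulate_variant_table <- function(somatic = NULL, genome, n_germline = 50,
                                   prob_range = c(0.85, 1), frac_lowprob = 0,
                                   frac_damaging = 1, mean_depth = 30,
                                   seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    mk <- function(chrom, pos, ref, alt, somatic_truth) {
      n <- length(pos)
      tt <- pmax(stats::rpois(n, mean_depth), 4L)
      nt <- pmax(stats::rpois(n, mean_depth), 4L)
      ta <- pmax(stats::rbinom(n, tt, 0.45), 1L)
      na <- if (somatic_truth) rep(0L, n) else
        pmax(stats::rbinom(n, nt, 0.5), 1L)
      data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 posterior_prob = stats::runif(n, prob_range[1], prob_range[2]),
                 tumor_alt_reads = ta, tumor_total_reads = tt,
                 normal_alt_reads = na, normal_total_reads = nt,
                 sift_damaging = FALSE, polyphen_damaging = FALSE,
                 amino_acid_change = "", gene = "",
                 is_somatic_truth = somatic_truth, stringsAsFactors = FALSE)
    }
    som <- NULL
    if (!is.null(somatic) && nrow(somatic)) {
      stopifnot_cols(somatic, c("chrom", "pos", "ref", "alt"), "somatic")
      if (any(somatic$ref == somatic$alt)) stop("ref and alt must differ")
      som <- mk(somatic$chrom, somatic$pos, somatic$ref, somatic$alt, TRUE)
      ns <- nrow(som)
      n_low <- round(frac_lowprob * ns)
      if (n_low) {
        low_idx <- sample.int(ns, n_low)
        som$posterior_prob[low_idx] <- stats::runif(n_low, 0.3, 0.79)
      }
      n_dam <- round(frac_damaging * ns)
      if (n_dam) {
        dam_idx <- sample.int(ns, n_dam)
        som$sift_damaging[dam_idx] <- stats::runif(n_dam) < 0.8
        som$polyphen_damaging[dam_idx] <-
          som$polyphen_damaging[dam_idx] | !som$sift_damaging[dam_idx] |
          stats::runif(n_dam) < 0.5
      }
      # annotate gene where the variant lands in one
      for (i in seq_len(ns)) {
        g <- genome$genes
        hit <- g$chrom == som$chrom[i] & g$start < som$pos[i] &
          g$end >= som$pos[i]
        if (any(hit)) som$gene[i] <- g$gene[which(hit)[1]]
      }
    }
    ger <- NULL
    if (n_germline > 0) {
      chrom <- sample(genome$chrom_names, n_germline, replace = TRUE,
                      prob = genome$chrom_lengths / sum(genome$chrom_lengths))
      pos <- floor(stats::runif(n_germline) *
                     (genome$chrom_lengths[chrom] - 1)) + 1L
      ref <- sample(bases, n_germline, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      ger <- mk(chrom, pos, ref, unname(alt), FALSE)
    }
    out <- rbind(som, ger)
    if (is.null(out)) return(mk(character(0), integer(0), character(0),
                                character(0), FALSE))
    out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
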