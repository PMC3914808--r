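# shared builders for the test suite; everything is generated in code

# one-row read pair with defaults filled in
mk_pair <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                    mapq_min = 60, sample = "tumor",
                    pair_id = "p1") {
  data.frame(pair_id = pair_id, chrom1 = chrom1, pos1 = as.integer(pos1),
             strand1 = strand1, chrom2 = chrom2, pos2 = as.integer(pos2),
             strand2 = strand2, mapq_min = as.integer(mapq_min),
             sample = sample, stringsAsFactors = FALSE)
}

mk_pairs <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$pair_id <- sprintf("p%03d", seq_len(nrow(out)))
  out
}

# a genome plus >= 6 gene-anchored junctions across all event types,
# used by the end-to-end recall checks
recall_scenario <- function(seed = 1) {
  g <- build_toy_genome(seed = seed, n_chroms = 3, chrom_length = 200000,
                        n_genes = 30)
  gn <- g$genes
  mid <- function(i) as.integer((gn$start[i] + gn$end[i]) / 2)
  c1 <- which(gn$chrom == "chr1")
  c2 <- which(gn$chrom == "chr2")
  c3 <- which(gn$chrom == "chr3")
  events <- rbind(
    sv_deletion("chr1", mid(c1[1]), mid(c1[3])),
    sv_tandem_duplication("chr1", mid(c1[5]), mid(c1[7])),
    sv_inversion("chr2", mid(c2[2]), mid(c2[5])),
    sv_amplicon("chr3", mid(c3[5]), mid(c3[7]), copies = 6),
    sv_translocation("chr2", mid(c2[8]), "+", "chr3", mid(c3[2]), "-"),
    sv_translocation("chr1", mid(c1[9]), "-", "chr2", mid(c2[6]), "+"))
  list(genome = g, events = events, implant = implant_events(g, events))
}

# literal per-base projection of a donor walk back to the reference:
# refpos[i] / refstrand[i] for donor base i (1-based within the walk)
walk_base_map <- function(walk) {
  refpos <- integer(0); refstrand <- character(0); chrom <- character(0)
  for (i in seq_len(nrow(walk))) {
    st <- walk$start[i]; en <- walk$end[i]
    if (walk$orient[i] == "+") {
      refpos <- c(refpos, st:(en - 1))
      refstrand <- c(refstrand, rep("+", en - st))
    } else {
      refpos <- c(refpos, (en - 1):st)
      refstrand <- c(refstrand, rep("-", en - st))
    }
    chrom <- c(chrom, rep(walk$chrom[i], en - st))
  }
  data.frame(chrom = chrom, refpos = refpos, refstrand = refstrand,
             stringsAsFactors = FALSE)
}

# constructive junction oracle: read each novel adjacency of the donor
# walk by placing a fragment literally across it in base space, projecting
# both mates through the base map, and classifying the resulting pair.
# Returns one row per distinct novel adjacency with the observed
# orientation and the cut coordinates on each side.
oracle_junctions <- function(donor, model = insert_model()) {
  L <- model$read_length
  out <- list()
  for (wname in names(donor$walks)) {
    walk <- donor$walks[[wname]]
    if (nrow(walk) < 2) next
    bmap <- walk_base_map(walk)
    seg_end_idx <- cumsum(walk$end - walk$start)
    for (j in seq_len(nrow(walk) - 1)) {
      a <- walk[j, ]; b <- walk[j + 1, ]
      contiguous <- a$chrom == b$chrom && a$orient == b$orient &&
        ((a$orient == "+" && b$start == a$end) ||
           (a$orient == "-" && b$end == a$start))
      if (contiguous) next
      cut <- seg_end_idx[j]                       # donor base index of cut
      m1 <- bmap[(cut - L + 1):cut, ]             # last L bases before cut
      m2 <- bmap[(cut + 1):(cut + L), ]           # first L bases after
      mate <- function(m, donor_strand) {
        seg_strand <- m$refstrand[1]
        list(chrom = m$chrom[1], pos = min(m$refpos) + 1L,
             strand = if (donor_strand == "+") seg_strand else
               setdiff(c("+", "-"), seg_strand))
      }
      a1 <- mate(m1, "+"); a2 <- mate(m2, "-")
      p <- classify_pairs(canonicalize_pairs(
        mk_pair(a1$chrom, a1$pos, a1$strand, a2$chrom, a2$pos, a2$strand)),
        model)
      bp_a <- if (a$orient == "+") a$end else a$start
      bp_b <- if (b$orient == "+") b$start else b$end
      out[[length(out) + 1]] <- data.frame(
        chrom_a = a$chrom, pos_a = bp_a, chrom_b = b$chrom, pos_b = bp_b,
        orientation = p$orientation, stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, out))
}

# exhaustive split-scan segmentation oracle (brute force, independent of
# the package's cumulative-sum implementation)
oracle_segment <- function(x, min_probes = 3, alpha = 1e-4) {
  n <- length(x)
  if (n < 2 * min_probes) return(list(c(1L, as.integer(n))))
  ts <- sapply(seq.int(min_probes, n - min_probes), function(i) {
    x1 <- x[1:i]; x2 <- x[(i + 1):n]
    m1 <- mean(x1); m2 <- mean(x2)
    sp <- (sum((x1 - m1)^2) + sum((x2 - m2)^2)) / (n - 2)
    if (sp <= 1e-12) { if (abs(m1 - m2) > 1e-12) Inf else 0 }
    else abs(m1 - m2) / sqrt(sp * (1 / i + 1 / (n - i)))
  })
  crit <- stats::qt(1 - alpha / 2, n - 2)
  k <- which.max(ts)
  if (!(ts[k] > crit)) return(list(c(1L, n)))
  sp <- as.integer(min_probes + k - 1L)
  left <- oracle_segment(x[1:sp], min_probes, alpha)
  right <- oracle_segment(x[(sp + 1):n], min_probes, alpha)
  c(left, lapply(right, function(r) as.integer(r + sp)))
}

# does a candidate table contain a row matching a truth junction?
matches_junction <- function(cands, j, w) {
  same <- (cands$chrom1 == j$chrom_a & cands$chrom2 == j$chrom_b &
             abs(cands$breakpoint1 - j$pos_a) <= w &
             abs(cands$breakpoint2 - j$pos_b) <= w) |
          (cands$chrom1 == j$chrom_b & cands$chrom2 == j$chrom_a &
             abs(cands$breakpoint1 - j$pos_b) <= w &
             abs(cands$breakpoint2 - j$pos_a) <= w)
  any(same & cands$orientation == j$orientation)
}
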