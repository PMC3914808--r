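#' Simulate paired-end read pairs from a donor genome
#'
#' Draws fragments uniformly along the donor walk with truncated-normal
#' insert sizes, projects both mates back through the segment walk into
#' reference coordinates, and returns the pair table consumed by the
#' classifier ([classify_pairs()]). Base-level sequence is not simulated:
#' fusion detection operates on coordinates, strands and mapping quality
#' only.
#'
#' The requested pair count (`round(coverage * donor_length /
#' (2 * read_length))`) is met exactly; fragments whose mate would cross a
#' donor segment boundary (split reads, a non-goal) are resampled.
#' Declared repeat-like regions of the underlying genome additionally emit
#' alignment-artifact noise: mates overlapping a repeat region drop to
#' mapq 0 with probability `repeat_mapq0_frac`, and clustered anomalous
#' pairs linking paired repeat regions are added at `repeat_anom_rate`
#' (relative to the region's own expected pair count). This noise is
#' germline: it appears in any sample simulated over that genome, which is
#' what the germline blacklist is built to absorb.
#'
#' @param donor A `donor_genome` from [implant_events()] / [as_donor()].
#' @param model An [insert_model()].
#' @param coverage Fold sequence coverage (> 0).
#' @param seed Integer seed or `NULL`.
#' @param sample Sample label, `"tumor"` or `"normal"`.
#' @param repeat_mapq0_frac Probability that a mate overlapping a repeat
#'   region is assigned mapq 0.
#' @param repeat_anom_rate Rate of clustered anomalous noise pairs per
#'   repeat region, as a fraction of the region's expected pair count.
#' @return data.frame with columns `pair_id, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, mapq_min, sample`, mates in canonical order,
#'   positions 1-based leftmost mapped base.
#' @examples
#' g <- build_toy_genome(seed = 1)
#' pairs <- simulate_pairs(as_donor(g), insert_model(), coverage = 2, seed = 1)
#' head(pairs)
#' @export
simulate_pairs <- function(donor, model = insert_model(), coverage,
                           seed = NULL, sample = "tumor",
                           repeat_mapq0_frac = 0.5, repeat_anom_rate = 0.3) {
  stopifnot(inherits(donor, "donor_genome"), coverage > 0)
  L <- model$read_length
  mu <- model$mean_insert; sigma <- model$sd_insert
  max_insert <- mu + 6 * sigma
  lens <- donor$lengths
  if (any(lens < max_insert))
    stop("donor chromosome(s) shorter than the maximum insert (",
         max_insert, " bp): ", paste(names(lens)[lens < max_insert],
                                     collapse = ", "))

  # global linear donor coordinate space: chromosomes laid end to end,
  # segments of each walk laid out in walk order
  segs <- do.call(rbind, donor$walks)
  seg_chrom_donor <- rep(names(donor$walks),
                         vapply(donor$walks, nrow, integer(1)))
  seg_len <- segs$end - segs$start
  seg_gstart <- cumsum(c(0, seg_len[-length(seg_len)]))
  chrom_offset <- stats::setNames(
    cumsum(c(0, unname(lens[-length(lens)]))), names(lens))

  n <- round(coverage * sum(lens) / (2 * L))

  empty <- data.frame(pair_id = character(0), chrom1 = character(0),
                      pos1 = integer(0), strand1 = character(0),
                      chrom2 = character(0), pos2 = integer(0),
                      strand2 = character(0), mapq_min = integer(0),
                      sample = character(0), stringsAsFactors = FALSE)

  rr <- donor$genome$repeat_regions

  pairs <- with_seed(seed, {
    draw <- function(m) {
      if (m == 0) return(NULL)
      ci <- sample.int(length(lens), m, replace = TRUE, prob = lens / sum(lens))
      ins <- round(stats::rnorm(m, mu, sigma))
      bad <- ins <= 2 * L | ins > max_insert
      while (any(bad)) {  # truncated normal: resample on violation
        ins[bad] <- round(stats::rnorm(sum(bad), mu, sigma))
        bad <- ins <= 2 * L | ins > max_insert
      }
      st <- floor(stats::runif(m) * (lens[ci] - ins + 1))
      g1 <- chrom_offset[names(lens)[ci]] + st          # mate 1 donor start
      g2 <- g1 + ins - L                                # mate 2 donor start
      i1 <- findInterval(g1, seg_gstart)
      i2 <- findInterval(g2, seg_gstart)
      ok <- (g1 + L <= seg_gstart[i1] + seg_len[i1]) &
            (g2 + L <= seg_gstart[i2] + seg_len[i2])
      data.frame(g1 = unname(g1), g2 = unname(g2), i1 = i1, i2 = i2,
                 ok = ok)
    }
    d <- draw(n)
    if (!is.null(d)) {
      tries <- 0L
      while (any(!d$ok)) {  # resample boundary-crossing fragments
        tries <- tries + 1L
        if (tries > 100L) stop("could not place fragments off segment boundaries")
        d[!d$ok, ] <- draw(sum(!d$ok))
      }
    }

    project <- function(g, i, donor_strand) {
      off <- g - seg_gstart[i]
      fwd <- segs$orient[i] == "+"
      pos0 <- ifelse(fwd, segs$start[i] + off, segs$end[i] - off - L)
      strand <- ifelse(fwd, donor_strand,
                       ifelse(donor_strand == "+", "-", "+"))
      list(chrom = segs$chrom[i], pos = as.integer(pos0) + 1L, strand = strand)
    }

    main <- if (is.null(d) || nrow(d) == 0) empty else {
      m1 <- project(d$g1, d$i1, "+")
      m2 <- project(d$g2, d$i2, "-")
      mapq1 <- rep(60L, nrow(d)); mapq2 <- rep(60L, nrow(d))
      if (!is.null(rr) && repeat_mapq0_frac > 0) {
        in_rr <- function(chrom, pos) {
          hit <- rep(FALSE, length(chrom))
          for (k in seq_len(nrow(rr))) {
            hit <- hit | (chrom == rr$chrom[k] & pos > rr$start[k] &
                            pos <= rr$end[k])
          }
          hit
        }
        h1 <- in_rr(m1$chrom, m1$pos); h2 <- in_rr(m2$chrom, m2$pos)
        mapq1[h1 & stats::runif(nrow(d)) < repeat_mapq0_frac] <- 0L
        mapq2[h2 & stats::runif(nrow(d)) < repeat_mapq0_frac] <- 0L
      }
      data.frame(pair_id = sprintf("frag%07d", seq_len(nrow(d))),
                 chrom1 = m1$chrom, pos1 = m1$pos, strand1 = m1$strand,
                 chrom2 = m2$chrom, pos2 = m2$pos, strand2 = m2$strand,
                 mapq_min = pmin(mapq1, mapq2),
                 sample = sample, stringsAsFactors = FALSE)
    }

    noise <- NULL
    if (!is.null(rr) && nrow(rr) > 0 && repeat_anom_rate > 0) {
      nr <- nrow(rr)
      partner <- if (nr == 1) 1L else c(seq_len(nr)[-1], 1L)
      rows <- vector("list", nr)
      for (k in seq_len(nr)) {
        width_k <- rr$end[k] - rr$start[k]
        n_noise <- round(repeat_anom_rate * coverage * width_k / (2 * L))
        if (n_noise == 0) next
        p <- partner[k]
        pk <- if (p == k && nr == 1) {
          # single region: mirror it across its chromosome
          clen <- donor$genome$chrom_lengths[[rr$chrom[k]]]
          data.frame(chrom = rr$chrom[k], start = clen - rr$end[k],
                     end = clen - rr$start[k])
        } else rr[p, , drop = FALSE]
        pos_a <- as.integer(floor(stats::runif(n_noise, rr$start[k],
                                               rr$end[k] - L))) + 1L
        pos_b <- as.integer(floor(stats::runif(n_noise, pk$start,
                                               pk$end - L))) + 1L
        rows[[k]] <- data.frame(
          pair_id = sprintf("noise%02d_%05d", k, seq_len(n_noise)),
          chrom1 = rr$chrom[k], pos1 = pos_a,
          strand1 = sample(c("+", "-"), n_noise, replace = TRUE),
          chrom2 = pk$chrom[1], pos2 = pos_b,
          strand2 = sample(c("+", "-"), n_noise, replace = TRUE),
          mapq_min = 60L, sample = sample, stringsAsFactors = FALSE)
      }
      noise <- do.call(rbind, rows[lengths(rows) > 0])
    }
    rbind(main, noise)
  })

  canonicalize_pairs(pairs, chrom_levels = NULL)
}
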