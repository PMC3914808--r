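#' Canonicalize mate order in a read-pair table
#'
#' Stores each pair with `(chrom1, pos1) <= (chrom2, pos2)` under natural
#' chromosome ordering (or explicit `chrom_levels`), swapping mates --
#' and their strands with them -- where needed. Classification operates
#' on canonical pairs only.
#'
#' @param pairs Read-pair data.frame (`pair_id, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, mapq_min, sample`).
#' @param chrom_levels Optional chromosome ordering.
#' @return The pair table in canonical order.
#' @export
canonicalize_pairs <- function(pairs, chrom_levels = NULL) {
  stopifnot_cols(pairs, c("chrom1", "pos1", "strand1",
                          "chrom2", "pos2", "strand2"), "pairs")
  if (nrow(pairs) == 0) return(pairs)
  n <- nrow(pairs)
  r <- chrom_rank(c(pairs$chrom1, pairs$chrom2), chrom_levels)
  r1 <- r[seq_len(n)]; r2 <- r[n + seq_len(n)]
  swap <- r1 > r2 | (r1 == r2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, c("chrom1", "pos1", "strand1")]
    pairs[swap, c("chrom1", "pos1", "strand1")] <-
      pairs[swap, c("chrom2", "pos2", "strand2")]
    pairs[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  pairs
}

is_canonical <- function(pairs, chrom_levels = NULL) {
  if (nrow(pairs) == 0) return(TRUE)
  n <- nrow(pairs)
  r <- chrom_rank(c(pairs$chrom1, pairs$chrom2), chrom_levels)
  r1 <- r[seq_len(n)]; r2 <- r[n + seq_len(n)]
  all(r1 < r2 | (r1 == r2 & pairs$pos1 <= pairs$pos2))
}

#' Classify read pairs as concordant or anomalous
#'
#' Assigns each pair an orientation class and anomaly reason. With mates
#' in canonical order, the strand convention is: `(+,-)` mates point
#' toward each other (facing; concordant when the outer span lies within
#' the insert model's concordance window, inclusive); `(-,+)` point away
#' from each other (opposing); `(+,+)` / `(-,-)` point the same way.
#' Interchromosomal pairs are always anomalous, with orientation read off
#' the same strand table. The outer span is `pos2 - pos1 + read_length`.
#'
#' @param pairs Canonical read-pair table (see [canonicalize_pairs()]).
#' @param model An [insert_model()].
#' @param chrom_levels Optional chromosome ordering used for the
#'   canonical-order check.
#' @return `pairs` with columns `orientation` (`CONCORDANT, FACING,
#'   OPPOSING, SAME_FORWARD, SAME_REVERSE`), `is_anomalous` and `reason`
#'   (`none, interchromosomal, oversized_span, orientation`) appended.
#' @examples
#' p <- data.frame(pair_id = "p1", chrom1 = "chr12", pos1 = 1000,
#'                 strand1 = "+", chrom2 = "chr12", pos2 = 1399,
#'                 strand2 = "-", mapq_min = 60, sample = "tumor")
#' classify_pairs(p, insert_model())$orientation  # span 500 -> CONCORDANT
#' @export
classify_pairs <- function(pairs, model = insert_model(), chrom_levels = NULL) {
  stopifnot_cols(pairs, c("chrom1", "pos1", "strand1",
                          "chrom2", "pos2", "strand2"), "pairs")
  if (!is_canonical(pairs, chrom_levels))
    stop("pairs must be in canonical mate order; see canonicalize_pairs()")
  n <- nrow(pairs)
  orientation <- character(n); reason <- character(n)
  if (n) {
    key <- paste0(pairs$strand1, pairs$strand2)
    ori <- c("+-" = "FACING", "-+" = "OPPOSING",
             "++" = "SAME_FORWARD", "--" = "SAME_REVERSE")[key]
    if (anyNA(ori)) stop("invalid strand value(s); expected '+' or '-'")
    inter <- pairs$chrom1 != pairs$chrom2
    span <- pairs$pos2 - pairs$pos1 + model$read_length
    rng <- concordant_range(model)
    conc <- !inter & key == "+-" & span >= rng[1] & span <= rng[2]
    orientation <- unname(ori)
    orientation[conc] <- "CONCORDANT"
    reason <- rep("orientation", n)
    reason[conc] <- "none"
    reason[!inter & key == "+-" & !conc] <- "oversized_span"
    reason[inter] <- "interchromosomal"
  }
  pairs$orientation <- orientation
  pairs$is_anomalous <- orientation != "CONCORDANT"
  pairs$reason <- reason
  pairs
}

#' Report-style orientation labels
#'
#' Maps orientation classes onto the labels used in fusion reports:
#' `Facing`, `Opposing`, `Same direction – forward`,
#' `Same direction – reverse`. Only anomalous orientations have
#' labels; `CONCORDANT` input is an error.
#'
#' @param orientation Character vector of orientation classes.
#' @return Character vector of labels.
#' @export
orientation_label <- function(orientation) {
  orientation <- as.character(orientation)
  if (any(orientation == "CONCORDANT"))
    stop("concordant pairs have no orientation label")
  lab <- c(FACING = "Facing", OPPOSING = "Opposing",
           SAME_FORWARD = "Same direction – forward",
           SAME_REVERSE = "Same direction – reverse")[orientation]
  if (anyNA(lab)) stop("unknown orientation class")
  unname(lab)
}

# inverse mapping, for fixture tables carrying printed labels
orientation_from_label <- function(label) {
  key <- gsub("–|—", "-", tolower(trimws(label)))
  key <- gsub("\\s+", " ", key)
  out <- c("facing" = "FACING", "opposing" = "OPPOSING",
           "same direction - forward" = "SAME_FORWARD",
           "same direction - reverse" = "SAME_REVERSE")[key]
  if (anyNA(out)) stop("unrecognized orientation label: ",
                       paste(unique(label[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Per-window read-pair summaries
#'
#' Counts, per genomic window, the mates landing there (`n_total`), the
#' mates of anomalous pairs (`n_anomalous`) and poorly mapped mates
#' (`n_poor_mapq`, pairs with `mapq_min` below the threshold). Each mate
#' contributes to exactly one window. Computed on the normal sample this
#' is the input to [build_blacklist()].
#'
#' @param pairs Read-pair table.
#' @param grid A [make_windows()] grid covering all chromosomes present.
#' @param model An [insert_model()] used for classification.
#' @param mapq_threshold Phred mapq below which a mate counts as poorly
#'   mapped.
#' @return data.frame `wid, chrom, start, end, n_total, n_anomalous,
#'   n_poor_mapq` (one row per window).
#' @export
summarize_windows <- function(pairs, grid, model = insert_model(),
                              mapq_threshold = 20) {
  stopifnot(inherits(grid, "window_grid"))
  cp <- if ("orientation" %in% names(pairs)) pairs else
    classify_pairs(canonicalize_pairs(pairs), model)
  out <- grid$windows
  nw <- nrow(out)
  tot <- integer(nw); anom <- integer(nw); poor <- integer(nw)
  if (nrow(cp)) {
    w1 <- window_ids(grid, cp$chrom1, cp$pos1)
    w2 <- window_ids(grid, cp$chrom2, cp$pos2)
    add <- function(v, idx) v + tabulate(idx, nw)
    tot <- add(add(tot, w1), w2)
    anom_idx <- c(w1[cp$is_anomalous], w2[cp$is_anomalous])
    anom <- add(anom, anom_idx)
    poor_idx <- c(w1[cp$mapq_min < mapq_threshold],
                  w2[cp$mapq_min < mapq_threshold])
    poor <- add(poor, poor_idx)
  }
  out$n_total <- tot
  out$n_anomalous <- anom
  out$n_poor_mapq <- poor
  out
}
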