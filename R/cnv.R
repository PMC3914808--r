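#' Copy-number concordance parameters
#'
#' @param tolerance Maximum distance in bases for matching a copy-number
#'   segment boundary to a fusion breakpoint.
#' @param gain_threshold Mean log2 ratio at or above which a segment is a
#'   gain (default ~= log2(3/2), a single-copy gain on a diploid
#'   background).
#' @param loss_threshold Mean log2 ratio at or below which a segment is a
#'   loss.
#' @return List of class `concordance_params`.
#' @export
concordance_params <- function(tolerance = 10000, gain_threshold = 0.58,
                               loss_threshold = -0.58) {
  stopifnot(tolerance >= 0, gain_threshold > loss_threshold)
  structure(list(tolerance = tolerance, gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold),
            class = "concordance_params")
}

# pooled two-sample t statistic for every admissible split of x;
# returns the accepted split index (last probe of the left half) or 0
best_split <- function(x, min_probes, crit) {
  n <- length(x)
  if (n < 2 * min_probes) return(0L)
  cs <- cumsum(x); css <- cumsum(x^2)
  i <- seq.int(min_probes, n - min_probes)
  n1 <- i; n2 <- n - i
  m1 <- cs[i] / n1; m2 <- (cs[n] - cs[i]) / n2
  ss1 <- css[i] - n1 * m1^2
  ss2 <- (css[n] - css[i]) - n2 * m2^2
  pooled <- (ss1 + ss2) / (n - 2)
  tt <- ifelse(pooled <= 1e-12,
               ifelse(abs(m1 - m2) > 1e-12, Inf, 0),
               abs(m1 - m2) / sqrt(pooled * (1 / n1 + 1 / n2)))
  k <- which.max(tt)  # leftmost maximum
  if (tt[k] > crit) i[k] else 0L
}

#' Segment aCGH log2 ratios by recursive binary segmentation
#'
#' Recursively splits each chromosome's ordered probe series at the
#' position maximizing the pooled two-sample t statistic, accepting a
#' split only when `|t|` exceeds the alpha-level critical value and both
#' halves retain at least `min_probes` probes. Ties break to the leftmost
#' maximum; the procedure is fully deterministic.
#'
#' @param probes data.frame `chrom, start, end, log2ratio`, sorted by
#'   position within chromosome.
#' @param min_probes Minimum probes per segment.
#' @param alpha Significance level of the split-acceptance test.
#' @return data.frame of class `cn_segments`: `chrom, start, end,
#'   mean_log2, n_probes` (state added by [call_states()]).
#' @examples
#' p <- data.frame(chrom = "chr1", start = 0:99 * 1000, end = 1:100 * 1000,
#'                 log2ratio = rep(c(0, 2), each = 50))
#' segment_probes(p)
#' @export
segment_probes <- function(probes, min_probes = 3, alpha = 1e-4) {
  stopifnot_cols(probes, c("chrom", "start", "end", "log2ratio"), "probes")
  if (any(!is.finite(probes$log2ratio))) stop("log2 ratios must be finite")
  out <- list()
  for (cn in unique(probes$chrom)) {
    p <- probes[probes$chrom == cn, , drop = FALSE]
    if (is.unsorted(p$start)) stop("probes must be sorted within ", cn)
    x <- p$log2ratio
    # iterative recursion over (lo, hi) probe index ranges
    stack <- list(c(1L, length(x)))
    bounds <- list()
    while (length(stack)) {
      rg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      lo <- rg[1]; hi <- rg[2]; nseg <- hi - lo + 1L
      crit <- if (nseg > 2) stats::qt(1 - alpha / 2, nseg - 2) else Inf
      sp <- if (nseg >= 2 * min_probes)
        best_split(x[lo:hi], min_probes, crit) else 0L
      if (sp == 0L) {
        bounds[[length(bounds) + 1L]] <- c(lo, hi)
      } else {
        # push right first so the left range is processed next (ordered output)
        stack[[length(stack) + 1L]] <- c(lo + sp, hi)
        stack[[length(stack) + 1L]] <- c(lo, lo + sp - 1L)
      }
    }
    bb <- do.call(rbind, bounds)
    bb <- bb[order(bb[, 1]), , drop = FALSE]
    out[[cn]] <- data.frame(
      chrom = cn,
      start = p$start[bb[, 1]], end = p$end[bb[, 2]],
      mean_log2 = vapply(seq_len(nrow(bb)),
                         function(i) mean(x[bb[i, 1]:bb[i, 2]]), numeric(1)),
      n_probes = bb[, 2] - bb[, 1] + 1L, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cn_segments", "data.frame")
  res
}

#' Call gain/loss/neutral states on segments
#'
#' @param segments [segment_probes()] output.
#' @param params [concordance_params()].
#' @return Segments with a `state` column (`gain`, `loss`, `neutral`).
#' @export
call_states <- function(segments, params = concordance_params()) {
  segments$state <- ifelse(segments$mean_log2 >= params$gain_threshold, "gain",
                    ifelse(segments$mean_log2 <= params$loss_threshold, "loss",
                           "neutral"))
  segments
}

#' Match copy-number boundaries to fusion breakpoints
#'
#' For each boundary of a gain/loss segment, reports any fusion
#' breakpoint within the matching tolerance; assignment is greedy by
#' increasing distance (ties toward the smaller coordinate) and each
#' fusion breakpoint is consumed by at most one boundary. Unmatched items
#' on both sides are reported symmetrically -- the desk version of
#' confirming amplification breakpoints against sequencing junctions.
#'
#' @param segments State-called segments ([call_states()]).
#' @param fusions Fusion candidates (data.frame with `chrom1,
#'   breakpoint1, chrom2, breakpoint2`) or a `fusion_calls` object.
#' @param params [concordance_params()].
#' @return List with `matched` (boundary/breakpoint pairs and distances),
#'   `unmatched_boundaries` and `unmatched_fusion_breakpoints`.
#' @export
match_breakpoints <- function(segments, fusions,
                              params = concordance_params()) {
  if (inherits(fusions, "fusion_calls")) fusions <- fusions$candidates
  seg <- segments[segments$state %in% c("gain", "loss"), , drop = FALSE]
  boundaries <- if (nrow(seg)) data.frame(
    chrom = rep(seg$chrom, 2),
    pos = c(seg$start, seg$end),
    side = rep(c("start", "end"), each = nrow(seg)),
    state = rep(seg$state, 2), stringsAsFactors = FALSE) else
    data.frame(chrom = character(0), pos = integer(0), side = character(0),
               state = character(0), stringsAsFactors = FALSE)
  fbp <- if (nrow(fusions)) data.frame(
    fusion = rep(seq_len(nrow(fusions)), 2),
    chrom = c(fusions$chrom1, fusions$chrom2),
    pos = c(fusions$breakpoint1, fusions$breakpoint2),
    stringsAsFactors = FALSE) else
    data.frame(fusion = integer(0), chrom = character(0), pos = integer(0))

  cand <- NULL
  if (nrow(boundaries) && nrow(fbp)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(boundaries)), function(b) {
      sel <- fbp$chrom == boundaries$chrom[b] &
        abs(fbp$pos - boundaries$pos[b]) <= params$tolerance
      if (!any(sel)) return(NULL)
      data.frame(b = b, f = which(sel),
                 dist = abs(fbp$pos[sel] - boundaries$pos[b]))
    }))
  }
  matched <- data.frame(chrom = character(0), boundary_pos = integer(0),
                        boundary_side = character(0), state = character(0),
                        fusion = integer(0), fusion_pos = integer(0),
                        distance = integer(0), stringsAsFactors = FALSE)
  used_b <- logical(nrow(boundaries)); used_f <- logical(nrow(fbp))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist, boundaries$pos[cand$b], fbp$pos[cand$f]), ,
                 drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      b <- cand$b[i]; f <- cand$f[i]
      if (used_b[b] || used_f[f]) next
      used_b[b] <- TRUE; used_f[f] <- TRUE
      matched[nrow(matched) + 1L, ] <- list(
        boundaries$chrom[b], boundaries$pos[b], boundaries$side[b],
        boundaries$state[b], fbp$fusion[f], fbp$pos[f], cand$dist[i])
    }
  }
  list(matched = matched,
       unmatched_boundaries = boundaries[!used_b, , drop = FALSE],
       unmatched_fusion_breakpoints = fbp[!used_f, , drop = FALSE])
}

#' @export
print.cn_segments <- function(x, ...) {
  cat(sprintf("Copy-number segments: %d segment(s) over %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if ("state" %in% names(x)) {
    tb <- table(x$state)
    cat("  states:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
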