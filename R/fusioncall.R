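#' Fusion-caller parameters
#'
#' Thresholds governing window blacklisting, link support and partner
#' prioritization. A window is blacklisted from the *normal* sample when
#' it holds at least `blacklist_min_reads` mates and its anomalous-mate
#' fraction reaches `blacklist_anom_frac` or its poorly-mapped fraction
#' reaches `blacklist_poor_frac`. Window links need `min_support`
#' anomalous pairs. The partner filter flags genes presenting with at
#' least `min_partners` distinct fusion partners -- the prioritization
#' used when amplified structures such as double minutes make
#' single-partner events hard to interpret.
#'
#' @param min_support Minimum anomalous pairs supporting a window link.
#' @param blacklist_anom_frac Anomalous-mate fraction triggering blacklisting.
#' @param blacklist_poor_frac Poorly-mapped-mate fraction triggering blacklisting.
#' @param blacklist_min_reads Minimum mates in a window before it can be
#'   blacklisted (evidence floor).
#' @param min_partners Distinct-partner count required by the partner filter.
#' @param mapq_threshold Minimum pair mapq for fusion evidence; also the
#'   poorly-mapped cutoff.
#' @return List of class `caller_params`.
#' @export
caller_params <- function(min_support = 3, blacklist_anom_frac = 0.2,
                          blacklist_poor_frac = 0.5, blacklist_min_reads = 10,
                          min_partners = 2, mapq_threshold = 20) {
  stopifnot(min_support >= 1,
            blacklist_anom_frac >= 0, blacklist_anom_frac <= 1,
            blacklist_poor_frac >= 0, blacklist_poor_frac <= 1)
  structure(list(min_support = min_support,
                 blacklist_anom_frac = blacklist_anom_frac,
                 blacklist_poor_frac = blacklist_poor_frac,
                 blacklist_min_reads = blacklist_min_reads,
                 min_partners = min_partners,
                 mapq_threshold = mapq_threshold),
            class = "caller_params")
}

#' Germline window blacklist
#'
#' Windows where the germline genome aligns with a high fraction of
#' anomalous or poorly mapped reads are ignored during fusion calling.
#'
#' @param normal_summary [summarize_windows()] output computed from the
#'   normal sample.
#' @param params [caller_params()].
#' @return Integer vector of blacklisted window ids.
#' @export
build_blacklist <- function(normal_summary, params = caller_params()) {
  stopifnot_cols(normal_summary,
                 c("wid", "n_total", "n_anomalous", "n_poor_mapq"),
                 "normal_summary")
  s <- normal_summary
  hit <- s$n_total >= params$blacklist_min_reads &
    (s$n_anomalous / s$n_total >= params$blacklist_anom_frac |
       s$n_poor_mapq / s$n_total >= params$blacklist_poor_frac)
  s$wid[hit]
}

#' Link windows by shared anomalous pairs
#'
#' The core sliding-window scan: every anomalous, well-mapped pair votes
#' for the (window, window) combination its mates land in; links touching
#' a blacklisted window or falling below the support floor are dropped.
#'
#' @param pairs Read-pair table (classified on the fly if needed).
#' @param grid [make_windows()] grid.
#' @param blacklist Integer window ids from [build_blacklist()].
#' @param model [insert_model()].
#' @param params [caller_params()].
#' @return data.frame of links: `window_a, window_b, support` and one
#'   `n_<orientation>` column per orientation class, in canonical
#'   (window_a <= window_b) order.
#' @export
link_windows <- function(pairs, grid, blacklist = integer(0),
                         model = insert_model(), params = caller_params()) {
  cp <- if ("orientation" %in% names(pairs)) pairs else
    classify_pairs(canonicalize_pairs(pairs), model)
  cp <- cp[cp$is_anomalous & cp$mapq_min >= params$mapq_threshold, ,
           drop = FALSE]
  ori_levels <- c("FACING", "OPPOSING", "SAME_FORWARD", "SAME_REVERSE")
  empty <- data.frame(window_a = integer(0), window_b = integer(0),
                      support = integer(0))
  for (o in ori_levels) empty[[paste0("n_", tolower(o))]] <- integer(0)
  if (nrow(cp) == 0) return(empty)
  w1 <- window_ids(grid, cp$chrom1, cp$pos1)
  w2 <- window_ids(grid, cp$chrom2, cp$pos2)
  wa <- pmin(w1, w2); wb <- pmax(w1, w2)
  keep <- !(wa %in% blacklist) & !(wb %in% blacklist)
  cp <- cp[keep, , drop = FALSE]; wa <- wa[keep]; wb <- wb[keep]
  if (length(wa) == 0) return(empty)
  key <- paste(wa, wb, sep = ":")
  agg <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  agg$window_a <- as.integer(sub(":.*", "", agg$key))
  agg$window_b <- as.integer(sub(".*:", "", agg$key))
  agg$support <- as.integer(table(key)[agg$key])
  for (o in ori_levels) {
    cnt <- table(key[cp$orientation == o])
    v <- as.integer(cnt[agg$key]); v[is.na(v)] <- 0L
    agg[[paste0("n_", tolower(o))]] <- v
  }
  agg <- agg[agg$support >= params$min_support, , drop = FALSE]
  agg <- agg[order(agg$window_a, agg$window_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg$key <- NULL
  agg
}

# gene with maximal overlap over a window; ties broken lexicographically;
# NA if no coding gene overlaps
gene_for_window <- function(grid, wid, genes) {
  win <- grid$windows[match(wid, grid$windows$wid), , drop = FALSE]
  coding <- genes[genes$is_coding, , drop = FALSE]
  vapply(seq_len(nrow(win)), function(i) {
    g <- coding[coding$chrom == win$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(NA_character_)
    ov <- pmin(g$end, win$end[i]) - pmax(g$start, win$start[i])
    g <- g[ov > 0, , drop = FALSE]; ov <- ov[ov > 0]
    if (!length(ov)) return(NA_character_)
    best <- ov == max(ov)
    sort(g$gene[best])[1]
  }, character(1))
}

#' Refine junction breakpoints from supporting mates
#'
#' The breakpoint on each side of a junction is taken as the innermost
#' supporting mate edge: the maximal 1-based end of forward mates, or the
#' minimal start of reverse mates, as dictated by the junction's
#' orientation class.
#'
#' @param supporting_pairs Canonical, classified pairs supporting one
#'   link.
#' @param orientation Orientation class of the junction.
#' @param read_length Mate length in bases.
#' @return Integer vector `c(breakpoint1, breakpoint2)` (1-based).
#' @export
refine_breakpoints <- function(supporting_pairs, orientation,
                               read_length = 101) {
  if (nrow(supporting_pairs) == 0)
    stop("breakpoint refinement requires at least one supporting pair")
  side_strands <- switch(orientation,
    FACING = c("+", "-"), OPPOSING = c("-", "+"),
    SAME_FORWARD = c("+", "+"), SAME_REVERSE = c("-", "-"),
    stop("unknown orientation class: ", orientation))
  edge <- function(pos, strand) {
    if (strand == "+") max(pos + read_length - 1L) else min(pos)
  }
  c(as.integer(edge(supporting_pairs$pos1, side_strands[1])),
    as.integer(edge(supporting_pairs$pos2, side_strands[2])))
}

#' Annotate window links as gene-fusion candidates
#'
#' A link becomes a candidate only if both of its windows overlap a
#' coding gene body (gene assigned by maximal overlap, ties broken
#' lexicographically) and the two genes differ. The candidate's
#' orientation is the modal orientation among its supporting pairs, and
#' its breakpoints come from [refine_breakpoints()] applied to the
#' modal-orientation supporters. Candidates sharing gene pair and
#' orientation (e.g. one junction whose straddling mates split across a
#' window boundary) are merged, summing support and keeping the
#' innermost breakpoints.
#'
#' @param links [link_windows()] output.
#' @param pairs The read-pair table the links were computed from.
#' @param genome `toy_genome` (or any list with a `genes` data.frame).
#' @param grid The window grid.
#' @param model [insert_model()].
#' @param params [caller_params()].
#' @return data.frame of fusion candidates: `gene1, gene2, chrom1,
#'   breakpoint1, chrom2, breakpoint2, orientation, orientation_label,
#'   support, kind, passes_partner_filter` (flag left `NA` until
#'   [partner_filter()]).
#' @export
annotate_fusions <- function(links, pairs, genome, grid,
                             model = insert_model(),
                             params = caller_params()) {
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      chrom1 = character(0), breakpoint1 = integer(0),
                      chrom2 = character(0), breakpoint2 = integer(0),
                      orientation = character(0),
                      orientation_label = character(0),
                      support = integer(0), kind = character(0),
                      passes_partner_filter = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(links) == 0) return(empty)
  genes <- if (inherits(genome, "toy_genome")) genome$genes else genome
  cp <- if ("orientation" %in% names(pairs)) pairs else
    classify_pairs(canonicalize_pairs(pairs), model)
  cp <- cp[cp$is_anomalous & cp$mapq_min >= params$mapq_threshold, ,
           drop = FALSE]
  pw1 <- window_ids(grid, cp$chrom1, cp$pos1)
  pw2 <- window_ids(grid, cp$chrom2, cp$pos2)
  pkey <- paste(pmin(pw1, pw2), pmax(pw1, pw2), sep = ":")

  ga <- gene_for_window(grid, links$window_a, genes)
  gb <- gene_for_window(grid, links$window_b, genes)
  ori_levels <- c("FACING", "OPPOSING", "SAME_FORWARD", "SAME_REVERSE")

  rows <- vector("list", nrow(links))
  for (i in seq_len(nrow(links))) {
    if (is.na(ga[i]) || is.na(gb[i]) || ga[i] == gb[i]) next
    sup <- cp[pkey == paste(links$window_a[i], links$window_b[i], sep = ":"), ,
              drop = FALSE]
    counts <- vapply(ori_levels, function(o) sum(sup$orientation == o),
                     integer(1))
    modal <- ori_levels[which.max(counts)]
    msup <- sup[sup$orientation == modal, , drop = FALSE]
    bp <- refine_breakpoints(msup, modal, model$read_length)
    rows[[i]] <- data.frame(
      gene1 = ga[i], gene2 = gb[i],
      chrom1 = msup$chrom1[1], breakpoint1 = bp[1],
      chrom2 = msup$chrom2[1], breakpoint2 = bp[2],
      orientation = modal, orientation_label = orientation_label(modal),
      support = nrow(msup),
      kind = if (msup$chrom1[1] == msup$chrom2[1]) "intrachromosomal"
             else "translocation",
      passes_partner_filter = NA, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[lengths(rows) > 0])
  if (is.null(out)) return(empty)

  # merge duplicate candidates (same gene pair + orientation)
  mk <- paste(out$gene1, out$gene2, out$orientation, sep = "|")
  merged <- lapply(unique(mk), function(k) {
    d <- out[mk == k, , drop = FALSE]
    if (nrow(d) > 1) {
      ss <- switch(d$orientation[1],
        FACING = c("+", "-"), OPPOSING = c("-", "+"),
        SAME_FORWARD = c("+", "+"), SAME_REVERSE = c("-", "-"))
      d$breakpoint1[1] <- if (ss[1] == "+") max(d$breakpoint1) else
        min(d$breakpoint1)
      d$breakpoint2[1] <- if (ss[2] == "+") max(d$breakpoint2) else
        min(d$breakpoint2)
      d$support[1] <- sum(d$support)
    }
    d[1, , drop = FALSE]
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$kind, chrom_rank(out$chrom1), out$breakpoint1), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag fusion candidates by distinct-partner count
#'
#' A candidate passes when at least one of its genes has at least
#' `min_partners` distinct partner genes across the candidate set.
#' Nothing is deleted: failing candidates are flagged, since validated
#' single-partner fusions do occur.
#'
#' @param candidates [annotate_fusions()] output (any data.frame with
#'   `gene1`/`gene2`).
#' @param params [caller_params()].
#' @return `candidates` with `passes_partner_filter` set.
#' @export
partner_filter <- function(candidates, params = caller_params()) {
  if (!nrow(candidates)) {
    candidates$passes_partner_filter <- logical(0)
    return(candidates)
  }
  n_partners <- partner_counts(candidates)
  candidates$passes_partner_filter <-
    n_partners[candidates$gene1] >= params$min_partners |
    n_partners[candidates$gene2] >= params$min_partners
  candidates
}

#' @rdname partner_filter
#' @export
partner_counts <- function(candidates) {
  genes <- unique(c(candidates$gene1, candidates$gene2))
  vapply(stats::setNames(genes, genes), function(g) {
    length(unique(c(candidates$gene2[candidates$gene1 == g],
                    candidates$gene1[candidates$gene2 == g])))
  }, integer(1))
}

#' Count fusion events touching a gene cluster
#'
#' Scans candidates for events with at least one partner gene inside a
#' cluster of interest (e.g. a genomic-instability hotspot such as the
#' NAV3/SYT1/PAWR cluster on 12q).
#'
#' @param candidates Fusion candidates (`gene1`/`gene2` columns), or a
#'   `fusion_calls` object.
#' @param cluster Non-empty character vector of gene names.
#' @return Named integer vector `c(n_in_cluster, n_total)`.
#' @export
hotspot_scan <- function(candidates, cluster) {
  if (inherits(candidates, "fusion_calls")) candidates <- candidates$candidates
  if (!length(cluster)) stop("cluster must be non-empty")
  stopifnot_cols(candidates, c("gene1", "gene2"), "candidates")
  hit <- candidates$gene1 %in% cluster | candidates$gene2 %in% cluster
  c(n_in_cluster = sum(hit), n_total = nrow(candidates))
}

#' Call gene fusions from tumor (and matched normal) read pairs
#'
#' End-to-end caller: summarizes the normal sample into a germline
#' blacklist, links tumor windows by anomalous pairs, annotates links
#' against the coding gene model, and applies the partner filter.
#'
#' @param tumor_pairs Tumor read-pair table.
#' @param normal_pairs Matched-normal read-pair table (or `NULL` to skip
#'   blacklisting).
#' @param genome `toy_genome` carrying the gene model.
#' @param model [insert_model()].
#' @param params [caller_params()].
#' @param grid Optional pre-built window grid.
#' @return Object of class `fusion_calls`: candidate table, window links,
#'   blacklist, grid and parameters.
#' @export
call_fusions <- function(tumor_pairs, normal_pairs = NULL, genome,
                         model = insert_model(), params = caller_params(),
                         grid = NULL) {
  grid <- grid %||% make_windows(genome$chrom_lengths, model)
  blacklist <- integer(0)
  if (!is.null(normal_pairs) && nrow(normal_pairs)) {
    ns <- summarize_windows(normal_pairs, grid, model, params$mapq_threshold)
    blacklist <- build_blacklist(ns, params)
  }
  links <- link_windows(tumor_pairs, grid, blacklist, model, params)
  cands <- annotate_fusions(links, tumor_pairs, genome, grid, model, params)
  cands <- partner_filter(cands, params)
  structure(list(candidates = cands, links = links, blacklist = blacklist,
                 grid = grid, model = model, params = params),
            class = "fusion_calls")
}

#' @export
print.fusion_calls <- function(x, ...) {
  cat(sprintf("Fusion calls: %d candidate(s) (%d passing partner filter), %d window link(s), %d blacklisted window(s)\n",
              nrow(x$candidates), sum(x$candidates$passes_partner_filter),
              nrow(x$links), length(x$blacklist)))
  if (nrow(x$candidates)) {
    for (k in c("intrachromosomal", "translocation")) {
      d <- x$candidates[x$candidates$kind == k, , drop = FALSE]
      if (!nrow(d)) next
      cat(if (k == "intrachromosomal") "Intrachromosomal rearrangements:\n"
          else "Translocations:\n")
      for (i in seq_len(nrow(d)))
        cat(sprintf("  %s:%d %s -- %s:%d %s  [%s, %d pairs%s]\n",
                    d$chrom1[i], d$breakpoint1[i], d$gene1[i],
                    d$chrom2[i], d$breakpoint2[i], d$gene2[i],
                    d$orientation_label[i], d$support[i],
                    if (isTRUE(d$passes_partner_filter[i])) ""
                    else ", single-partner"))
    }
  }
  invisible(x)
}

#' @export
summary.fusion_calls <- function(object, ...) {
  c(n_candidates = nrow(object$candidates),
    n_pass_partner = sum(object$candidates$passes_partner_filter),
    n_translocations = sum(object$candidates$kind == "translocation"),
    n_blacklisted_windows = length(object$blacklist))
}
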