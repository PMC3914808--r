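#' Rearrangement specifications
#'
#' Constructors for the rearrangement types that can be implanted into a
#' toy genome: deletion, tandem duplication, inversion, translocation and
#' tandem amplicon (the simulated analogue of the focally amplified
#' ring/double-minute structures seen in well-differentiated liposarcoma).
#' Intervals are 0-based half-open. Each constructor returns a one-row
#' data.frame; `rbind()` several together and pass them to
#' [implant_events()].
#'
#' For translocations, `strand_a`/`strand_b` are join strands: `"+"` keeps
#' the sequence left of the breakpoint in forward orientation, `"-"` the
#' sequence right of it in reverse orientation.
#'
#' @param chrom,chrom_a,chrom_b Chromosome names.
#' @param start,end Event interval (0-based half-open).
#' @param pos_a,pos_b Breakpoint positions (0-based cut coordinates).
#' @param strand_a,strand_b Join strands, `"+"` or `"-"`.
#' @param copies Number of copies of the amplified interval carried by the
#'   rearranged haplotype (>= 2).
#' @return One-row data.frame with columns
#'   `type, chrom_a, pos_a, strand_a, chrom_b, pos_b, strand_b, copies`.
#' @name rearrangements
NULL

sv_row <- function(type, ca, pa, sa, cb, pb, sb, copies = 1L) {
  data.frame(type = type, chrom_a = ca, pos_a = as.integer(pa), strand_a = sa,
             chrom_b = cb, pos_b = as.integer(pb), strand_b = sb,
             copies = as.integer(copies), stringsAsFactors = FALSE)
}

#' @rdname rearrangements
#' @export
sv_deletion <- function(chrom, start, end) {
  stopifnot(start < end)
  sv_row("deletion", chrom, start, "+", chrom, end, "+")
}

#' @rdname rearrangements
#' @export
sv_tandem_duplication <- function(chrom, start, end) {
  stopifnot(start < end)
  sv_row("tandem_duplication", chrom, start, "+", chrom, end, "+")
}

#' @rdname rearrangements
#' @export
sv_inversion <- function(chrom, start, end) {
  stopifnot(start < end)
  sv_row("inversion", chrom, start, "+", chrom, end, "-")
}

#' @rdname rearrangements
#' @export
sv_translocation <- function(chrom_a, pos_a, strand_a, chrom_b, pos_b, strand_b) {
  stopifnot(strand_a %in% c("+", "-"), strand_b %in% c("+", "-"))
  sv_row("translocation", chrom_a, pos_a, strand_a, chrom_b, pos_b, strand_b)
}

#' @rdname rearrangements
#' @export
sv_amplicon <- function(chrom, start, end, copies = 8) {
  stopifnot(start < end)
  if (copies < 2) stop("amplicon_ring requires copies >= 2")
  sv_row("amplicon_ring", chrom, start, "+", chrom, end, "+", copies)
}

# orientation implied by the reference strands of a junction-straddling
# pair once its mates are in canonical order
strand_pair_orientation <- function(s1, s2) {
  key <- paste0(s1, s2)
  c("+-" = "FACING", "-+" = "OPPOSING",
    "++" = "SAME_FORWARD", "--" = "SAME_REVERSE")[key]
}

#' Implant rearrangements into a toy genome
#'
#' Builds a rearranged (donor) genome as a walk of oriented reference
#' segments, together with a truth set enumerating every novel adjacency
#' and the copy-number consequences of the implanted events. The truth
#' set is the ground truth against which fusion calls and copy-number
#' segments are scored.
#'
#' Intrachromosomal events on the same chromosome must not overlap;
#' translocation breakpoints may not fall inside another event's interval.
#' Translocations are modeled as unbalanced: a derivative chromosome is
#' appended and the participating chromosomes are retained intact, so the
#' donor carries exactly one novel adjacency per translocation.
#'
#' Expected junction orientations: deletion `FACING`, tandem duplication
#' and amplicon `OPPOSING`, inversion `SAME_FORWARD` + `SAME_REVERSE`,
#' translocation per join strands. Junction coordinates record the cut
#' position on each side (printed as-is in reports, i.e. the 1-based index
#' of the last base left of the cut).
#'
#' @param genome A [build_toy_genome()] result.
#' @param specs data.frame of rearrangement specs (see [rearrangements]),
#'   or `NULL` for an unrearranged donor.
#' @return A list with `donor` (class `donor_genome`: named list of
#'   segment walks plus donor chromosome lengths) and `truth` (class
#'   `truth_set`: `junctions` and `copy_number` data.frames).
#' @examples
#' g <- build_toy_genome(seed = 1)
#' ev <- rbind(sv_deletion("chr1", 10000, 20000),
#'             sv_tandem_duplication("chr1", 30000, 40000))
#' res <- implant_events(g, ev)
#' res$truth$junctions
#' @export
implant_events <- function(genome, specs = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  lens <- genome$chrom_lengths
  seg <- function(chrom, start, end, orient = "+")
    data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
               orient = orient, stringsAsFactors = FALSE)
  walks <- lapply(genome$chrom_names, function(cn) seg(cn, 0L, lens[[cn]]))
  names(walks) <- genome$chrom_names

  junctions <- data.frame(event_id = character(0), chrom_a = character(0),
                          pos_a = integer(0), chrom_b = character(0),
                          pos_b = integer(0), orientation = character(0),
                          stringsAsFactors = FALSE)
  cn <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   total_copies = integer(0), stringsAsFactors = FALSE)

  if (!is.null(specs) && nrow(specs)) {
    stopifnot_cols(specs, c("type", "chrom_a", "pos_a", "strand_a",
                            "chrom_b", "pos_b", "strand_b", "copies"), "specs")
    specs$event_id <- sprintf("ev%02d", seq_len(nrow(specs)))

    check_pos <- function(chrom, pos) {
      if (!(chrom %in% names(lens))) stop("unknown chromosome: ", chrom)
      if (pos <= 0 || pos >= lens[[chrom]])
        stop("breakpoint ", chrom, ":", pos, " outside chromosome bounds")
    }
    for (i in seq_len(nrow(specs))) {
      check_pos(specs$chrom_a[i], specs$pos_a[i])
      check_pos(specs$chrom_b[i], specs$pos_b[i])
    }

    intra <- specs[specs$type != "translocation", , drop = FALSE]
    # no breakpoint may fall strictly inside another event's interval
    all_bp <- data.frame(chrom = c(specs$chrom_a, specs$chrom_b),
                         pos = c(specs$pos_a, specs$pos_b),
                         id = rep(specs$event_id, 2))
    if (nrow(intra)) {
      for (i in seq_len(nrow(intra))) {
        inside <- all_bp$chrom == intra$chrom_a[i] &
          all_bp$pos > intra$pos_a[i] & all_bp$pos < intra$pos_b[i] &
          all_bp$id != intra$event_id[i]
        if (any(inside))
          stop("breakpoint of ", paste(unique(all_bp$id[inside]), collapse = ","),
               " falls inside the interval of ", intra$event_id[i])
      }
    }

    add_junction <- function(id, ca, pa, cb, pb, orientation) {
      junctions[nrow(junctions) + 1L, ] <<-
        list(id, ca, as.integer(pa), cb, as.integer(pb), orientation)
    }

    # intrachromosomal events: rebuild each chromosome walk left-to-right
    for (cname in unique(intra$chrom_a)) {
      ev <- intra[intra$chrom_a == cname, , drop = FALSE]
      ev <- ev[order(ev$pos_a), , drop = FALSE]
      if (any(ev$pos_b[-nrow(ev)] > ev$pos_a[-1]))
        stop("overlapping events on ", cname)
      parts <- list(); cursor <- 0L
      for (i in seq_len(nrow(ev))) {
        a <- ev$pos_a[i]; b <- ev$pos_b[i]; id <- ev$event_id[i]
        switch(ev$type[i],
          deletion = {
            parts[[length(parts) + 1L]] <- seg(cname, cursor, a)
            cursor <- b
            add_junction(id, cname, a, cname, b, "FACING")
            cn[nrow(cn) + 1L, ] <- list(cname, a, b, 1L)
          },
          tandem_duplication = {
            parts[[length(parts) + 1L]] <- seg(cname, cursor, b)
            cursor <- a
            add_junction(id, cname, b, cname, a, "OPPOSING")
            cn[nrow(cn) + 1L, ] <- list(cname, a, b, 3L)
          },
          amplicon_ring = {
            parts[[length(parts) + 1L]] <- seg(cname, cursor, b)
            for (k in seq_len(ev$copies[i] - 1L))
              parts[[length(parts) + 1L]] <- seg(cname, a, b)
            cursor <- b
            add_junction(id, cname, b, cname, a, "OPPOSING")
            cn[nrow(cn) + 1L, ] <- list(cname, a, b, ev$copies[i] + 1L)
          },
          inversion = {
            parts[[length(parts) + 1L]] <- seg(cname, cursor, a)
            parts[[length(parts) + 1L]] <- seg(cname, a, b, "-")
            cursor <- b
            add_junction(id, cname, a, cname, b, "SAME_FORWARD")
            add_junction(id, cname, a, cname, b, "SAME_REVERSE")
          },
          stop("unknown event type: ", ev$type[i]))
      }
      parts[[length(parts) + 1L]] <- seg(cname, cursor, lens[[cname]])
      w <- do.call(rbind, parts)
      walks[[cname]] <- w[w$end > w$start, , drop = FALSE]
    }

    # translocations: append unbalanced derivative chromosomes
    tra <- specs[specs$type == "translocation", , drop = FALSE]
    for (i in seq_len(nrow(tra))) {
      id <- tra$event_id[i]
      ca <- tra$chrom_a[i]; pa <- tra$pos_a[i]; sa <- tra$strand_a[i]
      cb <- tra$chrom_b[i]; pb <- tra$pos_b[i]; sb <- tra$strand_b[i]
      side_a <- if (sa == "+") seg(ca, 0L, pa) else seg(ca, pa, lens[[ca]], "-")
      side_b <- if (sb == "+") seg(cb, pb, lens[[cb]]) else seg(cb, 0L, pb, "-")
      walks[[paste0("der_", id)]] <- rbind(side_a, side_b)
      # reference strand shown by a junction-straddling mate on each side
      obs_a <- sa
      obs_b <- if (sb == "+") "-" else "+"
      # canonical mate order before reading the orientation class
      if (chrom_rank(ca, genome$chrom_names)[1] >
          chrom_rank(cb, genome$chrom_names)[1] ||
          (ca == cb && pa > pb)) {
        ori <- strand_pair_orientation(obs_b, obs_a)
      } else {
        ori <- strand_pair_orientation(obs_a, obs_b)
      }
      add_junction(id, ca, pa, cb, pb, unname(ori))
    }
  }

  donor_lengths <- vapply(walks, function(w) sum(w$end - w$start), numeric(1))
  donor <- structure(list(walks = walks, lengths = donor_lengths,
                          genome = genome),
                     class = "donor_genome")
  truth <- structure(list(junctions = junctions, copy_number = cn,
                          somatic_variants = NULL, ploidy_truth = NULL),
                     class = "truth_set")
  list(donor = donor, truth = truth)
}

#' @rdname implant_events
#' @export
as_donor <- function(genome) implant_events(genome, NULL)$donor

#' @export
print.donor_genome <- function(x, ...) {
  cat(sprintf("Donor genome: %d chromosome(s), %s bp total\n",
              length(x$walks),
              format(sum(x$lengths), big.mark = ",")))
  nseg <- vapply(x$walks, nrow, integer(1))
  rearranged <- names(x$walks)[nseg > 1]
  if (length(rearranged))
    cat("  rearranged walks:", paste(rearranged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("Truth set: %d junction(s), %d copy-number interval(s)\n",
              nrow(x$junctions), nrow(x$copy_number)))
  invisible(x)
}
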