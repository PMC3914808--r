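#' Tile chromosomes into fixed windows
#'
#' Window size defaults to `round(mean_insert + 3 * sd_insert)` -- wide
#' enough that the mates of one anomalous fragment rarely split across
#' windows -- giving 650 bp under the default library model. Windows are
#' 0-based half-open and tile each chromosome exactly; the last window of
#' a chromosome may be short.
#'
#' @param chrom_lengths Named vector of chromosome lengths, or a
#'   `toy_genome`.
#' @param model An [insert_model()] (used for the default window size).
#' @param window_size Optional explicit window size in bases.
#' @return An object of class `window_grid` with the window table
#'   (`wid, chrom, start, end`) and the window size.
#' @examples
#' make_windows(c(chrA = 1300), insert_model())$windows  # two 650 bp windows
#' @export
make_windows <- function(chrom_lengths, model = insert_model(),
                         window_size = NULL) {
  if (inherits(chrom_lengths, "toy_genome"))
    chrom_lengths <- chrom_lengths$chrom_lengths
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  w <- as.integer(window_size %||%
                    round(model$mean_insert + 3 * model$sd_insert))
  if (w <= 0) stop("window size must be positive")
  rows <- lapply(names(chrom_lengths), function(cn) {
    len <- as.integer(chrom_lengths[[cn]])
    starts <- seq.int(0L, len - 1L, by = w)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + w, len), stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, rows)
  windows$wid <- seq_len(nrow(windows))
  windows <- windows[, c("wid", "chrom", "start", "end")]
  n_per <- vapply(rows, nrow, integer(1))
  first_wid <- stats::setNames(cumsum(c(1L, n_per[-length(n_per)])),
                               names(chrom_lengths))
  structure(list(windows = windows, window_size = w,
                 chrom_lengths = chrom_lengths, first_wid = first_wid,
                 n_windows = stats::setNames(n_per, names(chrom_lengths))),
            class = "window_grid")
}

#' Window id containing each position
#'
#' @param grid A `window_grid`.
#' @param chrom,pos Parallel vectors; `pos` is 1-based.
#' @return Integer window ids.
#' @export
window_ids <- function(grid, chrom, pos) {
  stopifnot(inherits(grid, "window_grid"))
  chrom <- as.character(chrom)
  unknown <- setdiff(unique(chrom), names(grid$chrom_lengths))
  if (length(unknown))
    stop("chromosome(s) absent from window grid: ",
         paste(unknown, collapse = ", "))
  idx <- (as.integer(pos) - 1L) %/% grid$window_size
  idx <- pmin(idx, grid$n_windows[chrom] - 1L)  # clamp into the short tail
  if (any(pos < 1L)) stop("positions must be >= 1")
  unname(grid$first_wid[chrom] + idx)
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("Window grid: %d windows of %d bp over %d chromosome(s)\n",
              nrow(x$windows), x$window_size, length(x$chrom_lengths)))
  invisible(x)
}
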