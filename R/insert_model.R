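#' Paired-end insert-size model
#'
#' Describes the sequencing library's fragment geometry: mean and standard
#' deviation of the (outer) insert size and the read length. A pair on the
#' same chromosome in forward/reverse ("facing") orientation is considered
#' concordant when its outer span lies within `mean_insert +/-
#' concordance_k * sd_insert` (inclusive); everything else is anomalous.
#' Defaults reflect a ~500 bp size-selected 2x101 bp library.
#'
#' @param mean_insert Mean outer insert size in bases.
#' @param sd_insert Standard deviation of the insert size in bases.
#' @param concordance_k Half-width of the concordance window, in standard
#'   deviations.
#' @param read_length Length of each mate in bases.
#' @return An object of class `insert_model`.
#' @examples
#' m <- insert_model()
#' concordant_range(m) # 350..650 by default
#' @export
insert_model <- function(mean_insert = 500, sd_insert = 50,
                         concordance_k = 3, read_length = 101) {
  if (!(mean_insert > 2 * read_length))
    stop("mean_insert must exceed twice the read length")
  if (sd_insert <= 0) stop("sd_insert must be positive")
  if (concordance_k <= 0) stop("concordance_k must be positive")
  structure(
    list(mean_insert = mean_insert, sd_insert = sd_insert,
         concordance_k = concordance_k, read_length = read_length),
    class = "insert_model")
}

#' @rdname insert_model
#' @param model An `insert_model`.
#' @export
concordant_range <- function(model) {
  c(model$mean_insert - model$concordance_k * model$sd_insert,
    model$mean_insert + model$concordance_k * model$sd_insert)
}

#' @export
print.insert_model <- function(x, ...) {
  rng <- concordant_range(x)
  cat(sprintf(
    "Insert-size model: %g +/- %g bp (2x%g bp reads); concordant span [%g, %g]\n",
    x$mean_insert, x$sd_insert, x$read_length, rng[1], rng[2]))
  invisible(x)
}
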