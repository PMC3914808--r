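# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Natural chromosome ordering: explicit levels win; otherwise "chr"-stripped
# numeric order with non-numeric names (X, Y, der1, ...) sorted after,
# alphabetically.
chrom_rank <- function(chrom, levels = NULL) {
  chrom <- as.character(chrom)
  if (!is.null(levels)) {
    r <- match(chrom, levels)
    if (anyNA(r)) stop("chromosome(s) not in supplied levels: ",
                       paste(unique(chrom[is.na(r)]), collapse = ", "))
    return(r)
  }
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  u <- unique(chrom)
  u_num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  ord <- order(is.na(u_num), u_num, u)
  match(chrom, u[ord])
}

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

# deterministic sub-seed derivation, kept well below .Machine$integer.max
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483647L)
}
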