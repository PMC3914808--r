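#' Fit Gaussian peaks to a DNA-content histogram
#'
#' Expectation-maximization fit of an `n_peaks`-component Gaussian
#' mixture to binned fluorescence counts, seeded from the `n_peaks`
#' largest local maxima of the (lightly smoothed) histogram. EM runs
#' until the log-likelihood change drops below `tol` or `max_iter`
#' iterations; with fixed inputs the fit is fully deterministic (the
#' `seed` argument is accepted for interface symmetry but the estimator
#' itself draws no random numbers).
#'
#' @param hist A `dna_histogram` or data.frame with `channel`/`count`.
#' @param n_peaks Number of peaks to fit (2 or 3: G0/G1 peaks with or
#'   without an aneuploid G2/M component).
#' @param reference_channel_hint Optional approximate channel of the
#'   diploid reference peak, used downstream by [estimate_ploidy()].
#' @param seed Unused; accepted for interface symmetry.
#' @param max_iter,tol EM stopping rule.
#' @return Object of class `ploidy_fit`: peak `means`, `sds`, `weights`
#'   (summing to 1), log-likelihood, iteration count and the input
#'   histogram.
#' @examples
#' h <- simulate_histogram(seed = 1)
#' fit <- fit_dna_content(h, n_peaks = 3)
#' fit
#' @export
fit_dna_content <- function(hist, n_peaks = 3, reference_channel_hint = NULL,
                            seed = NULL, max_iter = 500, tol = 1e-8) {
  if (inherits(hist, "dna_histogram")) {
    channel <- hist$channel; count <- hist$count
  } else {
    stopifnot_cols(hist, c("channel", "count"), "hist")
    channel <- hist$channel; count <- hist$count
  }
  if (!(n_peaks %in% 2:3)) stop("n_peaks must be 2 or 3")
  if (sum(count > 0) < 10 * n_peaks)
    stop("histogram too sparse: need at least ", 10 * n_peaks,
         " nonzero bins")

  # peak seeding: running-mean smooth, then strict local maxima above a
  # small height floor, de-duplicated within half a smoothing window
  sm <- stats::filter(count, rep(1 / 7, 7), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  floor_h <- 0.005 * max(sm)
  n <- length(sm)
  is_max <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 5); hi <- min(n, i + 5)
    win <- sm[lo:hi]
    # window maximum, taking the leftmost channel of any plateau
    sm[i] >= floor_h && sm[i] == max(win) &&
      i == lo + which.max(win == max(win)) - 1L
  }, logical(1))
  peaks_idx <- which(is_max)
  # merge maxima closer than 10 channels, keeping the taller
  if (length(peaks_idx) > 1) {
    keep <- rep(TRUE, length(peaks_idx))
    for (i in seq_along(peaks_idx)[-1]) {
      j <- max(which(keep[seq_len(i - 1)]))
      if (channel[peaks_idx[i]] - channel[peaks_idx[j]] < 10) {
        if (sm[peaks_idx[i]] > sm[peaks_idx[j]]) keep[j] <- FALSE
        else keep[i] <- FALSE
      }
    }
    peaks_idx <- peaks_idx[keep]
  }
  if (length(peaks_idx) < n_peaks)
    stop("found only ", length(peaks_idx), " candidate peak(s) but n_peaks=",
         n_peaks, "; the histogram does not resolve the requested mixture")
  top <- peaks_idx[order(sm[peaks_idx], decreasing = TRUE)][seq_len(n_peaks)]
  top <- sort(top)

  mu <- channel[top]
  sigma <- pmax(0.05 * mu, 0.5)
  w <- sm[top] * sigma
  w <- w / sum(w)

  x <- channel[count > 0]; nx <- count[count > 0]
  ntot <- sum(nx)
  loglik <- -Inf
  dens <- matrix(0, length(x), n_peaks)
  for (iter in seq_len(max_iter)) {
    for (k in seq_len(n_peaks))
      dens[, k] <- w[k] * stats::dnorm(x, mu[k], sigma[k])
    mix <- pmax(rowSums(dens), 1e-300)
    new_ll <- sum(nx * log(mix))
    conv <- abs(new_ll - loglik) < tol
    loglik <- new_ll
    if (conv) break
    g <- dens / mix  # responsibilities
    for (k in seq_len(n_peaks)) {
      wk <- nx * g[, k]
      sk <- sum(wk)
      mu[k] <- sum(wk * x) / sk
      sigma[k] <- max(sqrt(sum(wk * (x - mu[k])^2) / sk), 0.5)
      w[k] <- sk / ntot
    }
  }
  o <- order(mu)
  structure(list(means = mu[o], sds = sigma[o], weights = w[o],
                 loglik = loglik, n_iter = iter,
                 converged = iter < max_iter,
                 n_peaks = n_peaks,
                 reference_channel_hint = reference_channel_hint,
                 hist = list(channel = channel, count = count)),
            class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("DNA-content mixture fit: %d peak(s), loglik %.2f (%d EM iterations)\n",
              x$n_peaks, x$loglik, x$n_iter))
  for (k in seq_len(x$n_peaks))
    cat(sprintf("  peak %d: mean %.1f, sd %.2f (CV %.1f%%), weight %.3f\n",
                k, x$means[k], x$sds[k], 100 * x$sds[k] / x$means[k],
                x$weights[k]))
  invisible(x)
}

#' @export
plot.ploidy_fit <- function(x, ...) {
  ch <- x$hist$channel; ct <- x$hist$count
  graphics::plot(ch, ct, type = "h", col = "grey70",
                 xlab = "DNA content (channel)", ylab = "events", ...)
  total <- sum(ct)
  xs <- seq(min(ch), max(ch), length.out = 512)
  for (k in seq_along(x$means))
    graphics::lines(xs, total * x$weights[k] *
                      stats::dnorm(xs, x$means[k], x$sds[k]), col = k + 1)
  invisible(x)
}

#' Estimate ploidy from fitted DNA-content peaks
#'
#' Identifies the diploid G0/G1 reference peak (nearest the hint channel
#' when one is supplied, otherwise the lowest-mean peak carrying at least
#' 10% of events), then reports the aneuploid population's DNA index and
#' ploidy (`2 * aneuploid G0/G1 mean / diploid mean`, in N units), its
#' G2/M fraction (weight of the peak at twice the aneuploid G0/G1
#' position over total aneuploid weight) and per-peak CVs. When no peak
#' lies within 15% of twice the aneuploid G0/G1 mean, the G2/M fraction
#' is reported as `NA`.
#'
#' @param fit A [fit_dna_content()] result.
#' @param reference_channel_hint Approximate diploid-peak channel;
#'   defaults to the hint stored in the fit.
#' @return Object of class `ploidy_estimate` with `ploidy_index` (N
#'   units), `dna_index`, `g2m_fraction`, peak means/weights and
#'   `cv_per_peak`.
#' @examples
#' h <- simulate_histogram(seed = 1)
#' estimate_ploidy(fit_dna_content(h, 3), reference_channel_hint = 200)
#' @export
estimate_ploidy <- function(fit, reference_channel_hint = NULL) {
  stopifnot(inherits(fit, "ploidy_fit"))
  if (fit$n_peaks < 2) stop("need at least two fitted peaks")
  hint <- reference_channel_hint %||% fit$reference_channel_hint
  mu <- fit$means; w <- fit$weights; s <- fit$sds
  dip <- if (!is.null(hint)) which.min(abs(mu - hint)) else {
    major <- which(w >= 0.10)
    if (length(major)) major[which.min(mu[major])] else which.min(mu)
  }
  rest <- setdiff(seq_along(mu), dip)
  if (length(rest) == 1) {
    g1 <- rest; g2m <- NA_integer_
  } else {
    lo <- rest[which.min(mu[rest])]; hi <- rest[which.max(mu[rest])]
    if (abs(mu[hi] - 2 * mu[lo]) / (2 * mu[lo]) <= 0.15) {
      g1 <- lo; g2m <- hi
    } else {
      g1 <- rest[which.max(w[rest])]; g2m <- NA_integer_
    }
  }
  dna_index <- mu[g1] / mu[dip]
  g2m_fraction <- if (is.na(g2m)) NA_real_ else w[g2m] / (w[g1] + w[g2m])
  structure(list(
    diploid_g1_mean = mu[dip], aneuploid_g1_mean = mu[g1],
    aneuploid_g2m_mean = if (is.na(g2m)) NA_real_ else mu[g2m],
    dna_index = dna_index, ploidy_index = 2 * dna_index,
    g2m_fraction = g2m_fraction,
    cv_per_peak = stats::setNames(s / mu, paste0("peak", seq_along(mu))),
    peak_weights = w, fit = fit), class = "ploidy_estimate")
}

#' @export
print.ploidy_estimate <- function(x, ...) {
  cat(sprintf("Ploidy estimate: %.1fN aneuploid population (DNA index %.3f)\n",
              round(x$ploidy_index, 1), x$dna_index))
  if (!is.na(x$g2m_fraction))
    cat(sprintf("  G2/M (%.1fN) fraction: %.0f%%\n",
                round(2 * x$ploidy_index, 1), 100 * x$g2m_fraction))
  cat("  peak CVs:",
      paste(sprintf("%.1f%%", 100 * x$cv_per_peak), collapse = ", "), "\n")
  invisible(x)
}
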