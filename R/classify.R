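#' Histogram bin counts for a p-value set
#'
#' Bins p-values into `bins` equal-width bins on \[0, 1\]. Bins are
#' half-open on the right, `[(b-1)/B, b/B)`, except the last bin which is
#' closed so that p = 1 lands in bin `B`. Missing values are dropped
#' before binning.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA/NaN allowed and dropped).
#' @param bins Number of bins (default 40).
#' @return Integer vector of length `bins` with the per-bin counts.
#' @examples
#' bin_pvalues(c(0, 0.5, 1), bins = 40)[c(1, 21, 40)]
#' @export
bin_pvalues <- function(p, bins = 40L) {
  stopifnot(is.numeric(p), length(bins) == 1L, bins >= 2L)
  p <- p[!is.na(p)]
  if (length(p) == 0L) {
    stop("no non-missing p-values to bin", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  bins <- as.integer(bins)
  idx <- pmin(floor(p * bins) + 1L, bins)
  tabulate(idx, nbins = bins)
}

#' Binomial peak-detection threshold for histogram bins
#'
#' The quality-control threshold above which a histogram bin counts as a
#' peak: the Bonferroni-corrected alpha-level quantile of the binomial
#' distribution with size `m` (total p-values) and probability `1/bins`
#' (the per-bin probability under uniformity). A bin is a peak iff its
#' count is *strictly* greater than the returned value, so the familywise
#' probability of any false peak on a uniform set is at most `alpha`.
#'
#' @param m Total number of p-values in the set.
#' @param bins Number of histogram bins (default 40).
#' @param alpha Familywise error level (default 0.05).
#' @return Integer threshold count.
#' @examples
#' qc_threshold(20000)           # approx 567 for the default geometry
#' qc_threshold(1, bins = 40)    # 1: a single p-value can never be a peak
#' @export
qc_threshold <- function(m, bins = 40L, alpha = 0.05) {
  stopifnot(length(m) == 1L, is.finite(m), m >= 1, length(alpha) == 1L,
            alpha > 0, alpha < 1, bins >= 2L)
  as.integer(stats::qbinom(1 - alpha / bins, size = m, prob = 1 / bins))
}

pvalue_classes <- c("uniform", "anti_conservative", "conservative",
                    "bimodal", "other")

#' Classify a binned p-value histogram
#'
#' Assigns one of five distributional classes from the set of bins whose
#' counts exceed the peak-detection threshold:
#'
#' * no bin over threshold: `"uniform"`;
#' * flagged bins form a run anchored at the left boundary spanning at
#'   most a third of the unit range: `"anti_conservative"`;
#' * the mirror-image right-boundary run: `"conservative"`;
#' * boundary runs at both ends and nothing in between: `"bimodal"`;
#' * any interior run (humps, spikes, non-contiguous boundary peaks), or a
#'   boundary run longer than a third of the range: `"other"`.
#'
#' @param counts Integer vector of bin counts (see [bin_pvalues()]).
#' @param threshold Peak threshold from [qc_threshold()].
#' @return A single string, one of `uniform`, `anti_conservative`,
#'   `conservative`, `bimodal`, `other`.
#' @export
classify_counts <- function(counts, threshold) {
  stopifnot(is.numeric(counts), length(counts) >= 3L,
            length(threshold) == 1L, is.finite(threshold))
  B <- length(counts)
  flagged <- which(counts > threshold)
  if (length(flagged) == 0L) {
    return("uniform")
  }
  runs <- split(flagged, cumsum(c(1L, diff(flagged) != 1L)))
  touches_left <- vapply(runs, function(r) r[1L] == 1L, logical(1))
  touches_right <- vapply(runs, function(r) r[length(r)] == B, logical(1))
  interior <- !touches_left & !touches_right
  if (any(interior)) {
    return("other")
  }
  max_run <- floor(B / 3)
  if (any(touches_left) && any(touches_right)) {
    return("bimodal")
  }
  run_len <- length(runs[[1L]])
  if (touches_left[[1L]]) {
    if (run_len <= max_run) "anti_conservative" else "other"
  } else {
    if (run_len <= max_run) "conservative" else "other"
  }
}

#' Classify a p-value set by its histogram shape
#'
#' End-to-end histogram diagnostic: bins the set, computes the binomial
#' peak threshold and assigns the distributional class. Sets smaller than
#' `min_size` (default: one p-value per bin) carry too little information
#' to call a shape and are reported as `"unclassifiable"`.
#'
#' @inheritParams bin_pvalues
#' @inheritParams qc_threshold
#' @param min_size Minimum set size that will be classified.
#' @return A `pval_histogram` object: a list with elements `counts`,
#'   `bins`, `m` (set size after NA removal), `alpha`, `qc_threshold`,
#'   `flagged_bins` and `class`. Has [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' set.seed(1)
#' h <- classify_pvalues(runif(5000))
#' h$class
#' glance(h)
#' @export
classify_pvalues <- function(p, bins = 40L, alpha = 0.05, min_size = bins) {
  counts <- bin_pvalues(p, bins = bins)
  m <- sum(counts)
  thr <- qc_threshold(m, bins = bins, alpha = alpha)
  klass <- if (m < min_size) {
    "unclassifiable"
  } else {
    classify_counts(counts, thr)
  }
  structure(
    list(counts = counts, bins = as.integer(bins), m = m, alpha = alpha,
         qc_threshold = thr, flagged_bins = which(counts > thr),
         class = klass),
    class = "pval_histogram"
  )
}

#' @export
print.pval_histogram <- function(x, ...) {
  cat(sprintf(
    "<pval_histogram> %d p-values in %d bins; QC threshold %d (alpha = %g)\n",
    x$m, x$bins, x$qc_threshold, x$alpha
  ))
  cat(sprintf("  class: %s", x$class))
  if (length(x$flagged_bins)) {
    cat(sprintf("  (flagged bins: %s)", paste(x$flagged_bins, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pval_histogram
#' @export
tidy.pval_histogram <- function(x, ...) {
  B <- x$bins
  tibble::tibble(
    bin = seq_len(B),
    lower = (seq_len(B) - 1) / B,
    upper = seq_len(B) / B,
    count = x$counts,
    flagged = x$counts > x$qc_threshold
  )
}

#' @method glance pval_histogram
#' @export
glance.pval_histogram <- function(x, ...) {
  tibble::tibble(
    n = x$m, bins = x$bins, alpha = x$alpha,
    qc_threshold = x$qc_threshold,
    n_flagged = length(x$flagged_bins),
    class = x$class
  )
}

#' Plot a classified p-value histogram
#'
#' Bar chart of the bin counts with the binomial QC threshold drawn as a
#' horizontal line; bins over the threshold are highlighted.
#'
#' @param object A `pval_histogram` from [classify_pvalues()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot pval_histogram
#' @export
autoplot.pval_histogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                  y = .data$count, fill = .data$flagged)) +
    ggplot2::geom_col(width = 1 / object$bins, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$qc_threshold,
                        colour = "red", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "p-value", y = "count",
                  title = sprintf("class: %s", object$class)) +
    ggplot2::theme_minimal()
}
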