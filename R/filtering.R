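#' Metric-specific low-expression thresholds
#'
#' Default cut-offs below which a feature counts as low-expressed, per
#' expression metric: basemean 10 (library-size-normalised mean counts),
#' logcpm 1 (log2 counts per million), rpkm 1, fpkm 1, aveexpr 3.32
#' (average log2 CPM; 3.32 = log2(10)), and cuffdiff-style `value`
#' columns treated on the FPKM scale.
#'
#' @param basemean,logcpm,rpkm,fpkm,aveexpr,value Per-metric thresholds.
#' @return Named numeric vector of thresholds.
#' @export
expression_thresholds <- function(basemean = 10, logcpm = 1, rpkm = 1,
                                  fpkm = 1, aveexpr = 3.32, value = fpkm) {
  out <- c(basemean = basemean, logcpm = logcpm, rpkm = rpkm, fpkm = fpkm,
           aveexpr = aveexpr, value = value)
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("thresholds must be strictly positive", call. = FALSE)
  }
  out
}

# priority when a table carries several metric types; the row mean is
# taken within the governing metric only
METRIC_PRIORITY <- c("basemean", "logcpm", "aveexpr", "fpkm", "rpkm", "value")

#' Flag low-expression features for removal
#'
#' Picks the governing expression metric (priority basemean > logcpm >
#' aveexpr > fpkm > rpkm > value), averages across all columns carrying
#' that metric when there are several (one per contrast or sample), and
#' keeps a feature iff its mean expression is at or above the metric's
#' threshold. Missing expression values are treated as below threshold.
#'
#' @param table A data frame or `mined_table` with at least one
#'   recognised expression column.
#' @param thresholds Named thresholds from [expression_thresholds()].
#' @return An `expression_filter` object: list with `filterable`
#'   (logical), `keep` (logical vector over rows), `n_kept`, `n_dropped`,
#'   `metric`, `threshold` and `expression` (the per-row governing
#'   values). When no recognised expression column exists, `filterable`
#'   is `FALSE` and the set is excluded from rescue analysis.
#' @examples
#' tab <- data.frame(baseMean = c(5, 10, 50), pvalue = c(0.2, 0.01, 0.5))
#' filter_low_expression(tab)$keep
#' @export
filter_low_expression <- function(table, thresholds = expression_thresholds()) {
  dat <- table_data_of(table)
  roles <- assign_column_roles(names(dat))
  expr <- roles[roles$role == "expression", ]
  if (nrow(expr) == 0L) {
    return(structure(list(filterable = FALSE, keep = NULL,
                          n_kept = NA_integer_, n_dropped = NA_integer_,
                          metric = NA_character_, threshold = NA_real_,
                          expression = NULL),
                     class = "expression_filter"))
  }
  metric <- METRIC_PRIORITY[METRIC_PRIORITY %in% expr$metric][1L]
  cols <- expr$name[expr$metric == metric]
  vals <- matrix(
    unlist(lapply(cols, function(nm) {
      suppressWarnings(as.numeric(dat[[nm]]))
    })),
    nrow = nrow(dat)
  )
  v <- rowMeans(vals)
  thr <- thresholds[[metric]]
  keep <- !is.na(v) & v >= thr
  structure(list(filterable = TRUE, keep = keep,
                 n_kept = sum(keep), n_dropped = sum(!keep),
                 metric = metric, threshold = thr, expression = v),
            class = "expression_filter")
}

#' @export
print.expression_filter <- function(x, ...) {
  if (!x$filterable) {
    cat("<expression_filter> not filterable: no recognised expression column\n")
  } else {
    cat(sprintf(
      "<expression_filter> metric %s >= %g: kept %d, dropped %d\n",
      x$metric, x$threshold, x$n_kept, x$n_dropped
    ))
  }
  invisible(x)
}

#' Re-classify a p-value set after removing low-count features
#'
#' The rescue analysis: classify the set (and, when it is uniform or
#' anti-conservative, estimate pi0), drop low-expression features, and
#' classify / estimate again on the survivors. A malformed distribution
#' driven by discrete tests on low counts is "rescued" when the
#' post-filter class becomes anti-conservative or uniform.
#'
#' @param table Data frame or `mined_table` containing one p-value column
#'   and expression data.
#' @param bins,alpha Histogram geometry and peak-detection level.
#' @param thresholds Low-expression thresholds.
#' @param pvalue_col Name of the p-value column; default: the first
#'   column found by [find_pvalue_columns()].
#' @param pi0_method `"lfdr"` (default) or `"storey"`.
#' @return A `rescue_result`: list with `before` and `after` (each a list
#'   of `class`, `pi0`, `n`), `filterable`, `metric`, `n_before`,
#'   `n_after`. `pi0` is `NA` unless the class is uniform or
#'   anti-conservative. Has a [generics::tidy()] method.
#' @export
rescue_set <- function(table, bins = 40L, alpha = 0.05,
                       thresholds = expression_thresholds(),
                       pvalue_col = NULL, pi0_method = c("lfdr", "storey")) {
  pi0_method <- match.arg(pi0_method)
  dat <- table_data_of(table)
  if (is.null(pvalue_col)) {
    pcols <- find_pvalue_columns(names(dat))
    if (length(pcols) == 0L) {
      stop("no p-value column found", call. = FALSE)
    }
    pvalue_col <- pcols[1L]
  }
  p <- suppressWarnings(as.numeric(dat[[pvalue_col]]))
  stage <- function(pv) {
    pv_ok <- pv[is.finite(pv)]
    h <- classify_pvalues(pv_ok, bins = bins, alpha = alpha)
    pi0 <- NA_real_
    if (h$class %in% c("uniform", "anti_conservative")) {
      pi0 <- tryCatch(
        switch(pi0_method, lfdr = pi0_lfdr(pv_ok), storey = pi0_storey(pv_ok)),
        error = function(e) NA_real_
      )
    }
    list(class = h$class, pi0 = pi0, n = h$m)
  }
  before <- stage(p)
  filt <- filter_low_expression(dat, thresholds = thresholds)
  if (!filt$filterable) {
    out <- list(before = before, after = NULL, filterable = FALSE,
                metric = NA_character_, n_before = before$n,
                n_after = NA_integer_)
    return(structure(out, class = "rescue_result"))
  }
  after <- stage(p[filt$keep])
  structure(list(before = before, after = after, filterable = TRUE,
                 metric = filt$metric, n_before = before$n,
                 n_after = after$n),
            class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  if (!x$filterable) {
    cat(sprintf("<rescue_result> %s (n = %d); not filterable\n",
                x$before$class, x$n_before))
    return(invisible(x))
  }
  cat(sprintf("<rescue_result> %s (n = %d) -> %s (n = %d)\n",
              x$before$class, x$n_before, x$after$class, x$n_after))
  invisible(x)
}

#' @method tidy rescue_result
#' @export
tidy.rescue_result <- function(x, ...) {
  tibble::tibble(
    class_before = x$before$class,
    pi0_before = x$before$pi0,
    class_after = if (x$filterable) x$after$class else NA_character_,
    pi0_after = if (x$filterable) x$after$pi0 else NA_real_,
    n_before = x$n_before,
    n_after = x$n_after,
    filterable = x$filterable
  )
}

#' Class-transition matrix over a corpus of rescue results
#'
#' Tabulates before-class against after-class over all filterable rescue
#' results, the numeric backbone of a rescue Sankey chart. Sets whose
#' before or after stage is unclassifiable are excluded and counted
#' separately.
#'
#' @param results List of `rescue_result` objects, or a tibble of
#'   [tidy()]-ed rescue rows.
#' @return A `class_transitions` object: list with `matrix` (5x5 counts,
#'   before in rows), `before_counts`, `after_counts`,
#'   `before_proportions`, `after_proportions`, `n`, `n_excluded`. Has a
#'   [generics::tidy()] method returning the long form.
#' @export
transition_summary <- function(results) {
  rows <- if (is.data.frame(results)) {
    results
  } else {
    stopifnot(length(results) >= 1L)
    purrr::map_dfr(results, tidy)
  }
  rows <- rows[rows$filterable, , drop = FALSE]
  usable <- rows$class_before %in% pvalue_classes &
    rows$class_after %in% pvalue_classes
  n_excluded <- sum(!usable)
  rows <- rows[usable, , drop = FALSE]
  f_before <- factor(rows$class_before, levels = pvalue_classes)
  f_after <- factor(rows$class_after, levels = pvalue_classes)
  mat <- table(before = f_before, after = f_after)
  mat <- matrix(as.integer(mat), nrow = 5, dimnames = dimnames(mat))
  before_counts <- rowSums(mat)
  after_counts <- colSums(mat)
  n <- sum(mat)
  structure(list(
    matrix = mat,
    before_counts = before_counts,
    after_counts = after_counts,
    before_proportions = if (n > 0) before_counts / n else before_counts,
    after_proportions = if (n > 0) after_counts / n else after_counts,
    n = n, n_excluded = n_excluded
  ), class = "class_transitions")
}

#' @export
print.class_transitions <- function(x, ...) {
  cat(sprintf("<class_transitions> %d sets (%d excluded)\n", x$n,
              x$n_excluded))
  print(x$matrix)
  invisible(x)
}

#' @method tidy class_transitions
#' @export
tidy.class_transitions <- function(x, ...) {
  d <- as.data.frame.table(as.table(x$matrix), stringsAsFactors = FALSE)
  names(d) <- c("class_before", "class_after", "count")
  tibble::as_tibble(d)
}

#' Plot a class-transition summary
#'
#' Heatmap of the before-to-after class counts.
#'
#' @param object A `class_transitions` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot class_transitions
#' @export
autoplot.class_transitions <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class_after,
                                  y = .data$class_before,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::labs(x = "class after filtering", y = "class before") +
    ggplot2::theme_minimal()
}

table_data_of <- function(table) {
  if (inherits(table, "mined_table")) {
    if (!identical(table$status, "ok")) {
      stop("cannot operate on an import-failure record", call. = FALSE)
    }
    table$data
  } else if (is.data.frame(table)) {
    table
  } else {
    stop("expected a data frame or mined_table", call. = FALSE)
  }
}
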