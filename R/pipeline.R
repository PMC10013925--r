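#' Scan a directory of processed tables end to end
#'
#' Runs the full diagnostic pipeline over every file in a directory:
#' file-name prefilter, import with delimiter sniffing, p-value column
#' mining, set validation, histogram classification, pi0 estimation for
#' uniform / anti-conservative sets, and DE-tool inference. Every file
#' that passes the prefilter yields exactly one record per analysed set;
#' files that fail to import or contain no p-value column are recorded
#' with the corresponding status rather than dropped silently.
#'
#' By default one p-value column per file is analysed, drawn at random
#' (seedably) when a table carries several; `all_sets = TRUE` analyses
#' every column.
#'
#' @param path Directory of tables.
#' @param bins,alpha Histogram geometry and peak-detection level.
#' @param thresholds Low-expression thresholds (used only to report
#'   filterability; see [rescue_set()] for the rescue analysis).
#' @param lambda Storey smoother grid.
#' @param seed Integer seed governing per-file set selection.
#' @param all_sets Analyse every p-value column instead of one per file.
#' @return A `corpus_scan`: list with `records` (one tibble row per file
#'   x analysed set: `file`, `status`, `pvalue_column`, `n`, `class`,
#'   `pi0_lfdr`, `pi0_storey`, `tool`), `summary` (class counts and
#'   proportions over ok records) and `config` (parameter echo).
#' @export
scan_dir <- function(path, bins = 40L, alpha = 0.05,
                     thresholds = expression_thresholds(),
                     lambda = seq(0.05, 0.95, by = 0.05),
                     seed = NULL, all_sets = FALSE) {
  if (!dir.exists(path)) {
    stop(sprintf("input directory '%s' does not exist", path), call. = FALSE)
  }
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- files[filename_passes_prefilter(files)]
  empty <- tibble::tibble(
    file = character(), status = character(), pvalue_column = character(),
    n = integer(), class = character(), pi0_lfdr = numeric(),
    pi0_storey = numeric(), tool = character()
  )
  records <- with_seed_if(if (is.null(seed)) NULL else seed, {
    purrr::map_dfr(files, function(f) scan_one_file(f, bins, alpha, lambda,
                                                    all_sets))
  })
  if (nrow(records) == 0L) records <- empty
  ok <- records[records$status == "ok", , drop = FALSE]
  class_counts <- table(factor(ok$class,
                               levels = c(pvalue_classes, "unclassifiable")))
  classified <- ok$class %in% pvalue_classes
  summary <- list(
    n_files = length(files),
    n_records = nrow(records),
    n_ok = nrow(ok),
    class_counts = as.list(class_counts),
    class_proportions = as.list(
      if (sum(classified) > 0) {
        table(factor(ok$class[classified], levels = pvalue_classes)) /
          sum(classified)
      } else {
        stats::setNames(rep(0, 5), pvalue_classes)
      }
    )
  )
  structure(list(
    records = records,
    summary = summary,
    config = list(path = path, bins = as.integer(bins), alpha = alpha,
                  thresholds = as.list(thresholds), lambda = lambda,
                  seed = seed, all_sets = all_sets,
                  schema_version = "1.0")
  ), class = "corpus_scan")
}

scan_one_file <- function(f, bins, alpha, lambda, all_sets) {
  rec <- function(status, pvalue_column = NA_character_, n = NA_integer_,
                  class = NA_character_, pi0_lfdr = NA_real_,
                  pi0_storey = NA_real_, tool = NA_character_) {
    tibble::tibble(file = basename(f), status = status,
                   pvalue_column = pvalue_column, n = n, class = class,
                   pi0_lfdr = pi0_lfdr, pi0_storey = pi0_storey,
                   tool = tool)
  }
  tab <- read_processed_table(f)
  if (tab$status != "ok") {
    return(rec("import_failure"))
  }
  pcols <- find_pvalue_columns(tab)
  if (length(pcols) == 0L) {
    return(rec("no_pvalue_columns"))
  }
  selected <- if (all_sets || length(pcols) == 1L) {
    pcols
  } else {
    pcols[sample.int(length(pcols), 1L)]
  }
  tool <- infer_de_tool(tab)$tool
  purrr::map_dfr(selected, function(pc) {
    values <- tab$data[[pc]]
    verdict <- validate_pvalue_set(values)
    if (verdict$status != "ok") {
      return(rec(paste0("invalid_", verdict$status), pvalue_column = pc))
    }
    p <- values[is.finite(values)]
    h <- classify_pvalues(p, bins = bins, alpha = alpha)
    pi0_l <- NA_real_
    pi0_s <- NA_real_
    if (h$class %in% c("uniform", "anti_conservative")) {
      pi0_l <- tryCatch(pi0_lfdr(p), error = function(e) NA_real_)
      pi0_s <- tryCatch(pi0_storey(p, lambda = lambda),
                        error = function(e) NA_real_,
                        warning = function(w) 0)
    }
    rec("ok", pvalue_column = pc, n = h$m, class = h$class,
        pi0_lfdr = pi0_l, pi0_storey = pi0_s, tool = tool)
  })
}

#' @export
print.corpus_scan <- function(x, ...) {
  cat(sprintf("<corpus_scan> %s: %d files, %d records (%d ok)\n",
              x$config$path, x$summary$n_files, x$summary$n_records,
              x$summary$n_ok))
  counts <- unlist(x$summary$class_counts)
  counts <- counts[counts > 0]
  if (length(counts)) {
    cat("  classes:", paste(sprintf("%s=%d", names(counts), counts),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy corpus_scan
#' @export
tidy.corpus_scan <- function(x, ...) {
  x$records
}

#' @method glance corpus_scan
#' @export
glance.corpus_scan <- function(x, ...) {
  tibble::tibble(
    n_files = x$summary$n_files,
    n_records = x$summary$n_records,
    n_ok = x$summary$n_ok,
    prop_anti_conservative =
      x$summary$class_proportions$anti_conservative %||% NA_real_
  )
}

#' Serialise a corpus scan to JSON
#'
#' Writes the per-file records, class summary and the full parameter
#' echo to a JSON report. Output is deterministic for a given scan, so
#' identical seeds produce byte-identical reports.
#'
#' @param scan A `corpus_scan` from [scan_dir()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(scan, path) {
  stopifnot(inherits(scan, "corpus_scan"))
  jsonlite::write_json(
    list(config = scan$config, summary = scan$summary,
         records = scan$records),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
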