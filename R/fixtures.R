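FIXTURE_DIALECTS <- c("deseq2", "deseq", "edger", "limma", "cuffdiff",
                      "unknown")

#' Write a processed-table fixture in a known column-name dialect
#'
#' Emits a small delimited table that mimics the output of a named
#' differential-expression tool, together with a ground-truth manifest
#' recording every column's true role. The manifest is what mining
#' precision/recall is scored against, so it is written from the dialect
#' definition, never from the package's own column regexes.
#'
#' @param dialect One of `"deseq2"`, `"deseq"`, `"edger"`, `"limma"`,
#'   `"cuffdiff"`, `"unknown"`.
#' @param path Output file path; `".gz"` is appended when `gzip = TRUE`
#'   and the path does not already end in it.
#' @param p_values Optional numeric vector to use as the unadjusted
#'   p-value column; by default a null/alternative mixture is drawn.
#' @param n_rows Number of feature rows when `p_values` is not given.
#' @param delimiter `"tab"`, `"comma"` or `"semicolon"`.
#' @param gzip Compress the output.
#' @param include_adjusted Include the dialect's adjusted-p column.
#' @param n_pvalue_columns Number of unadjusted p-value columns (>= 1);
#'   extra columns get a numeric suffix in the dialect's own style.
#' @param seed Optional integer seed.
#' @return The manifest, invisibly: a list with `file`, `dialect`,
#'   `delimiter`, `gzip`, `tool`, `pub_date`, `n_rows` and a `columns`
#'   data frame (`name`, `role`, `metric`). Also written as JSON next to
#'   the table (`<path>.manifest.json`).
#' @export
write_fixture <- function(dialect = FIXTURE_DIALECTS, path,
                          p_values = NULL, n_rows = 500L,
                          delimiter = c("tab", "comma", "semicolon"),
                          gzip = FALSE, include_adjusted = TRUE,
                          n_pvalue_columns = 1L, seed = NULL) {
  dialect <- match.arg(dialect)
  delimiter <- match.arg(delimiter)
  stopifnot(n_pvalue_columns >= 1L)
  if (gzip && !grepl("\\.gz$", path)) {
    path <- paste0(path, ".gz")
  }
  built <- with_seed_if(seed, {
    if (is.null(p_values)) {
      p_values <- generate_pvalue_set(n_rows, pi0 = 0.8, delta = 2)$p_value
    }
    build_dialect_table(dialect, p_values, include_adjusted,
                        n_pvalue_columns)
  })
  delim <- switch(delimiter, tab = "\t", comma = ",", semicolon = ";")
  out <- tryCatch(
    readr::write_delim(built$table, path, delim = delim, progress = FALSE),
    error = function(e) {
      stop(sprintf("failed to write fixture to '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  manifest <- list(
    file = path, dialect = dialect, delimiter = delimiter, gzip = gzip,
    tool = built$tool, pub_date = built$pub_date,
    n_rows = nrow(built$table),
    columns = built$columns
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

build_dialect_table <- function(dialect, p, include_adjusted,
                                n_pvalue_columns) {
  n <- length(p)
  padj <- stats::p.adjust(p, method = "BH")
  base_mean <- round(2^stats::runif(n, 0, 12), 3)
  fpkm <- round(2^stats::runif(n, -2, 10), 3)
  logexpr <- round(stats::runif(n, -2, 12), 3)
  lfc <- round(stats::rnorm(n), 3)
  ids <- sprintf("G%05d", seq_len(n))
  col <- function(name, values, role, metric = NA_character_) {
    list(name = name, values = values, role = role, metric = metric)
  }
  spec <- switch(dialect,
    deseq2 = list(
      tool = "deseq2", pub_date = NA_character_, pbase = "pvalue",
      cols = list(
        col("baseMean", base_mean, "expression", "basemean"),
        col("log2FoldChange", lfc, "other"),
        col("lfcSE", round(abs(stats::rnorm(n, 0, 0.5)), 3), "other"),
        col("stat", round(stats::rnorm(n), 3), "other"),
        col("pvalue", p, "pvalue"),
        col("padj", padj, "adjusted")
      )
    ),
    deseq = list(
      tool = "deseq", pub_date = NA_character_, pbase = "pval",
      cols = list(
        col("id", ids, "other"),
        col("baseMean", base_mean, "expression", "basemean"),
        col("baseMeanA", round(base_mean * 2^(lfc / 2), 3),
            "expression", "basemean"),
        col("baseMeanB", round(base_mean * 2^(-lfc / 2), 3),
            "expression", "basemean"),
        col("foldChange", round(2^lfc, 3), "other"),
        col("log2FoldChange", lfc, "other"),
        col("pval", p, "pvalue"),
        col("padj", padj, "adjusted")
      )
    ),
    edger = list(
      tool = "edger", pub_date = NA_character_, pbase = "PValue",
      cols = list(
        col("logFC", lfc, "other"),
        col("logCPM", logexpr, "expression", "logcpm"),
        col("LR", round(stats::rchisq(n, 1), 3), "other"),
        col("PValue", p, "pvalue"),
        col("FDR", padj, "adjusted")
      )
    ),
    limma = list(
      tool = "limma", pub_date = "2016-05-01", pbase = "P.Value",
      cols = list(
        col("logFC", lfc, "other"),
        col("AveExpr", logexpr, "expression", "aveexpr"),
        col("t", round(stats::rnorm(n), 3), "other"),
        col("P.Value", p, "pvalue"),
        col("adj.P.Val", padj, "adjusted"),
        col("B", round(stats::rnorm(n), 3), "other")
      )
    ),
    cuffdiff = list(
      tool = "cuffdiff", pub_date = NA_character_, pbase = "p_value",
      cols = list(
        col("test_id", ids, "other"),
        col("gene_id", ids, "other"),
        col("gene", ids, "other"),
        col("locus", sprintf("chr1:%d-%d", seq_len(n) * 1000L,
                             seq_len(n) * 1000L + 500L), "other"),
        col("sample_1", rep("q1", n), "other"),
        col("sample_2", rep("q2", n), "other"),
        col("status", rep("OK", n), "other"),
        col("value_1", fpkm, "expression", "value"),
        col("value_2", round(fpkm * 2^lfc, 3), "expression", "value"),
        col("log2(fold_change)", lfc, "other"),
        col("test_stat", round(stats::rnorm(n), 3), "other"),
        col("p_value", p, "pvalue"),
        col("q_value", padj, "adjusted")
      )
    ),
    unknown = list(
      tool = "unknown", pub_date = NA_character_, pbase = "p.val",
      cols = list(
        col("gene", ids, "other"),
        col("log2fc", lfc, "other"),
        col("score", round(stats::rnorm(n), 3), "other"),
        col("p.val", p, "pvalue"),
        col("p.val.adj", padj, "adjusted")
      )
    )
  )
  cols <- spec$cols
  if (!include_adjusted) {
    cols <- purrr::keep(cols, ~ .x$role != "adjusted")
  }
  if (n_pvalue_columns > 1L) {
    extra <- purrr::map(seq_len(n_pvalue_columns - 1L) + 1L, function(i) {
      col(paste0(spec$pbase, "_", i),
          generate_pvalue_set(n, pi0 = 0.9, delta = 2)$p_value, "pvalue")
    })
    cols <- c(cols, extra)
  }
  tab <- tibble::as_tibble(
    stats::setNames(purrr::map(cols, "values"), purrr::map_chr(cols, "name")),
    .name_repair = "minimal"
  )
  columns <- data.frame(
    name = purrr::map_chr(cols, "name"),
    role = purrr::map_chr(cols, "role"),
    metric = purrr::map_chr(cols, "metric"),
    stringsAsFactors = FALSE
  )
  list(table = tab, columns = columns, tool = spec$tool,
       pub_date = spec$pub_date)
}

#' Write one fixture per column-name dialect
#'
#' Convenience corpus generator: one fixture file per requested dialect
#' under `dir`, each with its ground-truth manifest.
#'
#' @param dir Output directory (created if missing).
#' @param dialects Dialects to emit (default: all six).
#' @param ... Passed on to [write_fixture()].
#' @param seed Optional integer seed; each file gets a distinct
#'   deterministic sub-seed.
#' @return Invisibly, the list of manifests (named by dialect).
#' @export
simulate_fixture_corpus <- function(dir, dialects = FIXTURE_DIALECTS, ...,
                                    seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifests <- purrr::imap(stats::setNames(dialects, dialects),
                           function(d, nm) {
    sub_seed <- if (is.null(seed)) NULL else seed + match(d, FIXTURE_DIALECTS)
    write_fixture(d, file.path(dir, paste0(d, "_results.tsv")),
                  seed = sub_seed, ...)
  })
  invisible(manifests)
}
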