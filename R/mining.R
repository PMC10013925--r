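# Column-name regexes used throughout the mining stage. All matching is
# done on lower-cased names.
PVAL_REGEX <- "p[^a-z]{0,4}val"
ADJ_REGEX <- "adj|fdr|corr|thresh"
# canonical adjusted-p column names that do not themselves match PVAL_REGEX
ADJ_EXTRA_REGEX <- "^padj$|^q[^a-z]{0,4}val|^fdr$|adj[^a-z]{0,3}p"
EXPR_PATTERNS <- c(basemean = "basemean", value = "value", fpkm = "fpkm",
                   logcpm = "logcpm", rpkm = "rpkm", aveexpr = "aveexpr")

DROP_FILENAME_REGEX <- paste0(
  "series_matrix\\.txt\\.gz$|filelist\\.txt$|readme|\\.bam(\\.tdf|$)|",
  "\\.bai(\\.gz|$)|\\.sam(\\.gz|$)|\\.csfasta|",
  "\\.fa(sta)?(\\.gz|\\.bz2|\\.txt\\.gz|$)|\\.f(a|n)a(\\.gz|$)|\\.wig|",
  "\\.big[Ww]ig$|\\.bw(\\.|$)|\\.bed([Gg]raph)?(\\.tdf|\\.gz|\\.bz2|",
  "\\.txt\\.gz$|$)|(broad_)?lincs|\\.tdf$|\\.hic$|\\.rds(\\.gz|$)|",
  "\\.tar\\.gz$|\\.mtx(\\.gz$|$)|dge\\.txt\\.gz$|umis?\\.txt\\.gz$"
)
ALLOWED_EXTENSIONS <- c("tab", "xlsx", "diff", "tsv", "xls", "csv", "txt",
                        "rtf", "tar")

DE_TOOL_TEXT_REGEX <- paste0(
  "deseq2?|de(g|x)seq|rockhopper|cuff(diff|links)|edger|",
  "clc(bio)?? genomics|igeak|bayseq|samseq|noiseq|ebseq|limma|voom|",
  "sleuth|partek|(nrsa|nascent rna seq)|median ratio norm|rmats|",
  "ballgown|biojupie|seurat|exdega"
)

#' Should a supplementary file name be mined at all?
#'
#' Processed-table prefilter on file names: the name must carry one of
#' the accepted tabular extensions (optionally gzip/bzip2-compressed) and
#' must not match the drop pattern that marks files which cannot contain
#' p-values (series matrices, alignments, sequences, coverage tracks,
#' count matrices, ...). Matching is case-insensitive.
#'
#' @param filename Character vector of file names.
#' @return Logical vector, `TRUE` for names worth importing.
#' @examples
#' filename_passes_prefilter(c("deg_results.tsv", "sample1.bam",
#'                             "GSE1_series_matrix.txt.gz"))
#' @export
filename_passes_prefilter <- function(filename) {
  stopifnot(is.character(filename), all(nzchar(filename)))
  fn <- tolower(basename(filename))
  dropped <- grepl(DROP_FILENAME_REGEX, fn, perl = TRUE)
  ext <- tools::file_ext(sub("\\.(gz|bz2)$", "", fn))
  ext_ok <- ext %in% ALLOWED_EXTENSIONS
  ext_ok & !dropped
}

# role assignment for a vector of column names; deterministic,
# lower-cased matching, one role per column
assign_column_roles <- function(nms) {
  low <- tolower(nms)
  is_pval <- grepl(PVAL_REGEX, low, perl = TRUE)
  is_adj_marker <- grepl(ADJ_REGEX, low, perl = TRUE)
  role <- rep("other", length(nms))
  metric <- rep(NA_character_, length(nms))
  adjusted <- (is_pval & is_adj_marker) |
    grepl(ADJ_EXTRA_REGEX, low, perl = TRUE)
  pvalue <- is_pval & !adjusted
  role[adjusted] <- "adjusted"
  role[pvalue] <- "pvalue"
  for (i in which(role == "other")) {
    hit <- EXPR_PATTERNS[vapply(EXPR_PATTERNS, grepl, logical(1), x = low[i])]
    if (length(hit)) {
      role[i] <- "expression"
      metric[i] <- names(hit)[which.max(nchar(hit))]
    }
  }
  tibble::tibble(name = nms, role = role, metric = metric)
}

#' Find unadjusted p-value columns by name
#'
#' Columns whose lower-cased name matches `p[^a-z]{0,4}val` but not the
#' adjusted-p marker `adj|fdr|corr|thresh`.
#'
#' @param x Column names (character), a data frame, or a `mined_table`.
#' @return Character vector of matching column names (possibly empty).
#' @examples
#' find_pvalue_columns(c("p_value", "q_value", "padj"))
#' find_pvalue_columns(c("PValue", "FDR"))
#' @export
find_pvalue_columns <- function(x) {
  nms <- column_names_of(x)
  low <- tolower(nms)
  nms[grepl(PVAL_REGEX, low, perl = TRUE) &
        !grepl(ADJ_REGEX, low, perl = TRUE)]
}

#' Find expression-level columns by name
#'
#' Matches the metric patterns basemean, value, fpkm, logcpm, rpkm and
#' aveexpr against lower-cased column names; a name matching several
#' patterns takes the longest (most specific) one. Columns already
#' identified as p-value or adjusted-p columns are never returned.
#'
#' @inheritParams find_pvalue_columns
#' @return Tibble with columns `name` and `metric`.
#' @examples
#' find_expression_columns(c("baseMean", "pvalue", "value_1", "AveExpr"))
#' @export
find_expression_columns <- function(x) {
  roles <- assign_column_roles(column_names_of(x))
  out <- roles[roles$role == "expression", c("name", "metric")]
  tibble::as_tibble(out)
}

column_names_of <- function(x) {
  if (inherits(x, "mined_table")) {
    names(x$data)
  } else if (is.data.frame(x)) {
    names(x)
  } else if (is.character(x)) {
    x
  } else {
    stop("expected column names, a data frame or a mined_table",
         call. = FALSE)
  }
}

#' Read a processed-data table and assign column roles
#'
#' Imports delimited text (tab / comma / semicolon, sniffed from the
#' first lines; gzip decompressed transparently) or Excel files, keeps
#' the header, and coerces every p-value / adjusted / expression column
#' to numeric with non-numeric cells becoming `NA`. A file that cannot be
#' decoded, has no detectable delimiter, or is in an unsupported
#' container (.rtf, .tar) yields an *import-failure record*, not an
#' error, so corpus scans keep going.
#'
#' @param path Path to the file.
#' @return A `mined_table`: list with `source_path`, `status`
#'   (`"ok"`/`"import_failure"`), `reason` (when failed), `data`
#'   (tibble) and `columns` (tibble of `name`, `role`, `metric`).
#' @export
read_processed_table <- function(path) {
  stopifnot(file.exists(path))
  fail <- function(reason) {
    structure(list(source_path = path, status = "import_failure",
                   reason = reason, data = NULL, columns = NULL),
              class = "mined_table")
  }
  ext <- tolower(tools::file_ext(sub("\\.(gz|bz2)$", "", tolower(path))))
  if (ext %in% c("rtf", "tar")) {
    return(fail(sprintf("unsupported container: .%s", ext)))
  }
  dat <- if (ext %in% c("xls", "xlsx")) {
    tryCatch(readxl::read_excel(path, col_types = "text"),
             error = function(e) NULL)
  } else {
    read_delimited_sniffed(path)
  }
  if (is.null(dat) || ncol(dat) < 2L || nrow(dat) == 0L) {
    return(fail("undecodable text or no detectable delimiter"))
  }
  attr(dat, "spec") <- NULL
  attr(dat, "problems") <- NULL
  roles <- assign_column_roles(names(dat))
  numeric_cols <- roles$name[roles$role %in% c("pvalue", "adjusted",
                                               "expression")]
  for (nm in numeric_cols) {
    dat[[nm]] <- suppressWarnings(as.numeric(dat[[nm]]))
  }
  structure(list(source_path = path, status = "ok", reason = NA_character_,
                 data = tibble::as_tibble(dat), columns = roles),
            class = "mined_table")
}

read_delimited_sniffed <- function(path) {
  lines <- tryCatch(
    suppressWarnings(readr::read_lines(path, n_max = 25L,
                                       progress = FALSE)),
    error = function(e) NULL
  )
  if (is.null(lines) || length(lines) == 0L) return(NULL)
  if (any(grepl("[\x01-\x08\x0e-\x1f]", lines, useBytes = TRUE))) {
    return(NULL)
  }
  hits <- vapply(c("\t", ",", ";"), function(d) {
    sum(vapply(strsplit(lines, d, fixed = TRUE), length, integer(1)) - 1L)
  }, numeric(1))
  if (all(hits == 0)) return(NULL)
  delim <- c("\t", ",", ";")[which.max(hits)]
  tryCatch(
    suppressWarnings(readr::read_delim(
      path, delim = delim, col_types = readr::cols(.default = "c"),
      progress = FALSE, show_col_types = FALSE, name_repair = "minimal"
    )),
    error = function(e) NULL
  )
}

#' @export
print.mined_table <- function(x, ...) {
  cat(sprintf("<mined_table> %s [%s]\n", x$source_path, x$status))
  if (x$status == "ok") {
    cat(sprintf("  %d rows, %d columns (%d p-value, %d adjusted, %d expression)\n",
                nrow(x$data), ncol(x$data),
                sum(x$columns$role == "pvalue"),
                sum(x$columns$role == "adjusted"),
                sum(x$columns$role == "expression")))
  } else {
    cat(sprintf("  reason: %s\n", x$reason))
  }
  invisible(x)
}

#' Validate a mined p-value set
#'
#' Disqualifies vectors that are evidently not usable unadjusted
#' p-values: any finite value outside \[0, 1\] (`out_of_range`), no finite
#' values at all (`all_nan`), a significance-filtered export whose
#' maximum falls short of `truncated_max` (`truncated`), or a set piled
#' up against 1 (`right_skewed`: the last decile is the largest of the
#' ten decile bins *and* exceeds the first decile by a one-sided binomial
#' test at `skew_alpha`). Anything else is `ok`.
#'
#' @param values Numeric vector.
#' @param truncated_max Threshold on the maximum for the truncation call
#'   (default 0.9).
#' @param skew_alpha Significance level of the right-skew test (default 1e-3).
#' @return One-row tibble: `status`, `detail`, `n_finite`.
#' @examples
#' validate_pvalue_set(runif(100))$status
#' validate_pvalue_set(runif(100, 0, 0.049))$status  # "truncated"
#' @export
validate_pvalue_set <- function(values, truncated_max = 0.9,
                                skew_alpha = 1e-3) {
  stopifnot(is.numeric(values))
  verdict <- function(status, detail = NA_character_, n = 0L) {
    tibble::tibble(status = status, detail = detail, n_finite = n)
  }
  finite <- values[is.finite(values)]
  n <- length(finite)
  if (n == 0L) {
    return(verdict("all_nan", "no finite values"))
  }
  if (any(finite < 0 | finite > 1)) {
    return(verdict("out_of_range",
                   sprintf("values span [%.3g, %.3g]", min(finite),
                           max(finite)), n))
  }
  if (max(finite) < truncated_max) {
    return(verdict("truncated",
                   sprintf("max p = %.3g < %.3g", max(finite),
                           truncated_max), n))
  }
  dec <- bin_pvalues(finite, bins = 10L)
  first <- dec[1L]; last <- dec[10L]
  if (last == max(dec) && first + last > 0) {
    pbin <- stats::pbinom(last - 1L, first + last, 0.5, lower.tail = FALSE)
    if (pbin < skew_alpha) {
      return(verdict("right_skewed",
                     sprintf("last decile %d vs first %d (p = %.2g)",
                             last, first, pbin), n))
    }
  }
  verdict("ok", n = n)
}

#' Infer the differential-expression analysis tool
#'
#' Free text (file descriptions, articles) is searched first with the
#' tool-name pattern on lower-cased text; when no text evidence exists,
#' column-name heuristics are applied: FPKM-scale expression plus a
#' `p_value` column means cuffdiff; basemean plus `pval` / `pvalue`
#' means DESeq / DESeq2; logcpm means edgeR; aveexpr plus `p.value` and
#' a publication date after 2014-01-01 means limma. Everything else is
#' `"unknown"`.
#'
#' @param x Column names, data frame or `mined_table`.
#' @param pub_date Optional publication date (`Date` or string); required
#'   evidence for the limma heuristic.
#' @param free_text Optional accompanying text.
#' @return One-row tibble: `tool`, `evidence` (`"text_regex"`,
#'   `"column_heuristic"` or `NA` for unknown).
#' @examples
#' infer_de_tool(c("baseMean", "pvalue", "padj"))
#' infer_de_tool(c("logCPM", "PValue", "FDR"))
#' infer_de_tool(character(), free_text = "analysed with Rockhopper v2")
#' @export
infer_de_tool <- function(x, pub_date = NULL, free_text = NULL) {
  label <- function(tool, evidence) {
    tibble::tibble(tool = tool, evidence = evidence)
  }
  if (!is.null(free_text) && any(nzchar(free_text))) {
    txt <- tolower(paste(free_text, collapse = " "))
    m <- regmatches(txt, regexpr(DE_TOOL_TEXT_REGEX, txt, perl = TRUE))
    if (length(m) == 1L) {
      return(label(canonical_tool_name(m), "text_regex"))
    }
  }
  nms <- column_names_of(x)
  roles <- assign_column_roles(nms)
  metrics <- unique(stats::na.omit(roles$metric))
  pcols <- tolower(roles$name[roles$role == "pvalue"])
  recent <- !is.null(pub_date) &&
    as.Date(pub_date) > as.Date("2014-01-01")
  tool <- if (any(c("fpkm", "value") %in% metrics) && "p_value" %in% pcols) {
    "cuffdiff"
  } else if ("basemean" %in% metrics && "pval" %in% pcols) {
    "deseq"
  } else if ("basemean" %in% metrics && "pvalue" %in% pcols) {
    "deseq2"
  } else if ("logcpm" %in% metrics) {
    "edger"
  } else if ("aveexpr" %in% metrics && "p.value" %in% pcols && recent) {
    "limma"
  } else {
    NA_character_
  }
  if (is.na(tool)) {
    label("unknown", NA_character_)
  } else {
    label(tool, "column_heuristic")
  }
}

canonical_tool_name <- function(m) {
  switch(m,
    cufflinks = "cuffdiff",
    voom = "limma",
    m
  )
}

#' Per-group sample size from sample and p-value-set counts
#'
#' For a table carrying `n_pvalue_sets` contrasts over `n_samples`
#' samples, a balanced design implies `n_samples / (n_pvalue_sets + 1)`
#' replicates per group; when that division is not exact the design is
#' unbalanced and the per-group size is undefined (`NA`).
#'
#' @param n_samples Positive integer number of samples.
#' @param n_pvalue_sets Positive integer number of p-value sets.
#' @return One-row tibble: `n_samples`, `n_pvalue_sets`, `per_group_n`
#'   (integer or `NA`).
#' @examples
#' determine_sample_size(6, 1)$per_group_n  # 3
#' determine_sample_size(7, 1)$per_group_n  # NA (unbalanced)
#' @export
determine_sample_size <- function(n_samples, n_pvalue_sets) {
  stopifnot(length(n_samples) == 1L, length(n_pvalue_sets) == 1L)
  if (!is.finite(n_samples) || !is.finite(n_pvalue_sets) ||
      n_samples < 1 || n_pvalue_sets < 1 ||
      n_samples != round(n_samples) || n_pvalue_sets != round(n_pvalue_sets)) {
    stop("`n_samples` and `n_pvalue_sets` must be positive integers",
         call. = FALSE)
  }
  groups <- n_pvalue_sets + 1
  per <- if (n_samples %% groups == 0) {
    as.integer(n_samples / groups)
  } else {
    NA_integer_
  }
  tibble::tibble(n_samples = as.integer(n_samples),
                 n_pvalue_sets = as.integer(n_pvalue_sets),
                 per_group_n = per)
}
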