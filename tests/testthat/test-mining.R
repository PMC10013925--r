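test_that("filename prefilter keeps tabular names and drops the rest", {
  expect_false(filename_passes_prefilter("GSE1_series_matrix.txt.gz"))
  expect_false(filename_passes_prefilter("sample1.bam"))
  expect_false(filename_passes_prefilter("sample1.bed.gz"))
  expect_false(filename_passes_prefilter("genome.fa"))
  expect_false(filename_passes_prefilter("counts.mtx.gz"))
  expect_false(filename_passes_prefilter("GSE2_RAW.tar.gz"))
  expect_false(filename_passes_prefilter("readme.txt"))
  expect_false(filename_passes_prefilter("study_dge.txt.gz"))
  expect_false(filename_passes_prefilter("profile.wig.txt"))
  expect_true(filename_passes_prefilter("deg_results.tsv"))
  expect_true(filename_passes_prefilter("DEG_RESULTS.CSV"))
  expect_true(filename_passes_prefilter("gene_exp.diff"))
  expect_true(filename_passes_prefilter("supplement.xlsx"))
  expect_true(filename_passes_prefilter("results.txt.gz"))
  # vectorised
  expect_equal(
    filename_passes_prefilter(c("a.tsv", "b.bam", "c.unknownext")),
    c(TRUE, FALSE, FALSE)
  )
})

test_that("p-value columns are found and adjusted columns excluded", {
  expect_equal(find_pvalue_columns(c("p_value", "q_value", "padj")),
               "p_value")
  expect_equal(find_pvalue_columns(c("PValue", "FDR")), "PValue")
  expect_equal(find_pvalue_columns(c("log2FC", "baseMean")), character(0))
  expect_equal(find_pvalue_columns(c("pvalue", "adj.P.Val", "p.value",
                                     "fdr_pval", "threshold_pvalue")),
               c("pvalue", "p.value"))
})

test_that("expression columns are tagged with the most specific metric", {
  hit <- find_expression_columns(c("baseMean", "pvalue"))
  expect_equal(hit$name, "baseMean")
  expect_equal(hit$metric, "basemean")

  both <- find_expression_columns(c("value_1", "value_2"))
  expect_equal(both$metric, c("value", "value"))

  expect_equal(find_expression_columns("AveExpr")$metric, "aveexpr")
  expect_equal(find_expression_columns("logCPM")$metric, "logcpm")
  # longest pattern wins when several match
  expect_equal(find_expression_columns("basemean_value")$metric, "basemean")
  # p-value columns are never expression columns, despite containing "value"
  expect_equal(nrow(find_expression_columns(c("p_value", "pvalue"))), 0L)
})

test_that("p-value set validation flags the disqualifying shapes", {
  withr::local_seed(31)
  expect_equal(validate_pvalue_set(c(NA, NaN, NA))$status, "all_nan")
  expect_equal(validate_pvalue_set(runif(200, 0, 0.049))$status, "truncated")
  expect_equal(validate_pvalue_set(c(runif(100), 1.2))$status, "out_of_range")
  expect_equal(validate_pvalue_set(c(runif(100), -0.1))$status, "out_of_range")
  expect_equal(validate_pvalue_set(runif(500))$status, "ok")
  # mass piled against one
  skewed <- c(runif(200), runif(300, 0.92, 1))
  expect_equal(validate_pvalue_set(skewed)$status, "right_skewed")
  # anti-conservative sets are fine
  anti <- c(rbeta(200, 0.3, 1), runif(800))
  expect_equal(validate_pvalue_set(anti)$status, "ok")
  # NaNs alongside valid values are tolerated
  expect_equal(validate_pvalue_set(c(runif(500), rep(NaN, 50)))$status, "ok")
  expect_equal(validate_pvalue_set(c(runif(500), NaN))$n_finite, 500L)
})

test_that("validated-ok sets always lie inside the unit interval", {
  withr::local_seed(32)
  n_ok <- 0L
  for (i in 1:50) {
    v <- if (i %% 2 == 0) runif(100, -0.2, 1.2) else runif(100)
    verdict <- validate_pvalue_set(v)
    fin <- v[is.finite(v)]
    if (verdict$status == "ok") {
      n_ok <- n_ok + 1L
      expect_true(all(fin >= 0 & fin <= 1))
    } else {
      expect_true(verdict$status != "out_of_range" ||
                    any(fin < 0 | fin > 1))
    }
  }
  expect_gt(n_ok, 0L)
})

test_that("DE-tool column heuristics match the known tool dialects", {
  expect_equal(infer_de_tool(c("baseMean", "pvalue", "padj"))$tool, "deseq2")
  expect_equal(infer_de_tool(c("id", "baseMean", "pval", "padj"))$tool,
               "deseq")
  expect_equal(infer_de_tool(c("logFC", "logCPM", "PValue", "FDR"))$tool,
               "edger")
  expect_equal(
    infer_de_tool(c("value_1", "value_2", "p_value", "q_value"))$tool,
    "cuffdiff"
  )
  lim <- c("logFC", "AveExpr", "t", "P.Value", "adj.P.Val")
  expect_equal(infer_de_tool(lim, pub_date = "2016-05-01")$tool, "limma")
  # without a post-2014 date the limma heuristic refuses to fire
  expect_equal(infer_de_tool(lim)$tool, "unknown")
  expect_equal(infer_de_tool(lim, pub_date = "2012-01-01")$tool, "unknown")
  expect_equal(infer_de_tool(c("gene", "p.val"))$tool, "unknown")
})

test_that("free-text evidence outranks column heuristics", {
  lab <- infer_de_tool(c("baseMean", "pvalue"),
                       free_text = "Data were analysed with Rockhopper v2")
  expect_equal(lab$tool, "rockhopper")
  expect_equal(lab$evidence, "text_regex")
  expect_equal(infer_de_tool(character(),
                             free_text = "DESeq2 default settings")$tool,
               "deseq2")
  expect_equal(infer_de_tool(character(),
                             free_text = "normalised, then voom")$tool,
               "limma")
})

test_that("the balanced-design sample-size rule divides exactly or refuses", {
  expect_equal(determine_sample_size(6, 1)$per_group_n, 3L)
  expect_equal(determine_sample_size(2, 1)$per_group_n, 1L)
  expect_true(is.na(determine_sample_size(7, 1)$per_group_n))
  expect_equal(determine_sample_size(12, 3)$per_group_n, 3L)
  expect_error(determine_sample_size(0, 1), "positive")
  expect_error(determine_sample_size(6, -1), "positive")
  expect_error(determine_sample_size(6.5, 1), "positive")
})

test_that("fixtures round-trip through the reader with perfect role recovery", {
  dialects <- c("deseq2", "deseq", "edger", "limma", "cuffdiff", "unknown")
  delims <- c("tab", "comma", "semicolon", "tab", "comma", "semicolon")
  gz <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  for (i in seq_along(dialects)) {
    path <- file.path(withr::local_tempdir(),
                      paste0(dialects[i], ".", switch(delims[i],
                                                      tab = "tsv",
                                                      comma = "csv",
                                                      semicolon = "csv")))
    man <- write_fixture(dialects[i], path, n_rows = 120,
                         delimiter = delims[i], gzip = gz[i],
                         seed = 100 + i)
    tab <- read_processed_table(man$file)
    expect_equal(tab$status, "ok")
    expect_equal(nrow(tab$data), 120)

    # column-role precision and recall against the manifest ground truth
    got <- tab$columns[, c("name", "role")]
    truth <- man$columns[, c("name", "role")]
    expect_equal(got$name, truth$name)
    expect_equal(got$role, truth$role,
                 info = paste("dialect", dialects[i]))

    # tool heuristic accuracy
    expect_equal(infer_de_tool(tab, pub_date = man$pub_date)$tool,
                 man$tool, info = paste("dialect", dialects[i]))
  }
})

test_that("gzip and semicolon dialects parse identically to plain tab", {
  dir <- withr::local_tempdir()
  p <- generate_pvalue_set(80, pi0 = 0.8, seed = 9)$p_value
  m1 <- write_fixture("deseq2", file.path(dir, "a.tsv"), p_values = p,
                      delimiter = "tab", seed = 5)
  m2 <- write_fixture("deseq2", file.path(dir, "b.csv"), p_values = p,
                      delimiter = "semicolon", gzip = TRUE, seed = 5)
  t1 <- read_processed_table(m1$file)
  t2 <- read_processed_table(m2$file)
  expect_equal(t1$data$pvalue, t2$data$pvalue)
  expect_equal(t1$data$baseMean, t2$data$baseMean)
  expect_equal(t1$data$pvalue, p, tolerance = 1e-12)
})

test_that("re-reading a re-written parse yields equal values", {
  dir <- withr::local_tempdir()
  man <- write_fixture("edger", file.path(dir, "e.tsv"), n_rows = 60,
                       seed = 6)
  t1 <- read_processed_table(man$file)
  readr::write_delim(t1$data, file.path(dir, "e2.tsv"), delim = "\t")
  t2 <- read_processed_table(file.path(dir, "e2.tsv"))
  expect_equal(t1$data, t2$data)
})

test_that("binary junk produces an import-failure record, not a crash", {
  dir <- withr::local_tempdir()
  junk <- file.path(dir, "junk.csv")
  writeBin(as.raw(c(1:8, 255, 254, 0, 3, 7)), junk)
  tab <- read_processed_table(junk)
  expect_equal(tab$status, "import_failure")
  rtf <- file.path(dir, "doc.rtf")
  writeLines("{\\rtf1 hello}", rtf)
  expect_equal(read_processed_table(rtf)$status, "import_failure")
})

test_that("manifests honour include_adjusted and n_pvalue_columns", {
  dir <- withr::local_tempdir()
  m <- write_fixture("deseq2", file.path(dir, "noadj.tsv"),
                     include_adjusted = FALSE, n_rows = 50, seed = 7)
  expect_equal(sum(m$columns$role == "adjusted"), 0L)
  m3 <- write_fixture("deseq2", file.path(dir, "multi.tsv"),
                      n_pvalue_columns = 3, n_rows = 50, seed = 8)
  expect_equal(sum(m3$columns$role == "pvalue"), 3L)
  tab <- read_processed_table(m3$file)
  expect_equal(sort(find_pvalue_columns(tab)),
               sort(m3$columns$name[m3$columns$role == "pvalue"]))
})
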