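test_that("bin edges are half-open with the last bin closed", {
  counts <- bin_pvalues(c(0, 0.5, 1), bins = 40)
  expect_equal(which(counts == 1L), c(1L, 21L, 40L))
  expect_equal(sum(counts), 3L)

  # a value on a left edge belongs to the bin it opens
  expect_equal(which(bin_pvalues(0.025, bins = 40) == 1L), 2L)

  mids <- (seq_len(40) - 0.5) / 40
  expect_equal(bin_pvalues(mids, bins = 40), rep(1L, 40))

  expect_equal(sum(bin_pvalues(c(0.3, NA, NaN, 0.7))), 2L)
  expect_error(bin_pvalues(numeric(0)), "non-missing")
  expect_error(bin_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("qc_threshold matches brute-force binomial summation on a grid", {
  for (m in c(1:400, 1999, 2000)) {
    for (bins in c(20, 40, 100)) {
      for (alpha in c(0.01, 0.05)) {
        expect_identical(
          qc_threshold(m, bins, alpha),
          qc_threshold_bruteforce(m, bins, alpha),
          info = sprintf("m=%d bins=%d alpha=%g", m, bins, alpha)
        )
      }
    }
  }
  expect_identical(qc_threshold(20000, 40, 0.05),
                   qc_threshold_bruteforce(20000, 40, 0.05))
})

test_that("a single p-value can never be flagged as a peak", {
  expect_identical(qc_threshold(1, bins = 40), 1L)
})

test_that("qc_threshold is non-decreasing in m", {
  thr <- vapply(1:5000, qc_threshold, integer(1))
  expect_true(all(diff(thr) >= 0L))
})

test_that("classification rules cover the boundary and interior cases", {
  base <- rep(0L, 40)
  flag <- function(idx) {
    counts <- base
    counts[idx] <- 10L
    classify_counts(counts, threshold = 5L)
  }
  expect_equal(classify_counts(base, 5L), "uniform")
  expect_equal(flag(1:3), "anti_conservative")
  expect_equal(flag(1:13), "anti_conservative")   # run length == floor(40/3)
  expect_equal(flag(1:14), "other")               # one past the cap
  expect_equal(flag(38:40), "conservative")
  expect_equal(flag(27:40), "other")
  expect_equal(flag(c(1, 40)), "bimodal")
  expect_equal(flag(c(1:3, 38:40)), "bimodal")
  expect_equal(flag(20), "other")
  expect_equal(flag(c(1, 2, 20)), "other")        # interior run wins
  expect_equal(flag(c(20, 40)), "other")
  expect_equal(flag(1:40), "bimodal")             # one run touching both ends
  expect_error(classify_counts(base, c(1, 2)), "length")
})

test_that("every counts vector receives exactly one of the five classes", {
  withr::local_seed(41)
  for (i in 1:200) {
    counts <- rpois(40, lambda = sample(c(1, 50, 500), 1))
    klass <- classify_counts(counts, threshold = sample(0:600, 1))
    expect_true(klass %in% c("uniform", "anti_conservative", "conservative",
                             "bimodal", "other"))
  }
})

test_that("doubling every count never unflags a flagged bin", {
  withr::local_seed(42)
  for (i in 1:50) {
    m <- sample(50:3000, 1)
    p <- c(runif(round(0.9 * m)), runif(m - round(0.9 * m), 0, 0.05))
    counts <- bin_pvalues(p, bins = 40)
    flagged1 <- which(counts > qc_threshold(sum(counts)))
    counts2 <- 2L * counts
    flagged2 <- which(counts2 > qc_threshold(sum(counts2)))
    expect_true(all(flagged1 %in% flagged2))
  }
})

test_that("malformed generators land in their nominal class", {
  nominal <- c(conservative = "conservative", bimodal = "bimodal",
               hump = "other", spiky = "other")
  for (kind in names(nominal)) {
    hits <- vapply(1:20, function(s) {
      p <- generate_malformed_set(kind, n_features = 20000, seed = 800 + s)
      classify_pvalues(p$p_value)$class == nominal[[kind]]
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("conservative sets keep an unflagged first bin and flagged last bin", {
  p <- generate_malformed_set("conservative", n_features = 20000, seed = 5)
  h <- classify_pvalues(p$p_value)
  expect_false(1L %in% h$flagged_bins)
  expect_true(40L %in% h$flagged_bins)
  expect_gt(h$counts[40], h$qc_threshold)
})

test_that("pure-null sets are nearly always uniform", {
  hits <- vapply(1:50, function(s) {
    p <- generate_pvalue_set(20000, pi0 = 1, seed = 900 + s)$p_value
    classify_pvalues(p)$class == "uniform"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("with no true effects the lowermost bin holds m/B counts on average", {
  first_bin <- vapply(1:100, function(s) {
    p <- generate_pvalue_set(4000, pi0 = 1, seed = 1200 + s)$p_value
    bin_pvalues(p, bins = 40)[1]
  }, integer(1))
  expect_lt(abs(mean(first_bin) - 4000 / 40), 3)
})

test_that("small sets are reported unclassifiable, not guessed", {
  withr::local_seed(7)
  h <- classify_pvalues(runif(20), bins = 40)
  expect_equal(h$class, "unclassifiable")
})

test_that("tidy, glance and autoplot expose the report", {
  withr::local_seed(8)
  h <- classify_pvalues(runif(5000))
  td <- tidy(h)
  expect_equal(nrow(td), 40)
  expect_equal(sum(td$count), 5000)
  expect_equal(td$flagged, td$count > h$qc_threshold)
  g <- glance(h)
  expect_equal(g$class, h$class)
  expect_equal(g$qc_threshold, h$qc_threshold)
  expect_s3_class(ggplot2::autoplot(h), "ggplot")
})
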