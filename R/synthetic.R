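#' Simulate a p-value set from a null/alternative mixture
#'
#' Draws `round(pi0 * n_features)` true-null p-values i.i.d. Uniform(0,1)
#' and the remaining `round((1 - pi0) * n_features)` from an alternative
#' law, then shuffles them. Two alternative models are available:
#'
#' * `"ztest"`: p = 1 - pnorm(z) with z ~ Normal(delta, 1), the one-sided
#'   z-test transform; per-test power at level a is pnorm(delta -
#'   qnorm(1 - a)), which makes calibration of simulation scenarios a
#'   closed-form exercise.
#' * `"beta"`: p ~ Beta(shape1, shape2) with shape1 < 1 <= shape2, a
#'   generic small-p-concentrated law.
#'
#' @param n_features Number of tests (default 20000, the typical
#'   transcriptome-wide scale).
#' @param pi0 Fraction of true nulls in \[0, 1\].
#' @param alt_model `"ztest"` or `"beta"`.
#' @param delta Standardised effect size of the z-test alternative.
#' @param shape1,shape2 Beta alternative parameters (shape1 < 1 <= shape2).
#' @param seed Optional integer seed; when given the output is
#'   bit-reproducible and the global RNG state is left untouched.
#' @return A tibble with columns `p_value` and `true_null` (logical
#'   ground-truth label), with the configuration stored in the
#'   `"config"` attribute.
#' @examples
#' x <- generate_pvalue_set(2000, pi0 = 0.9, delta = 2, seed = 1)
#' sum(!x$true_null)  # exactly round(0.1 * 2000)
#' @export
generate_pvalue_set <- function(n_features = 20000L, pi0,
                                alt_model = c("ztest", "beta"),
                                delta = 2, shape1 = 0.25, shape2 = 1,
                                seed = NULL) {
  alt_model <- match.arg(alt_model)
  if (!is.numeric(pi0) || length(pi0) != 1L || is.na(pi0) ||
      pi0 < 0 || pi0 > 1) {
    stop("`pi0` must be a single number in [0, 1]", call. = FALSE)
  }
  stopifnot(n_features >= 1L)
  if (alt_model == "ztest" && !is.finite(delta)) {
    stop("`delta` must be finite", call. = FALSE)
  }
  if (alt_model == "beta" && !(shape1 < 1 && shape2 >= 1)) {
    stop("beta alternative requires shape1 < 1 <= shape2", call. = FALSE)
  }
  n <- as.integer(n_features)
  k <- as.integer(round((1 - pi0) * n))
  out <- with_seed_if(seed, {
    p_alt <- switch(alt_model,
      ztest = 1 - stats::pnorm(stats::rnorm(k, mean = delta, sd = 1)),
      beta = stats::rbeta(k, shape1, shape2)
    )
    p_null <- stats::runif(n - k)
    ord <- sample.int(n)
    tibble::tibble(
      p_value = c(p_alt, p_null)[ord],
      true_null = c(rep(FALSE, k), rep(TRUE, n - k))[ord]
    )
  })
  attr(out, "config") <- list(
    n_features = n, pi0 = pi0, alt_model = alt_model, delta = delta,
    shape1 = shape1, shape2 = shape2, n_alternatives = k, seed = seed
  )
  out
}

#' Simulate a malformed p-value set
#'
#' Emulates the pathological histogram shapes that discrete tests on
#' low-count data produce in practice:
#'
#' * `"conservative"`: mass piled against 1, including 15% of the values
#'   exactly 1.0 (the ties-at-one artifact of exact tests);
#' * `"bimodal"`: excess mass in both outermost bins;
#' * `"hump"`: a unimodal bump centred well inside (0.2, 0.8);
#' * `"spiky"`: point atoms at a few interior values.
#'
#' At the default 20000 features each shape is classified to its nominal
#' class (`conservative`, `bimodal`, `other`, `other` respectively) by
#' [classify_pvalues()] with near certainty.
#'
#' @param kind One of `"conservative"`, `"bimodal"`, `"hump"`, `"spiky"`.
#' @inheritParams generate_pvalue_set
#' @return A tibble with column `p_value`; the kind is stored in the
#'   `"kind"` attribute.
#' @export
generate_malformed_set <- function(kind = c("conservative", "bimodal",
                                            "hump", "spiky"),
                                   n_features = 20000L, seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n_features)
  stopifnot(n >= 1L)
  p <- with_seed_if(seed, {
    raw <- switch(kind,
      conservative = {
        n1 <- round(0.15 * n); n2 <- round(0.10 * n)
        c(rep(1, n1), stats::runif(n2, 0.9, 1), stats::runif(n - n1 - n2))
      },
      bimodal = {
        n1 <- round(0.12 * n); n2 <- round(0.05 * n); n3 <- round(0.05 * n)
        c(stats::runif(n1, 0, 0.025), rep(1, n2),
          stats::runif(n3, 0.975, 1), stats::runif(n - n1 - n2 - n3))
      },
      hump = {
        n1 <- round(0.2 * n)
        c(stats::rbeta(n1, 20, 20), stats::runif(n - n1))
      },
      spiky = {
        atoms <- c(0.15, 0.35, 0.65)
        n1 <- round(0.18 * n)
        c(rep_len(atoms, n1), stats::runif(n - n1))
      }
    )
    sample(raw)
  })
  out <- tibble::tibble(p_value = p)
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  out
}

#' Simulate a two-group RNA-seq count experiment at the count level
#'
#' Generates negative-binomial counts for two groups, computes
#' library-size factors by median-of-ratios, and tests every feature for
#' differential expression with a self-contained per-feature test:
#'
#' * `n_per_group >= 2`: Welch's t-test on log2(normalised count + 0.5);
#' * `n_per_group == 1`: the exact two-sample Poisson (conditional
#'   binomial) test on the count pair, which yields the discrete p-value
#'   atoms (including exactly 1) that single-pair comparisons produce.
#'
#' A `frac_low_count` fraction of features is drawn with group mean count
#' below ~5 (log2 mean ~ Uniform(-2, 2.3)); the rest with log2 mean ~
#' Uniform(3, 12). With many low-count features the unfiltered p-value
#' set is typically bimodal/conservative/other; removing them restores an
#' anti-conservative shape when true effects are present.
#'
#' Degenerate Welch cases are resolved deterministically: both groups
#' constant and equal gives p = 1 (the discrete-test tie atom); constant
#' but different gives p = 0.
#'
#' @param n_features Number of features (default 20000).
#' @param n_per_group Replicates per group (>= 1).
#' @param frac_de Fraction of truly differentially expressed features.
#' @param log2_fold_change Absolute log2 fold change of DE features; the
#'   sign is drawn per feature (fold changes 2^(+-lfc)), applied to the
#'   group-2 mean.
#' @param frac_low_count Fraction of features with low mean count.
#' @param dispersion Negative-binomial dispersion (> 0; default 0.1).
#' @param expr_log2_range,low_log2_range Ranges of the uniform log2-mean
#'   laws for ordinary and low-count features.
#' @param seed Optional integer seed.
#' @return A tibble with columns `feature_id`, `baseMean` (mean of
#'   library-size-normalised counts over all samples), `pvalue` and
#'   `true_de`; the count matrix, size factors and configuration are
#'   stored in attributes `"counts"`, `"size_factors"` and `"config"`.
#'   The column names deliberately follow the DESeq2 dialect so the
#'   result doubles as a minable processed table.
#' @examples
#' sim <- simulate_count_experiment(2000, n_per_group = 5, frac_de = 0.1,
#'                                  seed = 1)
#' classify_pvalues(sim$pvalue)$class
#' @export
simulate_count_experiment <- function(n_features = 20000L, n_per_group = 3L,
                                      frac_de = 0.1, log2_fold_change = 1,
                                      frac_low_count = 0, dispersion = 0.1,
                                      expr_log2_range = c(3, 12),
                                      low_log2_range = c(-2, 2.3),
                                      seed = NULL) {
  stopifnot(n_features >= 1L, frac_de >= 0, frac_de <= 1,
            frac_low_count >= 0, frac_low_count <= 1, dispersion > 0)
  if (n_per_group < 1L) {
    stop("`n_per_group` must be at least 1", call. = FALSE)
  }
  n <- as.integer(n_features)
  r <- as.integer(n_per_group)
  with_seed_if(seed, {
    n_low <- round(frac_low_count * n)
    low <- c(rep(TRUE, n_low), rep(FALSE, n - n_low))
    log2mu <- ifelse(low,
                     stats::runif(n, low_log2_range[1], low_log2_range[2]),
                     stats::runif(n, expr_log2_range[1], expr_log2_range[2]))
    mu1 <- 2^log2mu
    k <- round(frac_de * n)
    de <- rep(FALSE, n)
    de[sample.int(n, k)] <- TRUE
    lfc <- numeric(n)
    lfc[de] <- sample(c(-1, 1), k, replace = TRUE) * abs(log2_fold_change)
    mu2 <- mu1 * 2^lfc
    size <- 1 / dispersion
    counts <- cbind(
      matrix(stats::rnbinom(n * r, mu = rep(mu1, r), size = size), nrow = n),
      matrix(stats::rnbinom(n * r, mu = rep(mu2, r), size = size), nrow = n)
    )
    colnames(counts) <- c(paste0("g1_s", seq_len(r)), paste0("g2_s", seq_len(r)))
    sf <- size_factors(counts)
    norm <- sweep(counts, 2, sf, "/")
    base_mean <- rowMeans(norm)
    pv <- if (r >= 2L) {
      welch_log2_test(norm, seq_len(r), r + seq_len(r))
    } else {
      poisson_pair_test(counts[, 1L], counts[, 2L], sf[1L], sf[2L])
    }
    out <- tibble::tibble(
      feature_id = sprintf("F%06d", seq_len(n)),
      baseMean = base_mean,
      pvalue = pv,
      true_de = de
    )
    attr(out, "counts") <- counts
    attr(out, "size_factors") <- sf
    attr(out, "config") <- list(
      n_features = n, n_per_group = r, frac_de = frac_de,
      log2_fold_change = log2_fold_change, frac_low_count = frac_low_count,
      dispersion = dispersion, seed = seed
    )
    out
  })
}

# median-of-ratios size factors with a total-count fallback when too few
# features have all-positive counts
size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 100L) {
    libs <- colSums(counts)
    if (all(libs == 0)) return(rep(1, ncol(counts)))
    return(libs / mean(libs))
  }
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2,
        function(x) exp(stats::median(log(x) - logref)))
}

# vectorised Welch t on log2(normalised + 0.5)
welch_log2_test <- function(norm, idx1, idx2) {
  y <- log2(norm + 0.5)
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(y[, idx1, drop = FALSE])
  m2 <- rowMeans(y[, idx2, drop = FALSE])
  v1 <- rowSums((y[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((y[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  p
}

# exact conditional binomial test for a single count pair per feature
poisson_pair_test <- function(x1, x2, sf1, sf2) {
  pr <- sf1 / (sf1 + sf2)
  tot <- x1 + x2
  vapply(seq_along(x1), function(i) {
    n <- tot[i]
    if (n == 0) return(1)
    d <- stats::dbinom(0:n, n, pr)
    min(1, sum(d[d <= d[x1[i] + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}
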