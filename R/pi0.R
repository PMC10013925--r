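#' Proportion of true nulls by the rank-based local-FDR rule
#'
#' Estimates pi0, the fraction of hypotheses for which the null is true,
#' by averaging capped q-values over ranks. With the p-values sorted in
#' decreasing order p_(1) >= ... >= p_(n) and i_j = n + 1 - j the rank
#' from the top, each q_j = min(n p_(j) / i_j, 1) and
#'
#'   pi0 = 2 * sum_j i_j q_j / (n (n + 1)),
#'
#' clamped to \[0, 1\]. On a pure-uniform set every q is close to 1 and the
#' estimate approaches 1; an excess of small p-values pulls it down.
#'
#' @param p Numeric vector of at least two p-values in \[0, 1\]; NAs dropped.
#' @return A single number in \[0, 1\].
#' @examples
#' pi0_lfdr(c(0.01, 0.02, 0.5, 0.8, 1.0))  # 0.77666...
#' pi0_lfdr(rep(1, 10))                    # exactly 1
#' @export
pi0_lfdr <- function(p) {
  p <- check_pvalues(p)
  n <- length(p)
  if (n < 2L) {
    stop("need at least two p-values to estimate pi0", call. = FALSE)
  }
  p <- sort(p, decreasing = TRUE)
  i <- n:1L
  q <- pmin(n * p / i, 1)
  est <- 2 * sum(i * q) / (n * (n + 1))
  min(max(est, 0), 1)
}

#' Proportion of true nulls by Storey's smoother
#'
#' Computes the raw estimates pi0(lambda) = #\{p > lambda\} / (n (1 -
#' lambda)) on a grid of tuning values, fits a cubic smoothing spline
#' with `df` degrees of freedom to the (lambda, pi0(lambda)) pairs, and
#' takes the spline value at the largest lambda, clamped to \[0, 1\]. The
#' comparison `p > lambda` is strict, so ties at the grid points count as
#' "below".
#'
#' @inheritParams pi0_lfdr
#' @param lambda Grid of tuning values in (0, 1); default 0.05 to 0.95 in
#'   steps of 0.05.
#' @param df Degrees of freedom of the smoothing spline (default 3).
#' @return A single number in \[0, 1\]. If every p-value lies below
#'   `min(lambda)` the estimate is 0 and a warning is raised, since the
#'   tail carries no information about the null fraction.
#' @examples
#' set.seed(1)
#' pi0_storey(runif(5000))
#' @export
pi0_storey <- function(p, lambda = seq(0.05, 0.95, by = 0.05), df = 3) {
  p <- check_pvalues(p)
  n <- length(p)
  if (n < 100L) {
    stop("the Storey smoother is unstable below 100 p-values", call. = FALSE)
  }
  stopifnot(length(lambda) >= 4L, all(lambda > 0), all(lambda < 1))
  lambda <- sort(lambda)
  pi0_raw <- vapply(lambda, function(l) sum(p > l) / (n * (1 - l)), numeric(1))
  if (all(pi0_raw == 0)) {
    warning("all p-values lie below min(lambda); pi0 estimated as 0",
            call. = FALSE)
    return(0)
  }
  fit <- stats::smooth.spline(lambda, pi0_raw, df = df)
  est <- stats::predict(fit, x = max(lambda))$y
  min(max(est, 0), 1)
}

#' Estimate pi0 by one or both methods
#'
#' Tidy wrapper around [pi0_lfdr()] and [pi0_storey()].
#'
#' @inheritParams pi0_storey
#' @param method Character vector of methods to run.
#' @return A tibble with one row per method: `method`, `pi0`, `n`.
#' @examples
#' set.seed(1)
#' estimate_pi0(runif(2000))
#' @export
estimate_pi0 <- function(p, method = c("lfdr", "storey"),
                         lambda = seq(0.05, 0.95, by = 0.05), df = 3) {
  method <- match.arg(method, c("lfdr", "storey"), several.ok = TRUE)
  p <- check_pvalues(p)
  purrr::map_dfr(method, function(m) {
    est <- switch(m,
      lfdr = pi0_lfdr(p),
      storey = pi0_storey(p, lambda = lambda, df = df)
    )
    tibble::tibble(method = m, pi0 = est, n = length(p))
  })
}

#' Compare the two pi0 estimators across a collection of sets
#'
#' Runs both estimators on every p-value set and reports the paired
#' estimates together with their per-method means and the mean
#' difference.
#'
#' @param sets A list of numeric p-value vectors (optionally named), or a
#'   data frame with columns `set` and `p_value`.
#' @inheritParams pi0_storey
#' @return A tibble with columns `set`, `n`, `pi0_lfdr`, `pi0_storey` and
#'   `diff`, carrying a `"summary"` attribute (one-row tibble of means).
#' @export
compare_pi0_methods <- function(sets, lambda = seq(0.05, 0.95, by = 0.05),
                                df = 3) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("set", "p_value") %in% names(sets)))
    sets <- split(sets$p_value, sets$set)
  }
  stopifnot(is.list(sets), length(sets) >= 1L)
  ids <- names(sets)
  if (is.null(ids)) ids <- as.character(seq_along(sets))
  out <- purrr::map2_dfr(sets, ids, function(p, id) {
    p <- check_pvalues(p)
    tibble::tibble(
      set = id, n = length(p),
      pi0_lfdr = pi0_lfdr(p),
      pi0_storey = pi0_storey(p, lambda = lambda, df = df)
    )
  })
  out$diff <- out$pi0_lfdr - out$pi0_storey
  attr(out, "summary") <- tibble::tibble(
    mean_lfdr = mean(out$pi0_lfdr),
    mean_storey = mean(out$pi0_storey),
    mean_diff = mean(out$diff)
  )
  out
}

# drop NAs, enforce [0, 1]
check_pvalues <- function(p) {
  stopifnot(is.numeric(p))
  p <- p[is.finite(p)]
  if (length(p) == 0L) {
    stop("no finite p-values", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p
}
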