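#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment used throughout the pipeline (differential regions,
#' differential expression, optional adjustment of stratified panels).
#' Implemented directly so that downstream contracts (`fdr >= p`,
#' monotonicity in the p-value order) are owned by the package.
#'
#' @param p numeric vector of p-values in \[0, 1\]. `NA`s are propagated.
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.9))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  n <- length(pp)
  if (n == 0L) return(out)
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * pp[o]))[ro]
  out[ok] <- adj
  out
}

#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Rank comparison used for every stratified panel (signal change, occupancy,
#' expression fold change or region attributes by group). For small samples
#' without too many arrangements the exact two-sided p-value is computed by
#' full enumeration of group assignments (ties handled naturally); otherwise
#' the normal approximation with tie correction is used, without continuity
#' correction so that null p-values are close to uniform at the group sizes
#' the pipeline produces.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the enumeration path;
#'   `NULL` (default) enumerates when both groups have at most 20 values and
#'   the number of arrangements is at most 2e5.
#' @return list with `statistic` (U for the `x` group), `p`, and `method`.
#' @examples
#' rank_sum_test(c(1.2, 3.4, 2.2), c(5.1, 4.8, 6.0))
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  use_exact <- if (is.null(exact)) {
    max(n1, n2) <= 20 && choose(n1 + n2, n1) <= 2e5
  } else exact
  if (use_exact) {
    combs <- utils::combn(n1 + n2, n1)
    rs <- colSums(matrix(r[combs], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
    return(list(statistic = u_obs, p = p, method = "exact enumeration"))
  }
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(statistic = u_obs, p = 1, method = "degenerate"))
  z <- (u_obs - mu) / sqrt(sigma2)
  list(statistic = u_obs, p = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation, tie-corrected")
}

#' Welch two-sample t-test with degeneracy handling
#'
#' Thin vector interface over the Welch (or pooled-variance) t-test used for
#' PTM ratios and expression-by-vital-status comparisons. Zero-variance
#' identical groups are flagged (`degenerate = TRUE`, `p = NA`) rather than
#' reported as p = 0.
#'
#' @param x,y numeric vectors.
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
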