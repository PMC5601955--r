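# Configuration-comparison statistics: per-metric mean (SE) summaries and
# exact nonparametric tests with Bonferroni correction. Exact p-values use
# the permutation null (signed-rank: all sign assignments of the nonzero
# differences; rank-sum: all subsets of the combined mid-ranks), two-sided by
# doubling the smaller tail and capping at 1. Ties get mid-ranks; zero
# differences are dropped (Pratt-style exclusion) with a warning.

#' Per-metric mean and standard error
#'
#' @param table data.frame or matrix; rows = subjects (or seeds), columns =
#'   metrics
#' @return data.frame with `metric`, `mean`, `se`, `n`; SE is the sample SD
#'   (n-1 denominator) over sqrt(n), `NA` for a single row
#' @export
summarize_metrics <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) == 0) stop_invalid("table", "needs at least one row")
  data.frame(
    metric = colnames(x) %||% paste0("V", seq_len(ncol(x))),
    mean = colMeans(x, na.rm = TRUE),
    se = apply(x, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    }),
    n = apply(x, 2, function(v) sum(!is.na(v))),
    row.names = NULL)
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided p-value for the paired comparison `a` vs `b`. Zero differences
#' are dropped (with a warning; `p = 1` if nothing remains); absolute
#' differences receive mid-ranks. For up to `max_exact` nonzero differences
#' the null distribution of the positive-rank sum is enumerated exactly over
#' all 2^n sign assignments (via its generating polynomial); beyond that a
#' normal approximation with tie correction is used. The two-sided p doubles
#' the smaller tail, capped at 1.
#'
#' @param a,b equal-length numeric vectors of paired observations
#' @param max_exact largest n for exact enumeration (default 25)
#' @return list with `p`, `statistic` (positive-rank sum `V`), `n` (nonzero
#'   differences), `exact`
#' @export
wilcoxon_signed_rank <- function(a, b, max_exact = 25) {
  if (length(a) != length(b)) stop_invalid("b", "must have the same length as a")
  if (length(a) == 0) stop_invalid("a", "must be non-empty")
  d <- a - b
  if (any(d == 0)) {
    warning(sprintf("%d zero difference(s) dropped", sum(d == 0)))
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0) return(list(p = 1, statistic = NA_real_, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= max_exact) {
    # distribution of V over all sign assignments; ranks doubled so mid-ranks
    # become integers
    r2 <- round(2 * r)
    counts <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts)
      counts <- c(counts, rep(0, ri)) + shifted
    }
    total <- 2^n
    sums <- seq_along(counts) - 1 # support of 2V
    v2 <- round(2 * v)
    p_lo <- sum(counts[sums <= v2]) / total
    p_hi <- sum(counts[sums >= v2]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(p = p, statistic = v, n = as.integer(n), exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu) / sqrt(sigma2)
  list(p = min(1, 2 * stats::pnorm(-abs(z))), statistic = v,
       n = as.integer(n), exact = FALSE)
}

#' Exact Wilcoxon rank-sum test for independent samples
#'
#' Two-sided p-value for independent samples `a` and `b`. Combined
#' observations receive mid-ranks; for `length(a) + length(b) <= max_exact`
#' the permutation null of the rank sum of `a` is enumerated exactly (subset
#' generating polynomial), otherwise a normal approximation with tie
#' correction is used. Two size-6 samples with complete separation attain
#' the smallest exact p: `2 / choose(12, 6) = 0.00216...`, i.e. 0.002 at
#' three decimals.
#'
#' @param a,b non-empty numeric vectors
#' @param max_exact largest combined size for exact enumeration (default 20)
#' @return list with `p`, `statistic` (rank sum of `a`), `n` (`c(na, nb)`),
#'   `exact`
#' @export
wilcoxon_rank_sum <- function(a, b, max_exact = 20) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop_invalid("a", "both samples must be non-empty")
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  n <- na + nb
  if (n <= max_exact) {
    r2 <- round(2 * r)
    # dp[[k]] = counts over 2*ranksum of subsets of size k
    max_sum <- sum(r2)
    dp <- matrix(0, na + 1, max_sum + 1)
    dp[1, 1] <- 1
    for (ri in r2) {
      kmax <- min(na, nrow(dp) - 1)
      for (k in seq(kmax, 1)) {
        nz <- which(dp[k, ] > 0)
        if (length(nz)) dp[k + 1, nz + ri] <- dp[k + 1, nz + ri] + dp[k, nz]
      }
    }
    counts <- dp[na + 1, ]
    total <- choose(n, na)
    sums <- seq_along(counts) - 1
    w2 <- round(2 * w)
    p_lo <- sum(counts[sums <= w2]) / total
    p_hi <- sum(counts[sums >= w2]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(p = p, statistic = w, n = c(na, nb), exact = TRUE))
  }
  mu <- na * (n + 1) / 2
  tie_tab <- table(r)
  sigma2 <- na * nb / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (w - mu) / sqrt(sigma2)
  list(p = min(1, 2 * stats::pnorm(-abs(z))), statistic = w,
       n = c(na, nb), exact = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p vector of raw p-values
#' @param m family size (>= `length(p)`)
#' @return adjusted p-values `pmin(1, m * p)`
#' @export
bonferroni <- function(p, m) {
  check_scalar_num(m, "m", lower = 1, integer = TRUE)
  if (m < length(p))
    stop_invalid("m", sprintf("family size %d smaller than the %d p-values supplied",
                              m, length(p)))
  pmin(1, m * p)
}

#' Compare two configuration conditions metric by metric
#'
#' Runs the appropriate Wilcoxon test (signed-rank for paired conditions
#' measured on the same subjects, rank-sum for independent groups) on every
#' shared metric column, then applies Bonferroni correction over the family.
#'
#' @param table_a,table_b data.frames, rows = subjects, columns = metrics;
#'   for `paired = TRUE` the rows must align subject-by-subject
#' @param paired use the signed-rank test (default) or the rank-sum test
#' @param m Bonferroni family size; defaults to the number of shared metrics
#' @param alpha significance level after correction (default 0.05)
#' @return data.frame with `metric`, `test`, `statistic`, `p_raw`,
#'   `p_adjusted`, `significant`
#' @export
compare_conditions <- function(table_a, table_b, paired = TRUE, m = NULL,
                               alpha = 0.05) {
  metrics <- intersect(colnames(table_a), colnames(table_b))
  if (length(metrics) == 0) stop_invalid("table_b", "no shared metric columns")
  m <- m %||% length(metrics)
  rows <- lapply(metrics, function(mt) {
    va <- table_a[[mt]]; vb <- table_b[[mt]]
    ok <- if (paired) !is.na(va) & !is.na(vb) else TRUE
    res <- if (paired) wilcoxon_signed_rank(va[ok], vb[ok])
           else wilcoxon_rank_sum(va[!is.na(va)], vb[!is.na(vb)])
    data.frame(metric = mt,
               test = if (paired) "signed_rank" else "rank_sum",
               statistic = res$statistic, p_raw = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw, m)
  out$m <- m
  out$significant <- out$p_adjusted < alpha
  out
}
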