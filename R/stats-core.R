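#' Benjamini-Hochberg adjusted p-values (step-up)
#'
#' Computes BH q-values: `q_i` is the smallest value of `m * p_(j) / j` over
#' all order statistics `p_(j) >= p_i`, capped at 1. Rejecting all features
#' with `q < alpha` controls the false discovery rate at `alpha` under
#' independence (and positive dependence).
#'
#' @param p numeric vector of p-values, all in `[0, 1]`, no missing values.
#' @return numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  check_pvalues(p)
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  # step-up: cumulative minimum of m * p_(j) / j from the largest p downwards
  q_desc <- cummin(m / seq.int(m, 1L) * p[ord])
  q <- numeric(m)
  q[ord] <- pmin(1, q_desc)
  q
}

check_pvalues <- function(p) {
  if (anyNA(p)) stop("p-values contain missing values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  invisible(p)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion from beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes number of successes (0..n).
#' @param n number of trials, positive.
#' @param level confidence level in (0, 1); default 0.95.
#' @return named numeric vector `c(lower, upper)` of proportions.
#' @examples
#' clopper_pearson_ci(75, 85)   # the 88% origin call: (0.79, 0.94)
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be positive")
  if (successes < 0 || successes > n) stop("successes must be in 0..n")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided exact test by full enumeration of all tables with the observed
#' margins (Freeman-Halton): the p-value is the total conditional
#' (multivariate hypergeometric) probability of tables no more probable than
#' the observed one. No asymptotic fallback is provided; tables whose total
#' exceeds `max_total` raise an error.
#'
#' All-zero rows and columns carry no probability mass and are dropped
#' before enumeration.
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2 after
#'   dropping all-zero margins.
#' @param max_total enumeration cap on the table total (default 500).
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
fisher_exact <- function(tab, max_total = 500) {
  tab <- as.matrix(tab)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("table must contain non-negative integer counts")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2 x 2 after dropping all-zero rows/columns")
  n <- sum(tab)
  if (n > max_total)
    stop("table total ", n, " exceeds the enumeration cap (", max_total,
         "); exact enumeration unsupported at this size")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  logp_obs <- table_logprob(tab, rs, cs)
  # relative tolerance as in the classical implementations: count tables with
  # probability <= observed * (1 + eps) to absorb floating-point ties
  tol <- logp_obs + log1p(1e-7)
  total <- enumerate_tables_mass(rs, cs, tol)
  min(1, total)
}

# log conditional probability of a table given margins
table_logprob <- function(tab, rs = rowSums(tab), cs = colSums(tab)) {
  n <- sum(rs)
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) - sum(lgamma(tab + 1))
}

# Depth-first enumeration over all tables with fixed margins, accumulating
# exp(logprob) for tables with logprob <= tol. Rows are filled one at a time;
# the last row is forced by the column margins.
enumerate_tables_mass <- function(rs, cs, tol) {
  r <- length(rs)
  n <- sum(rs)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  total <- 0
  fill_row <- function(i, rem_cols, logfact_acc) {
    if (i == r) {
      lp <- const - logfact_acc - sum(lgamma(rem_cols + 1))
      if (lp <= tol) total <<- total + exp(lp)
      return(invisible())
    }
    for (row in row_compositions(rs[i], rem_cols)) {
      fill_row(i + 1L, rem_cols - row, logfact_acc + sum(lgamma(row + 1)))
    }
    invisible()
  }
  fill_row(1L, cs, 0)
  total
}

# all ways to write total as c non-negative cells bounded by caps
row_compositions <- function(total, caps) {
  c_ <- length(caps)
  out <- list()
  cell <- integer(c_)
  rec <- function(j, rem) {
    if (j == c_) {
      if (rem <= caps[j]) {
        cell[j] <<- rem
        out[[length(out) + 1L]] <<- cell
      }
      return(invisible())
    }
    hi <- min(caps[j], rem)
    lo <- max(0L, rem - sum(caps[(j + 1L):c_]))
    if (hi >= lo) for (v in lo:hi) {
      cell[j] <<- v
      rec(j + 1L, rem - v)
    }
    invisible()
  }
  rec(1L, total)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#' Invariant under strictly monotone transforms of either argument.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant vector after ranking")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Two-sample t test
#'
#' Two-sided t test of a difference in means; Welch (default) or pooled
#' variance. When both groups have zero variance and equal means the
#' statistic is defined as 0 with p = 1 (convention for constant features);
#' with unequal constant means the statistic is signed infinite with p = 0.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return list with elements `t`, `p`, `df`, `diff` (mean of `x` minus
#'   mean of `y`).
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  if (variant == "welch") {
    se2 <- vx / nx + vy / ny
    df <- if (se2 > 0) se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)) else nx + ny - 2
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- nx + ny - 2
  }
  if (se2 == 0) {
    if (d == 0) return(list(t = 0, p = 1, df = df, diff = 0))
    return(list(t = sign(d) * Inf, p = 0, df = df, diff = d))
  }
  tstat <- d / sqrt(se2)
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df, diff = d)
}

#' Row-wise two-sample t tests
#'
#' Vectorized form of [two_sample_t()] applied to every row of a matrix,
#' used by the class-comparison and power-simulation stages. Rows with zero
#' variance in both groups get `t = 0`, `p = 1` when the group means agree
#' (`p = 0` otherwise).
#'
#' @param m numeric matrix (features x samples).
#' @param idx1,idx2 column indices of the two groups (each >= 2 columns).
#' @param variant `"welch"` or `"pooled"`.
#' @return data.frame with columns `diff`, `t`, `df`, `p`, one row per row
#'   of `m`.
#' @export
row_t_test <- function(m, idx1, idx2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(idx1) < 2L || length(idx2) < 2L) stop("each group needs >= 2 samples")
  x <- m[, idx1, drop = FALSE]
  y <- m[, idx2, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  d <- mx - my
  if (variant == "welch") {
    se2 <- vx / nx + vy / ny
    df <- ifelse(se2 > 0,
                 se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
                 nx + ny - 2)
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- rep.int(nx + ny - 2, nrow(m))
  }
  tstat <- ifelse(se2 > 0, d / sqrt(se2), 0)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), as.numeric(d == 0))
  tstat[se2 == 0 & d != 0] <- sign(d[se2 == 0 & d != 0]) * Inf
  data.frame(diff = d, t = tstat, df = df, p = p, row.names = rownames(m))
}
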