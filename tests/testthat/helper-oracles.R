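# Independent oracles, deliberately written against the definitions rather
# than sharing code paths with the package.

# BH step-up from the definition: q_i = min over j with p_(j) >= p_i of
# m * p_(j) / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vals <- m * sp / seq_len(m)
  vapply(p, function(pi) min(1, min(vals[sp >= pi])), numeric(1))
}

# Freeman-Halton by exhaustive enumeration over the free (r-1) x (c-1)
# cells, keeping matrices whose margins match; probabilities via factorials
# (safe for small totals).
brute_fisher <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(m) prod(factorial(rs)) * prod(factorial(cs)) /
    (factorial(n) * prod(factorial(m)))
  r <- nrow(tab); cc <- ncol(tab)
  free <- expand.grid(rep(list(0:max(rs)), (r - 1) * (cc - 1)))
  p_obs <- prob(tab)
  total <- 0
  for (i in seq_len(nrow(free))) {
    m <- matrix(0, r, cc)
    m[seq_len(r - 1), seq_len(cc - 1)] <- unlist(free[i, ])
    m[r, seq_len(cc - 1)] <- cs[seq_len(cc - 1)] - colSums(m[seq_len(r - 1), , drop = FALSE])[seq_len(cc - 1)]
    m[, cc] <- rs - rowSums(m[, seq_len(cc - 1), drop = FALSE])
    if (any(m < 0)) next
    pm <- prob(m)
    if (pm <= p_obs * (1 + 1e-7)) total <- total + pm
  }
  min(1, total)
}

# Spearman by explicit rank transform then textbook Pearson formula.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  (sum(rx * ry) - n * mean(rx) * mean(ry)) /
    ((n - 1) * sd(rx) * sd(ry))
}

# Floor-and-ratio assignment rule, evaluated per subtype as a predicate:
# subtype i wins iff it clears the floor, is the unique maximum among
# candidates, and dominates every other candidate by the ratio.
oracle_rule <- function(r, floor, ratio) {
  cand <- which(r > floor)
  if (length(cand) == 0L) return("UNASSIGNED")
  if (length(cand) == 1L) return(names(r)[cand])
  winners <- Filter(function(i) {
    others <- setdiff(cand, i)
    all(r[i] > r[others]) && all(r[i] >= ratio * r[others])
  }, cand)
  if (length(winners) == 1L) names(r)[winners[[1]]] else "UNASSIGNED"
}

# Average-power BH fixed point by brute-force grid scan over alpha.
brute_power_fixed_point <- function(effect_sd, n, n_genes, n_de, fdr) {
  df <- 2 * n - 2
  ncp <- effect_sd * sqrt(n / 2)
  pow <- function(a) {
    q <- qt(1 - a / 2, df)
    pt(-q, df, ncp) + pt(q, df, ncp, lower.tail = FALSE)
  }
  gap <- function(a) a - fdr * (n_de * pow(a) + (n_genes - n_de) * a) / n_genes
  grid <- 10^seq(-8, log10(fdr), length.out = 20000)
  g <- vapply(grid, gap, numeric(1))
  i <- which(diff(sign(g)) != 0)[1]
  root <- uniroot(gap, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  pow(root)
}

make_log_em <- function(values, ...) {
  expression_matrix(values, "log_normalized", ...)
}
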