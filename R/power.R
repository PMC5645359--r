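#' Power by simulation for FDR-controlled differential expression
#'
#' The design calculation for a two-group expression study: per replicate,
#' `n_genes` independent unit-variance Gaussian genes are drawn for two
#' groups, `n_de` of them shifted by `effect_sd` in group 1; per-gene
#' two-sample t tests (pooled variance, matching the analytic oracle's
#' `2n - 2` degrees of freedom) are adjusted by Benjamini-Hochberg and
#' discoveries counted at `q < fdr_level`. Sensitivity (the fraction of
#' true effect genes discovered) and the realized false discovery
#' proportion are averaged over replicates per grid cell.
#'
#' @param n_genes genes simulated per replicate (default 20000).
#' @param n_de genes carrying a true effect (default 50).
#' @param effect_sd effect sizes in s.d. units (default grid
#'   `c(0.75, 1, 1.25, 1.5)`).
#' @param n_per_group samples per group (default grid `c(40, 45, 50)`).
#' @param fdr_level BH level (default 0.10).
#' @param reps replicates per grid cell (default 20).
#' @param seed RNG seed.
#' @return data.frame per (effect_sd, n_per_group) cell: `sensitivity`,
#'   `se` (Monte-Carlo standard error of the sensitivity), `fdr`
#'   (realized false discovery proportion, mean over reps), `fdr_se`,
#'   `n_false` (mean false discoveries), `reps`.
#' @export
simulate_power <- function(n_genes = 20000, n_de = 50,
                           effect_sd = c(0.75, 1, 1.25, 1.5),
                           n_per_group = c(40, 45, 50),
                           fdr_level = 0.10, reps = 20, seed = 17) {
  if (reps < 1) stop("reps must be >= 1")
  if (n_de > n_genes || n_de < 0) stop("n_de must lie in 0..n_genes")
  if (any(effect_sd < 0)) stop("effect_sd must be >= 0")
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must lie in (0, 1)")
  grid <- expand.grid(effect_sd = effect_sd, n_per_group = n_per_group,
                      KEEP.OUT.ATTRS = FALSE)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(g) {
      eff <- grid$effect_sd[g]; n <- grid$n_per_group[g]
      # with a zero effect there are no true positives: every discovery is false
      n_true <- if (eff > 0) n_de else 0L
      sens <- fdp <- nfalse <- numeric(reps)
      for (r in seq_len(reps)) {
        m <- matrix(stats::rnorm(n_genes * 2 * n), n_genes, 2 * n)
        if (n_de > 0) m[seq_len(n_de), seq_len(n)] <- m[seq_len(n_de), seq_len(n)] + eff
        tt <- row_t_test(m, seq_len(n), n + seq_len(n), variant = "pooled")
        q <- bh_adjust(tt$p)
        disc <- q < fdr_level
        sens[r] <- if (n_true > 0) mean(disc[seq_len(n_true)]) else 0
        nfalse[r] <- sum(disc) - (if (n_true > 0) sum(disc[seq_len(n_true)]) else 0)
        fdp[r] <- if (any(disc)) nfalse[r] / sum(disc) else 0
      }
      data.frame(effect_sd = eff, n_per_group = n,
                 sensitivity = mean(sens),
                 se = stats::sd(sens) / sqrt(reps),
                 fdr = mean(fdp), fdr_se = stats::sd(fdp) / sqrt(reps),
                 n_false = mean(nfalse), reps = reps)
    })
  })
  do.call(rbind, rows)
}

#' Closed-form fixed-point approximation of average BH power
#'
#' Independent check on [simulate_power()]: in the large-`m` limit the BH
#' step-up threshold converges to the solution of
#' `alpha = fdr_level * R(alpha) / m` with
#' `R(alpha) = n_de * power(alpha) + (m - n_de) * alpha`, where
#' `power(alpha)` is the two-sided rejection probability of a t test with
#' `2n - 2` degrees of freedom and noncentrality
#' `effect_sd * sqrt(n / 2)`. The returned sensitivity is `power` at the
#' fixed point.
#'
#' @param effect_sd effect size in s.d. units.
#' @param n_per_group samples per group.
#' @param n_genes,n_de,fdr_level as in [simulate_power()].
#' @param tol,max_iter fixed-point convergence control.
#' @return approximate sensitivity in `[0, 1]`.
#' @export
analytic_power_oracle <- function(effect_sd, n_per_group, n_genes = 20000,
                                  n_de = 50, fdr_level = 0.10,
                                  tol = 1e-12, max_iter = 10000) {
  df <- 2 * n_per_group - 2
  ncp <- effect_sd * sqrt(n_per_group / 2)
  pow <- function(alpha) {
    qcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-qcrit, df, ncp) + stats::pt(qcrit, df, ncp, lower.tail = FALSE)
  }
  alpha <- fdr_level * n_de / n_genes
  for (i in seq_len(max_iter)) {
    r <- n_de * pow(alpha) + (n_genes - n_de) * alpha
    alpha_new <- fdr_level * r / n_genes
    if (abs(alpha_new - alpha) < tol) return(pow(alpha_new))
    alpha <- alpha_new
  }
  stop("fixed point did not converge after ", max_iter,
       " iterations (last alpha = ", signif(alpha, 6), ")")
}
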