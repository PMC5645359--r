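#' Derive a tissue-of-origin signature from normal pools
#'
#' For each tissue, a one-versus-rest two-sample t test (Welch) on
#' log-normalized values ranks genes by ascending p, breaking ties by
#' descending absolute mean difference and then gene id. The top `top_n`
#' genes per tissue are combined into a deduplicated union — the tissue
#' "barcode" — and a prototype profile per tissue (mean over its pools) is
#' recorded over that union.
#'
#' @param normals `expr_matrix` in `log_normalized` state with a `tissue`
#'   annotation; exactly three tissues, each with >= 2 pools.
#' @param top_n markers kept per tissue (default 50).
#' @return a `tissue_signature`: list with `markers` (ranked list per
#'   tissue), `genes` (combined union), `prototypes` (union genes x
#'   tissues), `meta` (test, ranking rule, top_n).
#' @export
derive_tissue_signature <- function(normals, top_n = 50) {
  if (top_n < 1) stop("top_n must be >= 1")
  ovr <- one_vs_rest_tests(normals)
  markers <- lapply(ovr, function(res) {
    ord <- order(res$p, -abs(res$diff), res$gene)
    res$gene[ord][seq_len(min(top_n, nrow(res)))]
  })
  genes <- unique(unlist(markers, use.names = FALSE))
  tissue <- normals$samples$tissue
  proto <- vapply(names(ovr), function(tt)
    rowMeans(normals$values[genes, tissue == tt, drop = FALSE]),
    numeric(length(genes)))
  rownames(proto) <- genes
  if (any(apply(proto, 2, stats::sd) == 0))
    stop("constant prototype over the combined signature; degenerate input")
  structure(list(markers = markers, genes = genes, prototypes = proto,
                 pool_values = normals$values[genes, , drop = FALSE],
                 pool_tissue = tissue,
                 meta = list(test = "welch_t_one_vs_rest",
                             ranking = "p_then_abs_diff_then_gene",
                             top_n = top_n)),
            class = "tissue_signature")
}

one_vs_rest_tests <- function(normals) {
  stopifnot_state(normals, "log_normalized")
  tissue <- normals$samples$tissue
  if (is.null(tissue)) stop("normals must carry a 'tissue' annotation")
  tissues <- sort(unique(tissue))
  if (length(tissues) != 3L)
    stop("expected three tissues, got: ", paste(tissues, collapse = ", "))
  small <- names(which(table(tissue) < 2))
  if (length(small))
    stop("tissue(s) with < 2 pools: ", paste(small, collapse = ", "))
  stats::setNames(lapply(tissues, function(tt) {
    res <- row_t_test(normals$values, which(tissue == tt), which(tissue != tt))
    data.frame(gene = rownames(normals$values), diff = res$diff, p = res$p,
               q = bh_adjust(res$p), stringsAsFactors = FALSE)
  }), tissues)
}

#' Count tissue-specific differentially expressed genes
#'
#' One-versus-rest comparison per tissue with BH adjustment; returns the
#' number of genes at q < `alpha` for each tissue — the quantity behind
#' the strong fallopian-tube versus ovarian/peritoneal asymmetry in
#' tissue-specific expression programs.
#'
#' @param normals as in [derive_tissue_signature()].
#' @param alpha BH q-value threshold in (0, 1) (default 0.05).
#' @return named integer vector of DE gene counts per tissue.
#' @export
count_tissue_de <- function(normals, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  vapply(one_vs_rest_tests(normals), function(res) sum(res$q < alpha), integer(1))
}

#' Match tumors to normal tissues by Spearman correlation
#'
#' Computes the Spearman correlation between each tumor profile and each
#' tissue prototype over the combined signature gene set, calls the
#' best-correlated tissue (ties broken by the fixed priority
#' FT > OV > PER, with a warning), and records the pairwise
#' fallopian-tube versus ovary winner separately.
#'
#' @param tumors `expr_matrix` in `log_normalized` state covering the
#'   signature genes.
#' @param sig a `tissue_signature`.
#' @param aggregate `"prototype"` (default): correlate each tumor with the
#'   per-tissue mean profile; `"correlate_then_average"`: correlate with
#'   every individual pool and average the correlations within tissue.
#' @return a `tissue_assignments` data.frame: `sample_id`, `rho_<tissue>`
#'   columns, `call`, `ft_better_than_ov` (logical).
#' @export
match_tissue <- function(tumors, sig,
                         aggregate = c("prototype", "correlate_then_average")) {
  aggregate <- match.arg(aggregate)
  stopifnot_state(tumors, "log_normalized")
  tissues <- colnames(sig$prototypes)
  missing <- setdiff(sig$genes, rownames(tumors$values))
  if (length(missing))
    stop("signature genes absent from tumor matrix: ",
         paste(missing, collapse = ", "))
  m <- tumors$values[sig$genes, , drop = FALSE]
  priority <- intersect(c("FT", "OV", "PER"), tissues)
  priority <- c(priority, setdiff(tissues, priority))
  tissue_rho <- function(x, tt) {
    if (aggregate == "prototype")
      return(spearman_rho(x, sig$prototypes[, tt]))
    pools <- which(sig$pool_tissue == tt)
    mean(vapply(pools, function(j) spearman_rho(x, sig$pool_values[, j]),
                numeric(1)))
  }
  rho <- t(apply(m, 2, function(x)
    vapply(tissues, function(tt) tissue_rho(x, tt), numeric(1))))
  colnames(rho) <- paste0("rho_", tissues)
  call <- apply(rho, 1, function(r) {
    best <- tissues[r == max(r)]
    if (length(best) > 1L) {
      warning("correlation tie; broken by tissue priority")
      best <- priority[priority %in% best][1]
    }
    best
  })
  out <- data.frame(sample_id = colnames(m), rho, call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (all(c("FT", "OV") %in% tissues))
    out$ft_better_than_ov <- out$rho_FT > out$rho_OV
  class(out) <- c("tissue_assignments", "data.frame")
  out
}

#' Summarize the tissue-of-origin call for a cohort
#'
#' Reports the proportion of tumors better correlated with fallopian tube
#' than with ovarian tissue, with an exact (Clopper-Pearson) 95%
#' confidence interval, plus the mean Spearman correlation to each tissue
#' over the combined signature set.
#'
#' @param assignments a `tissue_assignments` data.frame from
#'   [match_tissue()] (>= 1 row, with FT and OV correlations).
#' @param level confidence level (default 0.95).
#' @return list with `n`, `n_ft_better`, `proportion`, `ci` (lower/upper
#'   proportions), `mean_rho` (named per tissue), `call_counts`.
#' @export
summarize_origin <- function(assignments, level = 0.95) {
  if (nrow(assignments) == 0L) stop("empty assignment table")
  if (is.null(assignments$ft_better_than_ov))
    stop("assignments lack the FT-vs-OV comparison")
  n <- nrow(assignments)
  x <- sum(assignments$ft_better_than_ov)
  rho_cols <- grep("^rho_", names(assignments), value = TRUE)
  mean_rho <- colMeans(assignments[rho_cols])
  names(mean_rho) <- sub("^rho_", "", rho_cols)
  list(n = n, n_ft_better = x, proportion = x / n,
       ci = clopper_pearson_ci(x, n, level),
       mean_rho = mean_rho,
       call_counts = table(assignments$call))
}
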