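#' Two-group class comparison of expression
#'
#' Per-gene two-sample t tests between the two sample groups, with
#' Benjamini-Hochberg adjustment across all genes. Genes constant across
#' all samples are kept with `t = 0`, `p = 1` (never significant) so gene
#' counts are preserved.
#'
#' @param em `expr_matrix` in `log_normalized` state.
#' @param group_col name of the annotation column holding exactly two
#'   group labels (default `"group"`), each with >= 2 samples.
#' @param variant `"welch"` (default) or `"pooled"` t test.
#' @return a `de_results` data.frame sorted by ascending p (ties by gene
#'   id): columns `gene`, `diff` (first group minus second, groups in
#'   sorted label order), `t`, `p`, `q`. Attributes record `groups`,
#'   `group_sizes` and `variant`.
#' @export
compare_groups <- function(em, group_col = "group", variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot_state(em, "log_normalized")
  labels <- em$samples[[group_col]]
  if (is.null(labels)) stop("annotation column '", group_col, "' not found")
  if (anyNA(labels)) stop("missing group labels")
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2L)
    stop("need exactly two groups, got: ", paste(groups, collapse = ", "))
  idx1 <- which(labels == groups[1])
  idx2 <- which(labels == groups[2])
  tt <- row_t_test(em$values, idx1, idx2, variant)
  res <- data.frame(gene = rownames(em$values), diff = tt$diff, t = tt$t,
                    p = tt$p, q = bh_adjust(tt$p), stringsAsFactors = FALSE)
  res <- res[order(res$p, res$gene), ]
  rownames(res) <- NULL
  attr(res, "groups") <- groups
  attr(res, "group_sizes") <- c(length(idx1), length(idx2))
  attr(res, "variant") <- variant
  class(res) <- c("de_results", "data.frame")
  res
}

#' Count significant genes at raw and FDR thresholds
#'
#' Strict inequalities at both cuts, matching the reporting convention
#' "P < 0.01" / "FDR of 10%".
#'
#' @param results a `de_results` table (or any data.frame with `p`, `q`).
#' @param raw_p_cut raw p-value threshold in (0, 1] (default 0.01).
#' @param fdr_cut BH q-value threshold in (0, 1] (default 0.10).
#' @return named integer vector `c(n_raw_p, n_fdr)`.
#' @export
count_significant <- function(results, raw_p_cut = 0.01, fdr_cut = 0.10) {
  for (cut in c(raw_p_cut, fdr_cut))
    if (cut <= 0 || cut > 1) stop("thresholds must lie in (0, 1]")
  c(n_raw_p = sum(results$p < raw_p_cut),
    n_fdr = sum(results$q < fdr_cut))
}
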