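#' Median-of-ratios size factors
#'
#' Per-sample scale factors by the median-of-ratios rule: for each sample,
#' the median over reference genes of the ratio between that sample's count
#' and the gene's geometric mean across samples. Reference genes are those
#' with no zero count in any sample. Factors are rescaled to geometric
#' mean 1, so normalized values stay on the counts scale.
#'
#' @param em `expr_matrix` in `raw_counts` state.
#' @return numeric vector of positive size factors, one per sample, named.
#' @export
size_factors <- function(em) {
  stopifnot_state(em, "raw_counts")
  counts <- em$values
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no reference genes (every gene has a zero count in some sample); ",
         "consider adding a pseudocount upstream")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(s) exp(stats::median(s - loggeo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Log-normalize counts
#'
#' `log2(count / factor + 1)` per cell; pseudocount 1 keeps zeros at zero.
#'
#' @param em `expr_matrix` in `raw_counts` state.
#' @param factors size factors from [size_factors()] (or any positive
#'   per-sample scale), length `ncol(em)`.
#' @return `expr_matrix` in `log_normalized` state.
#' @export
log_normalize <- function(em, factors = size_factors(em)) {
  stopifnot_state(em, "raw_counts")
  if (length(factors) != ncol(em$values))
    stop("length(factors) must equal the number of samples")
  if (any(factors <= 0)) stop("size factors must be positive")
  vals <- log2(sweep(em$values, 2, factors, "/") + 1)
  expression_matrix(vals, "log_normalized", em$samples)
}

#' Select the most variable genes
#'
#' Ranks genes by across-sample variance of log-normalized values and keeps
#' the top `k`, preserving the original gene order within the selection.
#' Variance ties are broken by gene id (lexicographic), so the selection is
#' deterministic.
#'
#' @param em `expr_matrix` in `log_normalized` state (variance ranking on
#'   raw counts would be scale-confounded).
#' @param k number of genes to keep; if `k` exceeds the gene count, all
#'   genes are returned with a warning.
#' @return `expr_matrix` restricted to the selected genes.
#' @export
select_most_variable <- function(em, k) {
  stopifnot_state(em, "log_normalized")
  if (k < 1) stop("k must be >= 1")
  m <- em$values
  if (k >= nrow(m)) {
    if (k > nrow(m)) warning("k exceeds the number of genes; returning all")
    return(em)
  }
  v <- apply(m, 1, stats::var)
  keep <- rownames(m)[order(-v, rownames(m))[seq_len(k)]]
  keep <- rownames(m)[rownames(m) %in% keep]  # original order
  subset_genes(em, keep)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of samples under Ward's variance-minimizing
#' criterion, on Euclidean distance or Pearson correlation distance
#' (`1 - r`). With the correlation distance this is Ward linkage on a
#' non-Euclidean dissimilarity, as commonly practiced. Deterministic given
#' the input.
#'
#' @param em `expr_matrix` with >= 2 samples.
#' @param distance `"euclidean"` or `"pearson"`.
#' @param k optional number of clusters to cut the tree into.
#' @return list with `tree` (an `hclust` object over samples) and, when `k`
#'   is given, `labels` (named integer cluster ids from [stats::cutree()]).
#' @export
ward_cluster <- function(em, distance = c("euclidean", "pearson"), k = NULL) {
  distance <- match.arg(distance)
  if (!inherits(em, "expr_matrix")) stop("expected an expr_matrix")
  m <- t(em$values)  # samples in rows
  if (nrow(m) < 2L) stop("need at least 2 samples to cluster")
  if (distance == "euclidean") {
    d <- stats::dist(m)
  } else {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0))
      stop("constant sample(s) under pearson distance: ",
           paste(rownames(m)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(m)))
  }
  tree <- stats::hclust(d, method = "ward.D2")
  out <- list(tree = tree)
  if (!is.null(k)) out$labels <- stats::cutree(tree, k = k)
  out
}
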