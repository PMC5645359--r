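#' Expression matrix with sample annotations
#'
#' The container every expression stage consumes: a genes x samples numeric
#' matrix together with per-sample annotations and a state flag recording
#' whether values are raw counts or log-normalized intensities. Modeled on
#' the light list-based expression containers used throughout expression
#' analysis.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); no missing values.
#' @param state `"raw_counts"` (non-negative integers) or
#'   `"log_normalized"`.
#' @param samples data.frame of per-sample annotations with a `sample_id`
#'   column matching `colnames(values)`; may carry `group`, `subtype`,
#'   `tissue`, `origin`. Built from the column names when omitted.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, state = c("raw_counts", "log_normalized"),
                              samples = NULL) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (anyNA(values)) stop("expression values contain missing entries")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (state == "raw_counts" && (any(values < 0) || any(values != round(values))))
    stop("raw_counts state requires non-negative integer values")
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(samples)) stop("samples must have a sample_id column")
  cn <- colnames(values) %||% character(0)
  if (!identical(as.character(samples$sample_id), cn))
    stop("samples$sample_id must match colnames(values) in order")
  structure(list(values = values, state = state, samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  ann <- setdiff(names(x$samples), "sample_id")
  if (length(ann)) cat("annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

stopifnot_state <- function(em, state) {
  if (!inherits(em, "expr_matrix")) stop("expected an expr_matrix")
  if (em$state != state)
    stop("expected an expr_matrix in state '", state, "', got '", em$state, "'")
  invisible(em)
}

#' Restrict an expression matrix to a gene set
#'
#' @param em an `expr_matrix`.
#' @param genes character vector of gene ids; all must be present.
#' @return an `expr_matrix` over `genes`, in the given order.
#' @export
subset_genes <- function(em, genes) {
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  expression_matrix(em$values[genes, , drop = FALSE], em$state, em$samples)
}
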