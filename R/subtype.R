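#' Build subtype prototype profiles
#'
#' A nearest-prototype (centroid) model over a signature gene set: the
#' prototype of each subtype is the arithmetic mean of the log-normalized
#' expression of its reference samples, per signature gene. Gene centers
#' (the mean over all reference samples) are stored with the model;
#' classification correlates gene-centered profiles, the usual convention
#' for centroid classifiers, so shared abundance structure does not
#' inflate every correlation.
#'
#' @param reference `expr_matrix` in `log_normalized` state.
#' @param labels subtype label per reference sample (>= 2 subtypes, each
#'   with >= 1 sample); defaults to the `subtype` annotation column.
#' @param signature_genes character vector of signature gene ids
#'   (nominally 100 per published subtype signatures); all must be present
#'   in the matrix.
#' @param metric correlation used at assignment time: `"pearson"`
#'   (default, conventional for centroid classifiers) or `"spearman"`.
#' @return a `subtype_model`: list with `signature`, `prototypes`
#'   (signature genes x subtypes), `centers`, `metric`.
#' @export
build_prototypes <- function(reference, labels = reference$samples$subtype,
                             signature_genes, metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  stopifnot_state(reference, "log_normalized")
  if (is.null(labels)) stop("subtype labels are required")
  missing <- setdiff(signature_genes, rownames(reference$values))
  if (length(missing))
    stop("signature genes absent from the reference matrix: ",
         paste(missing, collapse = ", "))
  labels <- as.character(labels)
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2L) stop("need >= 2 subtypes")
  m <- reference$values[signature_genes, , drop = FALSE]
  proto <- vapply(subtypes,
                  function(s) rowMeans(m[, labels == s, drop = FALSE]),
                  numeric(length(signature_genes)))
  if (any(apply(proto, 2, stats::sd) == 0))
    stop("constant prototype profile(s); signature is degenerate")
  structure(list(signature = signature_genes, prototypes = proto,
                 centers = rowMeans(m), metric = metric),
            class = "subtype_model")
}

model_correlations <- function(profile, model) {
  if (is.null(names(profile)) || anyNA(match(model$signature, names(profile))))
    stop("profile must be named and cover every signature gene")
  if (stats::sd(profile[model$signature]) == 0)
    stop("undefined correlation: constant profile over the signature")
  x <- profile[model$signature] - model$centers
  cen <- model$prototypes - model$centers
  method <- if (model$metric == "spearman") "spearman" else "pearson"
  drop(stats::cor(x, cen, method = method))
}

#' Assign a sample to an expression subtype, with abstention
#'
#' Correlates a profile with every subtype prototype and applies the
#' floor-and-ratio rule: candidates are subtypes whose correlation is
#' strictly greater than `floor`; with no candidate the sample is
#' UNASSIGNED; with a single candidate it is assigned; with several it is
#' assigned to the best-correlated subtype only when that correlation is
#' at least `ratio` times the second highest, otherwise UNASSIGNED.
#'
#' @param profile named numeric vector of log-normalized expression
#'   covering the model's signature genes.
#' @param model a `subtype_model` from [build_prototypes()].
#' @param floor correlation floor in (-1, 1); default 0.2.
#' @param ratio ambiguity-rejection ratio >= 1; default 1.5.
#' @return list with `correlations` (named, per subtype), `call` (subtype
#'   id or `"UNASSIGNED"`) and `rule` (which criterion fired:
#'   `"no_candidate"`, `"single_candidate"`, `"clear_best"`,
#'   `"ambiguous"`).
#' @export
assign_subtype <- function(profile, model, floor = 0.2, ratio = 1.5) {
  r <- model_correlations(profile, model)
  c(list(correlations = r), apply_assignment_rule(r, floor, ratio))
}

#' Apply the floor-and-ratio assignment rule to a correlation vector
#'
#' The decision logic of [assign_subtype()] as a pure function: candidates
#' are classes with correlation strictly above `floor`; one candidate wins
#' outright; among several, the maximum wins only when it strictly exceeds
#' and is at least `ratio` times the runner-up (an exact tie at the top is
#' always ambiguous — the ratio test only breaks ties for positive
#' correlations).
#'
#' @param correlations named numeric vector, one correlation per class.
#' @param floor,ratio as in [assign_subtype()].
#' @return list with `call` (class name or `"UNASSIGNED"`) and `rule`.
#' @export
apply_assignment_rule <- function(correlations, floor = 0.2, ratio = 1.5) {
  if (floor <= -1 || floor >= 1) stop("floor must lie in (-1, 1)")
  if (ratio < 1) stop("ratio must be >= 1")
  r <- correlations
  cand <- which(r > floor)
  if (length(cand) == 0L) return(list(call = "UNASSIGNED", rule = "no_candidate"))
  if (length(cand) == 1L) return(list(call = names(r)[cand], rule = "single_candidate"))
  ord <- cand[order(r[cand], decreasing = TRUE)]
  if (r[ord[1]] > r[ord[2]] && r[ord[1]] >= ratio * r[ord[2]])
    list(call = names(r)[ord[1]], rule = "clear_best")
  else
    list(call = "UNASSIGNED", rule = "ambiguous")
}

#' Assign every sample of a cohort to a subtype
#'
#' Applies [assign_subtype()] per sample; per-sample errors (e.g. a
#' constant profile) are recorded as `"ERROR"` calls rather than aborting
#' the cohort.
#'
#' @param em `expr_matrix` in `log_normalized` state covering the
#'   signature genes.
#' @param model a `subtype_model`.
#' @param floor,ratio as in [assign_subtype()].
#' @return a `subtype_assignments` data.frame: `sample_id`, one
#'   correlation column per subtype (`corr_<subtype>`), `call`, `rule`;
#'   attribute `proportions` holds the call frequency table (including
#'   UNASSIGNED).
#' @export
assign_cohort <- function(em, model, floor = 0.2, ratio = 1.5) {
  stopifnot_state(em, "log_normalized")
  subtypes <- colnames(model$prototypes)
  n <- ncol(em$values)
  out <- data.frame(sample_id = colnames(em$values) %||% character(0),
                    stringsAsFactors = FALSE)
  corr <- matrix(NA_real_, n, length(subtypes),
                 dimnames = list(NULL, paste0("corr_", subtypes)))
  call <- character(n); rule <- character(n)
  for (j in seq_len(n)) {
    a <- tryCatch(assign_subtype(em$values[, j], model, floor, ratio),
                  error = function(e) NULL)
    if (is.null(a)) {
      call[j] <- "ERROR"; rule[j] <- "error"
    } else {
      corr[j, ] <- a$correlations
      call[j] <- a$call; rule[j] <- a$rule
    }
  }
  out <- cbind(out, as.data.frame(corr))
  out$call <- call
  out$rule <- rule
  levels_all <- c(subtypes, "UNASSIGNED")
  attr(out, "proportions") <- table(factor(call, levels = levels_all))
  class(out) <- c("subtype_assignments", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
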