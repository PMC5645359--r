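#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate gene or sample ids and negative raw counts are rejected with
#' distinct errors. The state flag is inferred — all-integer values imply
#' raw counts — unless overridden.
#'
#' @param path TSV file path.
#' @param state optional state override (`"raw_counts"` or
#'   `"log_normalized"`).
#' @param annotations optional annotation data.frame (with `sample_id`) or
#'   path to an annotation TSV; matched to the matrix columns.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, state = NULL, annotations = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column and >= 1 sample")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values (ragged or malformed rows?)")
  rownames(m) <- genes
  inferred <- if (all(m >= 0) && all(m == round(m))) "raw_counts" else "log_normalized"
  state <- state %||% inferred
  if (state == "raw_counts" && any(m < 0)) stop("negative counts in raw matrix")
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (!is.null(annotations)) {
    idx <- match(colnames(m), annotations$sample_id)
    if (anyNA(idx)) stop("annotation rows missing for samples: ",
                         paste(colnames(m)[is.na(idx)], collapse = ", "))
    annotations <- annotations[idx, , drop = FALSE]
    rownames(annotations) <- NULL
  }
  expression_matrix(m, state, annotations)
}

#' Write an expression matrix to TSV
#'
#' Genes as rows under a `gene` column, sample ids as the header.
#'
#' @param em an `expr_matrix`.
#' @param path output TSV path.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotations
#'
#' Annotation TSVs carry one row per sample with a `sample_id` column and
#' any of `group` (STIC/NOSTIC), `subtype`, `tissue`, `origin`.
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("annotations need a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotations")
  df
}

#' @rdname read_annotations
#' @param annotations data.frame to write.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write SEG files
#'
#' SEG columns: sample, chromosome, start, end, optional num_probes,
#' seg_mean — 1-based inclusive coordinates on disk, converted to the
#' package's internal 0-based half-open convention on read and back on
#' write.
#'
#' @param path SEG file path.
#' @return a `segment_set` (0-based half-open).
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) == 5L) {
    names(df) <- c("sample", "chrom", "start", "end", "seg_mean")
  } else if (ncol(df) >= 6L) {
    df <- df[, 1:6]
    names(df) <- c("sample", "chrom", "start", "end", "num_probes", "seg_mean")
  } else stop("SEG file needs 5 or 6 columns")
  if (any(df$end < df$start)) stop("SEG rows with end < start")
  df$start <- df$start - 1L  # 1-based inclusive -> 0-based half-open
  segment_set(df)
}

#' @rdname read_seg
#' @param segs a `segment_set` to write.
#' @export
write_seg <- function(segs, path) {
  out <- as.data.frame(segs)
  out$start <- out$start + 1L  # back to 1-based inclusive
  cols <- intersect(c("sample", "chrom", "start", "end", "num_probes", "seg_mean"),
                    names(out))
  utils::write.table(out[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like region table
#'
#' Columns `chrom`, `start`, `end`, `label`; coordinates are 0-based
#' half-open, as in BED.
#'
#' @param path TSV path.
#' @return data.frame of regions.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing region columns: ", paste(miss, collapse = ", "))
  if (any(df$end <= df$start)) stop("regions with end <= start")
  df
}

#' Read / write gene-list files (one id per line)
#'
#' @param path text file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified parameters fall back to the study defaults: correlation
#' floor 0.2 and ratio 1.5 for subtype assignment, 50 markers per tissue,
#' BH FDR 0.10 and raw p 0.01 for class comparison, seed 17.
#'
#' @param path YAML file path (may be omitted for an all-defaults run).
#' @return a `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
}

default_run_config <- function() {
  list(seed = 17,
       synthetic = list(n_stic = 48, n_nostic = 47, n_genes = 20000,
                        n_de_genes = 0, de_effect_sd = 0, subtype_sep = 2,
                        mirna_n_de = 24,
                        origin_mix = list(FT = 0.88, OV = 0.12, PER = 0),
                        origin_noise_sd = 0.6, n_tumors_origin = 85),
       subtype = list(floor = 0.2, ratio = 1.5),
       origin = list(top_n = 50),
       de = list(raw_p = 0.01, fdr = 0.10),
       scna = list(baseline_freq = 0.2, group_delta = 0, n_regions = 82),
       power = list(effects = c(0.75, 1.5), n_per_group = 48, reps = 5))
}

validate_run_config <- function(cfg) {
  st <- cfg$subtype
  if (st$floor <= -1 || st$floor >= 1) stop("subtype floor must lie in (-1, 1)")
  if (st$ratio < 1) stop("subtype ratio must be >= 1")
  if (cfg$de$raw_p <= 0 || cfg$de$raw_p > 1 || cfg$de$fdr <= 0 || cfg$de$fdr > 1)
    stop("de thresholds must lie in (0, 1]")
  if (cfg$origin$top_n < 1) stop("origin top_n must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config` to write.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
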