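#' Segment set constructor
#'
#' Validated container for segmented copy-number profiles. Coordinates are
#' 0-based half-open internally; [read_seg()]/[write_seg()] translate from
#' and to the 1-based inclusive SEG convention.
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open, `start < end`), `seg_mean` (log2 ratio),
#'   optionally `num_probes`.
#' @return a `segment_set` data.frame.
#' @export
segment_set <- function(segments) {
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("missing segment columns: ", paste(miss, collapse = ", "))
  if (any(segments$end <= segments$start))
    stop("segments with end <= start")
  by <- split(segments, list(segments$sample, segments$chrom), drop = TRUE)
  for (b in by) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping segments within sample ", b$sample[1],
           " on ", b$chrom[1])
  }
  class(segments) <- c("segment_set", "data.frame")
  segments
}

#' Region call matrix constructor
#'
#' @param regions data.frame `chrom`, `start`, `end`, `label`; 0-based
#'   half-open, non-overlapping.
#' @param calls integer matrix regions x samples with values in -2..2.
#' @param samples data.frame with `sample_id` (matching the call columns)
#'   and optionally `group`.
#' @return a `region_calls` object.
#' @export
region_calls <- function(regions, calls, samples) {
  if (!all(calls %in% -2:2)) stop("calls must lie in {-2,-1,0,1,2}")
  if (anyNA(calls)) stop("calls must be complete")
  if (nrow(regions) != nrow(calls)) stop("regions/calls dimension mismatch")
  if (!identical(as.character(samples$sample_id), colnames(calls)))
    stop("samples$sample_id must match call columns")
  if (any(regions$end <= regions$start)) stop("regions with end <= start")
  by <- split(regions, regions$chrom)
  for (b in by) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping regions on ", b$chrom[1])
  }
  structure(list(regions = regions, calls = calls, samples = samples),
            class = "region_calls")
}

#' @export
print.region_calls <- function(x, ...) {
  cat(sprintf("region_calls: %d regions x %d samples\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Call discrete copy-number states per region
#'
#' The call for a region in a sample is derived from the length-weighted
#' mean log2 ratio of the segments overlapping the region: `+2` at or
#' above `amp_cut` (2+ fold amplification at the default log2 >= 1), `-2`
#' at or below `del_cut` (deep/homozygous deletion proxy), otherwise `+1`
#' / `-1` at the single-copy cuts, else `0`. Regions with no overlapping
#' segment in a sample are called 0 with a coverage warning.
#'
#' @param segs a `segment_set`.
#' @param regions data.frame `chrom`, `start`, `end`, `label` (0-based
#'   half-open).
#' @param amp_cut,del_cut deep-event thresholds on the log2 ratio
#'   (defaults +1, -1).
#' @param gain_cut,loss_cut single-copy thresholds (defaults +0.3, -0.3).
#' @return a `region_calls` object (samples in sorted order; no `group`
#'   annotation).
#' @export
call_regions <- function(segs, regions, amp_cut = 1, del_cut = -1,
                         gain_cut = 0.3, loss_cut = -0.3) {
  stopifnot(inherits(segs, "segment_set"))
  samples <- sort(unique(segs$sample))
  calls <- matrix(0L, nrow(regions), length(samples),
                  dimnames = list(regions$label, samples))
  uncovered <- 0L
  for (j in seq_along(samples)) {
    ss <- segs[segs$sample == samples[j], ]
    for (i in seq_len(nrow(regions))) {
      ov <- ss$chrom == regions$chrom[i] &
        ss$start < regions$end[i] & ss$end > regions$start[i]
      if (!any(ov)) { uncovered <- uncovered + 1L; next }
      s <- ss[ov, ]
      w <- pmin(s$end, regions$end[i]) - pmax(s$start, regions$start[i])
      wm <- sum(w * s$seg_mean) / sum(w)
      calls[i, j] <- if (wm >= amp_cut) 2L else if (wm <= del_cut) -2L
      else if (wm >= gain_cut) 1L else if (wm <= loss_cut) -1L else 0L
    }
  }
  if (uncovered > 0L)
    warning(uncovered, " region-sample pairs had no segment coverage; called 0")
  region_calls(regions, calls,
               data.frame(sample_id = samples, stringsAsFactors = FALSE))
}

#' Fraction of the genome significantly altered
#'
#' Per sample, the total length of segments whose log2 ratio meets the
#' deep-amplification or deep-deletion cut, divided by the total segment
#' length covered in that sample.
#'
#' @param segs a `segment_set`.
#' @param amp_cut,del_cut thresholds on the log2 ratio (defaults +1, -1:
#'   2+ fold amplification or homozygous-deletion proxy).
#' @return named numeric vector of fractions in `[0, 1]`, one per sample.
#' @export
fraction_genome_altered <- function(segs, amp_cut = 1, del_cut = -1) {
  stopifnot(inherits(segs, "segment_set"))
  vapply(split(segs, segs$sample), function(s) {
    len <- s$end - s$start
    covered <- sum(len)
    if (covered <= 0) stop("zero covered length for sample ", s$sample[1])
    sum(len[s$seg_mean >= amp_cut | s$seg_mean <= del_cut]) / covered
  }, numeric(1))
}

#' Per-region alteration-frequency comparison between groups
#'
#' For every region, a 2x2 Fisher's exact test of altered/not-altered
#' against group membership, with BH adjustment across regions. A region
#' altered in no sample at all carries no information and is assigned
#' p = 1 with a flag.
#'
#' @param calls a `region_calls` object whose `samples` carry a two-level
#'   `group` annotation (or pass `groups` explicitly).
#' @param groups optional group label per sample.
#' @param altered_states call values counted as altered (default deep
#'   events `c(-2, 2)`; set to `c(-2, -1, 1, 2)` to include single-copy
#'   events).
#' @return data.frame per region: `label`, `freq_<group>` columns
#'   (alteration frequency per group), `p`, `q`, `flat` (TRUE when the
#'   region was altered in no sample).
#' @export
region_frequency_test <- function(calls, groups = calls$samples$group,
                                  altered_states = c(-2, 2)) {
  stopifnot(inherits(calls, "region_calls"))
  if (is.null(groups)) stop("group labels are required")
  gl <- sort(unique(as.character(groups)))
  if (length(gl) != 2L) stop("need exactly two groups")
  alt <- matrix(calls$calls %in% altered_states, nrow(calls$calls))
  n1 <- sum(groups == gl[1]); n2 <- sum(groups == gl[2])
  a1 <- rowSums(alt[, groups == gl[1], drop = FALSE])
  a2 <- rowSums(alt[, groups == gl[2], drop = FALSE])
  flat <- (a1 + a2) == 0
  p <- rep(1, nrow(calls$calls))
  for (i in which(!flat)) {
    tab <- matrix(c(a1[i], n1 - a1[i], a2[i], n2 - a2[i]), 2)
    p[i] <- fisher_exact(tab)
  }
  out <- data.frame(label = calls$regions$label,
                    f1 = a1 / n1, f2 = a2 / n2,
                    p = p, q = bh_adjust(p), flat = flat,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("freq_", gl)
  out
}
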