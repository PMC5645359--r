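#' Run the end-to-end comparative analysis on a synthetic cohort
#'
#' Orchestrates every stage on data drawn by the synthetic generators:
#' simulate (tumor mRNA, miRNA, normal pools, origin-mixture tumors,
#' region calls) -> normalize -> STIC vs NOSTIC class comparison (mRNA and
#' miRNA) -> subtype assignment -> tissue-of-origin matching -> region
#' frequency comparison -> power table. Writes per-stage TSVs, a
#' machine-readable JSON summary and a run log (seed and resolved
#' parameters) into `out_dir`. Deterministic for a fixed configuration:
#' the summary is byte-identical across runs.
#'
#' @param config a `run_config` from [read_run_config()]; defaults used
#'   when omitted.
#' @param out_dir output directory (created if needed).
#' @return the summary list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  syn <- config$synthetic
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- simulate -------------------------------------------------------------
  cohort <- stage("simulate_mrna", generate_tumor_expression(
    cohort_config(n_stic = syn$n_stic, n_nostic = syn$n_nostic,
                  n_genes = syn$n_genes, n_de_genes = syn$n_de_genes,
                  de_effect_sd = syn$de_effect_sd,
                  subtype_sep = syn$subtype_sep, seed = seed)))
  mirna <- stage("simulate_mirna", generate_mirna_counts(
    mirna_config(n_stic = syn$n_stic, n_nostic = syn$n_nostic,
                 n_de = syn$mirna_n_de, seed = seed + 1)))
  # marker-set sizes keep the default 20%/1.5%/1.5% split of the gene count
  normals <- stage("simulate_normals", generate_normal_pools(
    normal_pool_config(n_genes = syn$n_genes,
                       n_ft_markers = round(0.2 * syn$n_genes),
                       n_ov_markers = round(0.015 * syn$n_genes),
                       n_per_markers = round(0.015 * syn$n_genes),
                       seed = seed + 2)))
  scna <- stage("simulate_scna", generate_copy_number(
    scna_config(n_regions = config$scna$n_regions,
                baseline_alteration_freq = config$scna$baseline_freq,
                group_delta = config$scna$group_delta, seed = seed + 3)))
  write_expression(cohort$expression, file.path(out_dir, "mrna_counts.tsv"))
  write_annotations(cohort$expression$samples, file.path(out_dir, "mrna_annotations.tsv"))
  write_expression(mirna$expression, file.path(out_dir, "mirna_counts.tsv"))
  write_expression(normals$expression, file.path(out_dir, "normal_counts.tsv"))
  write_gene_list(cohort$signature_genes, file.path(out_dir, "subtype_signature.txt"))

  # --- normalize ------------------------------------------------------------
  mrna_log <- stage("normalize", log_normalize(cohort$expression))
  mirna_log <- stage("normalize_mirna", log_normalize(
    mirna$expression, colSums(mirna$expression$values) /
      exp(mean(log(colSums(mirna$expression$values))))))
  normals_log <- stage("normalize_normals", log_normalize(normals$expression))

  # --- class comparison -----------------------------------------------------
  de <- stage("class_comparison", compare_groups(mrna_log))
  de_counts <- count_significant(de, config$de$raw_p, config$de$fdr)
  utils::write.table(de, file.path(out_dir, "de_mrna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de_mi <- stage("class_comparison_mirna", compare_groups(mirna_log))
  de_mi_counts <- count_significant(de_mi, config$de$raw_p, config$de$fdr)
  utils::write.table(de_mi, file.path(out_dir, "de_mirna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- subtype assignment ---------------------------------------------------
  model <- stage("subtype_model",
                 build_prototypes(mrna_log, signature_genes = cohort$signature_genes))
  assigns <- stage("subtype_assignment",
                   assign_cohort(mrna_log, model,
                                 floor = config$subtype$floor,
                                 ratio = config$subtype$ratio))
  utils::write.table(assigns, file.path(out_dir, "subtype_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- tissue of origin -----------------------------------------------------
  sig <- stage("tissue_signature",
               derive_tissue_signature(normals_log, top_n = config$origin$top_n))
  tde <- stage("tissue_de", count_tissue_de(normals_log))
  mix <- unlist(syn$origin_mix)
  tumors <- stage("simulate_origin_tumors",
                  generate_tumors_from_tissue(normals$prototypes, mix,
                                              noise_sd = syn$origin_noise_sd,
                                              n = syn$n_tumors_origin,
                                              seed = seed + 4))
  matches <- stage("tissue_match", match_tissue(tumors$expression, sig))
  origin <- stage("origin_summary", summarize_origin(matches))
  utils::write.table(matches, file.path(out_dir, "tissue_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(sig$genes, file.path(out_dir, "tissue_signature.txt"))

  # --- copy number ----------------------------------------------------------
  freq <- stage("scna_comparison", region_frequency_test(scna))
  utils::write.table(freq, file.path(out_dir, "scna_frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- power ----------------------------------------------------------------
  pw <- stage("power", simulate_power(effect_sd = config$power$effects,
                                      n_per_group = config$power$n_per_group,
                                      reps = config$power$reps, seed = seed + 5))
  utils::write.table(pw, file.path(out_dir, "power.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = seed,
    parameters = unclass(config),
    class_comparison = list(
      mrna = as.list(de_counts), mirna = as.list(de_mi_counts)),
    subtype = list(proportions = as.list(attr(assigns, "proportions"))),
    tissue_of_origin = list(
      n = origin$n, n_ft_better = origin$n_ft_better,
      proportion = origin$proportion,
      ci = as.list(origin$ci), mean_rho = as.list(origin$mean_rho),
      tissue_de_counts = as.list(tde)),
    scna = list(n_regions = nrow(freq),
                n_fdr_significant = sum(freq$q < config$de$fdr)),
    power = pw,
    files = list.files(out_dir))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste("seed:", seed),
               paste("R:", R.version.string),
               paste("hgscompare:", as.character(utils::packageVersion("hgscompare"))),
               yaml::as.yaml(unclass(config))),
             file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
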