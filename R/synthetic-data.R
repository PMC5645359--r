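#' Synthetic cohort generators
#'
#' Generators that emulate the statistical structure of a two-arm HGSC
#' molecular study: a tumor expression cohort with latent expression
#' subtypes and an optional STIC-group effect, normal-tissue reference
#' pools with a mesothelial lineage shared by ovarian surface epithelium
#' and peritoneum, low-abundance miRNA counts, and region-level somatic
#' copy-number calls. Counts are negative-binomial on a log-normal mean
#' field; effects are additive shifts on the log2 mean, expressed in units
#' of the per-gene standard deviation of log2-normalized expression.
#'
#' @name synthetic_data
NULL

# delta-method s.d. of log2(count/sf + 1) for NB(mu, dispersion phi)
log2_sd_nb <- function(mu, phi, extra_var = 0) {
  sqrt((mu + phi * mu^2) / ((mu + 1)^2 * log(2)^2) + extra_var)
}

#' Tumor cohort configuration
#'
#' @param n_stic,n_nostic samples per group (defaults 48, 47).
#' @param n_genes number of genes (default 20000).
#' @param n_subtypes latent expression subtypes (fixed design: 4).
#' @param subtype_sep separation of subtype prototype means, in units of
#'   the within-subtype s.d. of log2-normalized expression.
#' @param n_de_genes number of genes carrying a true group effect (0 under
#'   the null).
#' @param de_effect_sd group effect size, in within-group s.d. units on the
#'   log2 scale.
#' @param bio_sd tumor-to-tumor biological s.d. of log2 expression; the
#'   dominant variance component, as in bulk tumor cohorts.
#' @param nb_dispersion negative-binomial dispersion of the count draw
#'   around each sample's mean (var = mu + phi mu^2); technical plus
#'   residual.
#' @param mean_log2,sd_log2_field mean and s.d. of the per-gene baseline
#'   log2 mean field.
#' @param libsize_sd s.d. of log library-size factors (log-normal).
#' @param block_size genes per subtype prototype block (default 100,
#'   mirroring the scale of published 100-gene subtype signatures).
#' @param seed RNG seed (default 17).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_stic = 48, n_nostic = 47, n_genes = 20000,
                          n_subtypes = 4, subtype_sep = 2, n_de_genes = 0,
                          de_effect_sd = 0, bio_sd = 0.5, nb_dispersion = 0.05,
                          mean_log2 = 6.5, sd_log2_field = 1.5,
                          libsize_sd = 0.3, block_size = 100, seed = 17) {
  cfg <- list(n_stic = n_stic, n_nostic = n_nostic, n_genes = n_genes,
              n_subtypes = n_subtypes, subtype_sep = subtype_sep,
              n_de_genes = n_de_genes, de_effect_sd = de_effect_sd,
              bio_sd = bio_sd, nb_dispersion = nb_dispersion, mean_log2 = mean_log2,
              sd_log2_field = sd_log2_field, libsize_sd = libsize_sd,
              block_size = block_size, seed = seed)
  counts <- c("n_stic", "n_nostic", "n_genes", "n_subtypes", "block_size")
  if (any(unlist(cfg[counts]) < 1)) stop("all counts must be positive")
  if (n_de_genes < 0 || n_de_genes > n_genes)
    stop("n_de_genes must lie in 0..n_genes")
  if (de_effect_sd < 0) stop("de_effect_sd must be >= 0")
  if (bio_sd < 0) stop("bio_sd must be >= 0")
  if (subtype_sep < 0) stop("subtype_sep must be >= 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (n_subtypes * block_size > n_genes)
    stop("subtype blocks exceed the gene count")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a two-group tumor expression cohort
#'
#' Draws a genes x samples count matrix with four latent expression
#' subtypes (disjoint prototype gene blocks shifted by `subtype_sep` s.d.)
#' and, when `n_de_genes > 0`, a true STIC-group shift of `de_effect_sd`
#' s.d. on the log2 mean of randomly chosen genes. With `n_de_genes = 0`
#' group labels are independent of expression: the global null.
#'
#' @param config a [cohort_config()].
#' @return list with `expression` (`expr_matrix`, raw counts, sample
#'   annotations `group` in STIC/NOSTIC and `subtype`), `signature_genes`
#'   (the subtype block genes, a stand-in classifier signature),
#'   `de_genes` (ids of genes carrying the group effect) and `config`.
#' @export
generate_tumor_expression <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_stic + config$n_nostic
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    samples <- sprintf("T%03d", seq_len(n))
    group <- rep(c("STIC", "NOSTIC"), c(config$n_stic, config$n_nostic))
    subtype <- sample.int(config$n_subtypes, n, replace = TRUE)

    mu_log2 <- stats::rnorm(config$n_genes, config$mean_log2, config$sd_log2_field)
    sd_units <- log2_sd_nb(2^mu_log2, config$nb_dispersion,
                           extra_var = config$bio_sd^2)

    block_genes <- sample.int(config$n_genes, config$n_subtypes * config$block_size)
    block_of <- rep(seq_len(config$n_subtypes), each = config$block_size)
    de_genes <- if (config$n_de_genes > 0)
      sample.int(config$n_genes, config$n_de_genes) else integer(0)

    lm <- matrix(mu_log2, config$n_genes, n)
    for (k in seq_len(config$n_subtypes)) {
      gk <- block_genes[block_of == k]
      in_k <- subtype == k
      if (any(in_k))
        lm[gk, in_k] <- lm[gk, in_k] + config$subtype_sep * sd_units[gk]
    }
    if (length(de_genes) && config$de_effect_sd > 0) {
      stic <- group == "STIC"
      lm[de_genes, stic] <- lm[de_genes, stic] +
        config$de_effect_sd * sd_units[de_genes]
    }
    lm <- lm + matrix(stats::rnorm(config$n_genes * n, 0, config$bio_sd),
                      config$n_genes)
    libf <- exp(stats::rnorm(n, 0, config$libsize_sd))
    mu <- sweep(2^lm, 2, libf, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow = config$n_genes, dimnames = list(genes, samples))
    em <- expression_matrix(counts, "raw_counts",
                            data.frame(sample_id = samples, group = group,
                                       subtype = paste0("S", subtype),
                                       stringsAsFactors = FALSE))
    list(expression = em,
         signature_genes = genes[block_genes],
         de_genes = genes[de_genes],
         subtype_blocks = split(genes[block_genes], paste0("S", block_of)),
         config = config)
  })
}

#' Normal-tissue pool configuration
#'
#' Defaults emulate the observed asymmetry between tissue-specific
#' expression programs: a large fallopian-tube marker set against much
#' smaller ovarian-surface and peritoneal sets, plus a shared mesothelial
#' component that makes OV and PER pools resemble each other more than
#' either resembles FT.
#'
#' @param n_pools_per_tissue replicate pools per tissue (>= 2; default 3).
#' @param n_genes number of genes.
#' @param n_ft_markers,n_ov_markers,n_per_markers disjoint tissue-specific
#'   marker set sizes (defaults 4000/300/300).
#' @param marker_shift_sd marker effect in units of the within-tissue s.d.
#'   of log2 expression; scalar or length 3 (FT, OV, PER). The peritoneal
#'   default is larger: peritoneum is the most divergent of the three from
#'   Muellerian-type epithelium.
#' @param mesothelial_corr s.d. (log2) of the per-gene component shared by
#'   OV and PER pools but absent from FT — the mesothelial lineage signal.
#' @param pool_sd pool-to-pool biological s.d. (log2) within a tissue.
#' @param nb_dispersion,mean_log2,sd_log2_field,libsize_sd as in
#'   [cohort_config()]; pools are deeply sequenced so dispersion is low.
#' @param seed RNG seed.
#' @return a `normal_pool_config` list.
#' @export
normal_pool_config <- function(n_pools_per_tissue = 3, n_genes = 20000,
                               n_ft_markers = 4000, n_ov_markers = 300,
                               n_per_markers = 300,
                               marker_shift_sd = c(FT = 6, OV = 6, PER = 9),
                               mesothelial_corr = 0.3, pool_sd = 0.2,
                               nb_dispersion = 0.02, mean_log2 = 6.5,
                               sd_log2_field = 1.5, libsize_sd = 0.3,
                               seed = 17) {
  if (n_pools_per_tissue < 2)
    stop("n_pools_per_tissue must be >= 2 (one-vs-rest testing needs replication)")
  if (n_ft_markers + n_ov_markers + n_per_markers > n_genes)
    stop("marker sets exceed the gene count")
  if (length(marker_shift_sd) == 1L) marker_shift_sd <- rep(marker_shift_sd, 3)
  if (any(marker_shift_sd < 0) || mesothelial_corr < 0 || pool_sd < 0)
    stop("effect and noise parameters must be >= 0")
  structure(list(n_pools_per_tissue = n_pools_per_tissue, n_genes = n_genes,
                 n_ft_markers = n_ft_markers, n_ov_markers = n_ov_markers,
                 n_per_markers = n_per_markers,
                 marker_shift_sd = stats::setNames(marker_shift_sd, c("FT", "OV", "PER")),
                 mesothelial_corr = mesothelial_corr, pool_sd = pool_sd,
                 nb_dispersion = nb_dispersion, mean_log2 = mean_log2,
                 sd_log2_field = sd_log2_field, libsize_sd = libsize_sd,
                 seed = seed),
            class = "normal_pool_config")
}

#' Generate normal-tissue reference pools
#'
#' Three tissues — fallopian tube (FT), ovarian surface epithelium (OV)
#' and peritoneum (PER) — each with replicate pooled profiles. Marker sets
#' are disjoint by construction; OV and PER share a mesothelial component,
#' so their profiles correlate more with each other than with FT.
#'
#' @param config a [normal_pool_config()].
#' @return list with `expression` (`expr_matrix`, raw counts, annotation
#'   `tissue`), `prototypes` (genes x 3 matrix of true tissue log2 means),
#'   `markers` (list of marker gene ids per tissue) and `config`.
#' @export
generate_normal_pools <- function(config) {
  stopifnot(inherits(config, "normal_pool_config"))
  withr::with_seed(config$seed, {
    tissues <- c("FT", "OV", "PER")
    np <- config$n_pools_per_tissue
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    tissue <- rep(tissues, each = np)
    pools <- paste0(tissue, "_p", rep(seq_len(np), times = 3))

    mu_log2 <- stats::rnorm(config$n_genes, config$mean_log2, config$sd_log2_field)
    sd_units <- log2_sd_nb(2^mu_log2, config$nb_dispersion,
                           extra_var = config$pool_sd^2)
    idx <- sample.int(config$n_genes,
                      config$n_ft_markers + config$n_ov_markers + config$n_per_markers)
    markers <- list(FT = idx[seq_len(config$n_ft_markers)],
                    OV = idx[config$n_ft_markers + seq_len(config$n_ov_markers)],
                    PER = idx[config$n_ft_markers + config$n_ov_markers +
                                seq_len(config$n_per_markers)])
    meso <- stats::rnorm(config$n_genes, 0, config$mesothelial_corr)

    proto <- matrix(mu_log2, config$n_genes, 3, dimnames = list(genes, tissues))
    proto[, "OV"] <- proto[, "OV"] + meso
    proto[, "PER"] <- proto[, "PER"] + meso
    for (tt in tissues) {
      mk <- markers[[tt]]
      sgn <- sample(c(-1, 1), length(mk), replace = TRUE)
      proto[mk, tt] <- proto[mk, tt] +
        sgn * config$marker_shift_sd[[tt]] * sd_units[mk]
    }

    lm <- proto[, tissue, drop = FALSE] +
      matrix(stats::rnorm(config$n_genes * length(pools), 0, config$pool_sd),
             config$n_genes)
    libf <- exp(stats::rnorm(length(pools), 0, config$libsize_sd))
    mu <- sweep(2^lm, 2, libf, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow = config$n_genes, dimnames = list(genes, pools))
    em <- expression_matrix(counts, "raw_counts",
                            data.frame(sample_id = pools, tissue = tissue,
                                       stringsAsFactors = FALSE))
    list(expression = em, prototypes = proto,
         markers = lapply(markers, function(i) genes[i]), config = config)
  })
}

#' Generate tumors from normal-tissue prototypes
#'
#' Test harness for the tissue-of-origin matcher: each tumor is one
#' tissue's true log2 prototype plus independent Gaussian noise, with the
#' generating tissue recorded. Profiles are returned in log-normalized
#' state, ready for matching.
#'
#' @param prototypes genes x tissues matrix of log2 prototype profiles
#'   (as returned by [generate_normal_pools()]).
#' @param origin_mix named probabilities over the prototype tissues,
#'   summing to 1 (e.g. `c(FT = 0.88, OV = 0.12, PER = 0)`).
#' @param noise_sd per-gene Gaussian noise s.d. on the log2 scale (>= 0).
#' @param n number of tumors (default 85).
#' @param seed RNG seed.
#' @return list with `expression` (`expr_matrix`, log-normalized,
#'   annotation `origin`) and `origin` (character vector of true origins).
#' @export
generate_tumors_from_tissue <- function(prototypes, origin_mix, noise_sd,
                                        n = 85, seed = 17) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  tissues <- colnames(prototypes)
  if (is.null(names(origin_mix)) || !setequal(names(origin_mix), tissues))
    stop("origin_mix must be named after the prototype tissues")
  origin_mix <- origin_mix[tissues]
  if (abs(sum(origin_mix) - 1) > 1e-8) stop("origin_mix must sum to 1")
  withr::with_seed(seed, {
    origin <- sample(tissues, n, replace = TRUE, prob = origin_mix)
    vals <- prototypes[, origin, drop = FALSE] +
      matrix(stats::rnorm(nrow(prototypes) * n, 0, noise_sd), nrow(prototypes))
    colnames(vals) <- sprintf("T%03d", seq_len(n))
    em <- expression_matrix(vals, "log_normalized",
                            data.frame(sample_id = colnames(vals),
                                       origin = origin, stringsAsFactors = FALSE))
    list(expression = em, origin = origin)
  })
}

#' miRNA cohort configuration
#'
#' @param n_stic,n_nostic samples per group (defaults 48, 47).
#' @param n_mirna number of miRNAs (default 800).
#' @param n_de number of true group-differential miRNAs (default 24),
#'   drawn from the low-abundance half of the mean field.
#' @param de_effect_sd effect size in s.d. units (default 2).
#' @param bio_sd tumor-to-tumor biological s.d. of log2 expression.
#' @param nb_dispersion NB dispersion of the count draw.
#' @param mean_log2,sd_log2_field low-abundance log2 mean field (defaults
#'   give most miRNAs mean counts in the single digits).
#' @param low_mean_threshold threshold (mean count) defining the
#'   low-abundance regime (default 10).
#' @param libsize_sd,seed as in [cohort_config()].
#' @return a `mirna_config` list.
#' @export
mirna_config <- function(n_stic = 48, n_nostic = 47, n_mirna = 800,
                         n_de = 24, de_effect_sd = 2, bio_sd = 0.6,
                         nb_dispersion = 0.1,
                         mean_log2 = 1.6, sd_log2_field = 1.4,
                         low_mean_threshold = 10, libsize_sd = 0.3,
                         seed = 17) {
  if (n_de < 0 || n_de > n_mirna) stop("n_de must lie in 0..n_mirna")
  if (de_effect_sd < 0) stop("de_effect_sd must be >= 0")
  structure(list(n_stic = n_stic, n_nostic = n_nostic, n_mirna = n_mirna,
                 n_de = n_de, de_effect_sd = de_effect_sd, bio_sd = bio_sd,
                 nb_dispersion = nb_dispersion, mean_log2 = mean_log2,
                 sd_log2_field = sd_log2_field,
                 low_mean_threshold = low_mean_threshold,
                 libsize_sd = libsize_sd, seed = seed),
            class = "mirna_config")
}

#' Generate a low-abundance miRNA count cohort
#'
#' Emulates a miRNA panel in which most features have low counts and any
#' true group-differential features sit in the low-abundance tail.
#'
#' @param config a [mirna_config()].
#' @return list with `expression` (`expr_matrix`, raw counts, annotation
#'   `group`), `de_mirnas` (ids with a true effect) and `config`.
#' @export
generate_mirna_counts <- function(config) {
  stopifnot(inherits(config, "mirna_config"))
  withr::with_seed(config$seed, {
    n <- config$n_stic + config$n_nostic
    ids <- sprintf("mir%04d", seq_len(config$n_mirna))
    samples <- sprintf("T%03d", seq_len(n))
    group <- rep(c("STIC", "NOSTIC"), c(config$n_stic, config$n_nostic))
    mu_log2 <- stats::rnorm(config$n_mirna, config$mean_log2, config$sd_log2_field)
    sd_units <- log2_sd_nb(2^mu_log2, config$nb_dispersion,
                           extra_var = config$bio_sd^2)
    low_half <- order(mu_log2)[seq_len(floor(config$n_mirna / 2))]
    de <- if (config$n_de > 0) sample(low_half, config$n_de) else integer(0)
    lm <- matrix(mu_log2, config$n_mirna, n)
    if (length(de) && config$de_effect_sd > 0) {
      stic <- group == "STIC"
      lm[de, stic] <- lm[de, stic] + config$de_effect_sd * sd_units[de]
    }
    lm <- lm + matrix(stats::rnorm(config$n_mirna * n, 0, config$bio_sd),
                      config$n_mirna)
    libf <- exp(stats::rnorm(n, 0, config$libsize_sd))
    mu <- sweep(2^lm, 2, libf, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow = config$n_mirna, dimnames = list(ids, samples))
    em <- expression_matrix(counts, "raw_counts",
                            data.frame(sample_id = samples, group = group,
                                       stringsAsFactors = FALSE))
    list(expression = em, de_mirnas = ids[de], config = config)
  })
}

#' Copy-number call configuration
#'
#' @param n_regions number of focal regions (default 82).
#' @param region_lengths base-pair lengths, recycled to `n_regions`.
#' @param baseline_alteration_freq per-region probability that a sample
#'   carries a deep alteration in the region, shared across groups; scalar
#'   or length `n_regions`.
#' @param group_delta per-region frequency difference added in the STIC
#'   group (0 under the null); must keep frequencies in `[0, 1]`.
#' @param amp_prob probability an alteration is an amplification (+2)
#'   rather than a deep deletion (-2), fixed per region.
#' @param n_stic,n_nostic samples per group (defaults 48, 48: copy-number
#'   profiling covers the full case set).
#' @param seed RNG seed.
#' @return an `scna_config` list.
#' @export
scna_config <- function(n_regions = 82, region_lengths = NULL,
                        baseline_alteration_freq = 0.2, group_delta = 0,
                        amp_prob = 0.6, n_stic = 48, n_nostic = 48,
                        seed = 17) {
  if (n_regions < 1) stop("n_regions must be positive")
  f <- rep_len(baseline_alteration_freq, n_regions)
  d <- rep_len(group_delta, n_regions)
  if (any(f < 0 | f > 1)) stop("baseline_alteration_freq must lie in [0, 1]")
  if (any(f + d < 0 | f + d > 1))
    stop("group_delta must keep frequencies in [0, 1]")
  structure(list(n_regions = n_regions, region_lengths = region_lengths,
                 baseline_alteration_freq = f, group_delta = d,
                 amp_prob = amp_prob, n_stic = n_stic, n_nostic = n_nostic,
                 seed = seed),
            class = "scna_config")
}

#' Generate region-level copy-number calls for two groups
#'
#' Each region carries a deep alteration (+2 amplification or -2 deletion,
#' with a per-region preferred direction) with probability
#' `baseline_alteration_freq` in NOSTIC samples and
#' `baseline_alteration_freq + group_delta` in STIC samples.
#'
#' @param config an [scna_config()].
#' @return a `region_calls` object: list with `regions` (data.frame
#'   `chrom`, `start`, `end`, `label`; 0-based half-open), `calls`
#'   (regions x samples integer matrix in -2..2) and `samples` (data.frame
#'   `sample_id`, `group`).
#' @export
generate_copy_number <- function(config) {
  stopifnot(inherits(config, "scna_config"))
  withr::with_seed(config$seed, {
    n <- config$n_stic + config$n_nostic
    group <- rep(c("STIC", "NOSTIC"), c(config$n_stic, config$n_nostic))
    samples <- sprintf("T%03d", seq_len(n))
    lens <- config$region_lengths
    if (is.null(lens))
      lens <- round(stats::runif(config$n_regions, 1e5, 1e7))
    lens <- rep_len(lens, config$n_regions)
    starts <- cumsum(c(0, lens[-config$n_regions] + 5e5))
    regions <- data.frame(chrom = paste0("chr", 1 + (seq_len(config$n_regions) - 1) %% 22),
                          start = starts, end = starts + lens,
                          label = sprintf("R%02d", seq_len(config$n_regions)),
                          stringsAsFactors = FALSE)
    dir <- ifelse(stats::rbinom(config$n_regions, 1, config$amp_prob) == 1, 2L, -2L)
    freq <- matrix(config$baseline_alteration_freq, config$n_regions, n)
    freq[, group == "STIC"] <- freq[, group == "STIC"] + config$group_delta
    hit <- matrix(stats::rbinom(length(freq), 1, freq), config$n_regions)
    calls <- hit * dir
    dimnames(calls) <- list(regions$label, samples)
    region_calls(regions, calls,
                 data.frame(sample_id = samples, group = group,
                            stringsAsFactors = FALSE))
  })
}
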