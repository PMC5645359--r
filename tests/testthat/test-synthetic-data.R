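test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- cohort_config(n_genes = 300, n_stic = 6, n_nostic = 5, block_size = 20,
                       seed = 4)
  expect_identical(generate_tumor_expression(cfg), generate_tumor_expression(cfg))
  np <- normal_pool_config(n_genes = 400, n_ft_markers = 60, n_ov_markers = 10,
                           n_per_markers = 10, seed = 4)
  expect_identical(generate_normal_pools(np), generate_normal_pools(np))
  mc <- mirna_config(n_mirna = 100, n_stic = 6, n_nostic = 6, seed = 4)
  expect_identical(generate_mirna_counts(mc), generate_mirna_counts(mc))
  sc <- scna_config(n_regions = 10, seed = 4)
  expect_identical(generate_copy_number(sc), generate_copy_number(sc))
})

test_that("cohort configuration rejects invalid settings", {
  expect_error(cohort_config(n_de_genes = 30, n_genes = 20), "0..n_genes")
  expect_error(cohort_config(de_effect_sd = -1), ">= 0")
  expect_error(cohort_config(n_genes = 0), "positive")
  expect_error(normal_pool_config(n_pools_per_tissue = 1), "replication")
  expect_error(mirna_config(n_de = 200, n_mirna = 100), "0..n_mirna")
  expect_error(scna_config(baseline_alteration_freq = 1.2), "\\[0, 1\\]")
  expect_error(scna_config(baseline_alteration_freq = 0.9, group_delta = 0.3),
               "keep frequencies")
  expect_error(generate_tumors_from_tissue(matrix(1:6, 3, dimnames = list(NULL, c("FT", "OV"))),
                                           c(FT = 1, OV = 0), noise_sd = -1),
               ">= 0")
})

test_that("tumor cohorts carry the configured structure", {
  g <- generate_tumor_expression(cohort_config(n_genes = 500, n_stic = 10,
                                               n_nostic = 8, n_de_genes = 20,
                                               de_effect_sd = 1, block_size = 50,
                                               seed = 9))
  em <- g$expression
  expect_identical(em$state, "raw_counts")
  expect_true(all(em$values >= 0) && all(em$values == round(em$values)))
  expect_equal(table(em$samples$group), table(rep(c("NOSTIC", "STIC"), c(8, 10))))
  expect_length(g$de_genes, 20)
  expect_length(g$signature_genes, 200)
  expect_true(all(em$samples$subtype %in% paste0("S", 1:4)))
})

test_that("the injected group effect matches its nominal size in s.d. units", {
  shifts <- vapply(1:20, function(s) {
    g <- generate_tumor_expression(cohort_config(n_genes = 2000, n_de_genes = 50,
                                                 de_effect_sd = 1, seed = s))
    ln <- log_normalize(g$expression)
    grp <- ln$samples$group
    d <- rowMeans(ln$values[g$de_genes, grp == "STIC"]) -
      rowMeans(ln$values[g$de_genes, grp == "NOSTIC"])
    sdp <- apply(ln$values[g$de_genes, ], 1, function(x) {
      nx <- sum(grp == "STIC"); ny <- sum(grp == "NOSTIC")
      sqrt(((nx - 1) * var(x[grp == "STIC"]) + (ny - 1) * var(x[grp == "NOSTIC"])) /
             (nx + ny - 2))
    })
    mean(d / sdp)
  }, numeric(1))
  expect_equal(mean(shifts), 1, tolerance = 0.1)
})

test_that("null-cohort p-values are uniform under the global null", {
  g <- generate_tumor_expression(cohort_config(seed = 42))
  de <- compare_groups(log_normalize(g$expression))
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("normal pools place the mesothelial tissues together", {
  np <- generate_normal_pools(normal_pool_config(seed = 3))
  ln <- log_normalize(np$expression)
  tissue <- ln$samples$tissue
  prof <- vapply(c("FT", "OV", "PER"),
                 function(t) rowMeans(ln$values[, tissue == t, drop = FALSE]),
                 numeric(nrow(ln$values)))
  cc <- cor(prof)
  expect_gt(cc["OV", "PER"], cc["OV", "FT"])
  expect_gt(cc["OV", "PER"], cc["PER", "FT"])
  # Ward/Euclidean joins the mesothelial pools before fallopian tube
  lab <- ward_cluster(ln, "euclidean", k = 2)$labels
  expect_equal(length(unique(lab[tissue == "FT"])), 1)
  expect_true(all(lab[tissue != "FT"] != lab[tissue == "FT"][1]))
  # marker sets are disjoint
  expect_equal(anyDuplicated(unlist(np$markers)), 0)
})

test_that("null normal pools produce exchangeable tissues", {
  np <- generate_normal_pools(normal_pool_config(n_genes = 4000,
                                                 n_ft_markers = 800,
                                                 n_ov_markers = 60,
                                                 n_per_markers = 60,
                                                 marker_shift_sd = 0,
                                                 mesothelial_corr = 0, seed = 8))
  counts <- count_tissue_de(log_normalize(np$expression), alpha = 0.05)
  expect_true(all(counts <= 5))  # near zero at q < 0.05 under the null
})

test_that("tumors generated from tissue prototypes record their origin", {
  np <- generate_normal_pools(normal_pool_config(n_genes = 1000,
                                                 n_ft_markers = 200,
                                                 n_ov_markers = 15,
                                                 n_per_markers = 15, seed = 2))
  noiseless <- generate_tumors_from_tissue(np$prototypes, c(FT = 1, OV = 0, PER = 0),
                                           noise_sd = 0, n = 5, seed = 2)
  expect_true(all(noiseless$origin == "FT"))
  for (j in 1:5)
    expect_equal(spearman_rho(noiseless$expression$values[, j], np$prototypes[, "FT"]), 1)
  expect_error(generate_tumors_from_tissue(np$prototypes, c(FT = 0.5, OV = 0.1, PER = 0.1),
                                           noise_sd = 1),
               "sum to 1")
})

test_that("miRNA cohorts live in the low-abundance regime", {
  mi <- generate_mirna_counts(mirna_config(seed = 2))
  cfg <- mi$config
  expect_gte(mean(rowMeans(mi$expression$values) < cfg$low_mean_threshold), 0.8)
  expect_length(mi$de_mirnas, 24)
  null_counts <- vapply(1:5, function(s) {
    m <- generate_mirna_counts(mirna_config(n_de = 0, seed = s))
    sf <- colSums(m$expression$values)
    sf <- sf / exp(mean(log(sf)))
    count_significant(compare_groups(log_normalize(m$expression, sf)))[["n_fdr"]]
  }, integer(1))
  expect_gte(mean(null_counts == 0), 0.8)
})

test_that("copy-number generation respects the configured frequencies", {
  cn0 <- generate_copy_number(scna_config(baseline_alteration_freq = 0, seed = 1))
  expect_true(all(cn0$calls == 0))
  cn1 <- generate_copy_number(scna_config(
    baseline_alteration_freq = c(1, rep(0.2, 81)), seed = 1))
  expect_true(all(cn1$calls[1, ] %in% c(-2, 2)))
  cn <- generate_copy_number(scna_config(baseline_alteration_freq = 0.3,
                                         n_regions = 200, seed = 6))
  freq <- rowMeans(cn$calls != 0)
  expect_equal(mean(freq), 0.3, tolerance = 0.02)
  expect_true(all(cn$calls %in% c(-2, 0, 2)))
})
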