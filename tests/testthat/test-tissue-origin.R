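marker_pools <- function(seed = 1, n_genes = 90, block = 25, shift = 4,
                         pool_sd = 0.3, n_per = 3) {
  # three tissues with disjoint strong marker blocks
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    tissues <- c("FT", "OV", "PER")
    tissue <- rep(tissues, each = n_per)
    base <- rnorm(n_genes, 5, 1)
    proto <- matrix(base, n_genes, 3, dimnames = list(genes, tissues))
    for (k in 1:3) proto[(k - 1) * block + 1:block, k] <-
      proto[(k - 1) * block + 1:block, k] + shift
    m <- proto[, tissue] + matrix(rnorm(n_genes * length(tissue), 0, pool_sd), n_genes)
    colnames(m) <- paste0(tissue, "_", rep(seq_len(n_per), 3))
    list(em = expression_matrix(m, "log_normalized",
                                data.frame(sample_id = colnames(m), tissue = tissue,
                                           stringsAsFactors = FALSE)),
         proto = proto, genes = genes, block = block)
  })
}

test_that("signature derivation recovers disjoint marker blocks", {
  mp <- marker_pools()
  sig <- derive_tissue_signature(mp$em, top_n = 20)
  expect_length(sig$genes, 60)
  true_blocks <- list(FT = mp$genes[1:25], OV = mp$genes[26:50], PER = mp$genes[51:75])
  for (tt in names(true_blocks))
    expect_true(all(sig$markers[[tt]] %in% true_blocks[[tt]]))
  # top_n >= n_genes keeps every gene; the three full lists overlap
  # completely and the union deduplicates them
  sig_all <- derive_tissue_signature(mp$em, top_n = 90)
  expect_setequal(sig_all$genes, mp$genes)
  expect_identical(sig_all$genes, unique(unlist(sig_all$markers, use.names = FALSE)))
  expect_error(derive_tissue_signature(mp$em, top_n = 0), ">= 1")
  # a tissue with < 2 pools is rejected
  short <- mp$em
  keep <- short$samples$tissue != "OV" | short$samples$sample_id == "OV_1"
  short <- expression_matrix(short$values[, keep], "log_normalized",
                             short$samples[keep, ])
  expect_error(derive_tissue_signature(short), "< 2 pools")
})

test_that("signature derivation is deterministic and order-invariant", {
  mp <- marker_pools(seed = 6)
  sig <- derive_tissue_signature(mp$em, top_n = 10)
  perm <- rev(seq_len(ncol(mp$em$values)))
  em_p <- expression_matrix(mp$em$values[, perm], "log_normalized",
                            mp$em$samples[perm, ])
  sig_p <- derive_tissue_signature(em_p, top_n = 10)
  expect_identical(sig$markers, sig_p$markers)
  expect_equal(sig$prototypes, sig_p$prototypes)
})

test_that("tissue DE counts mirror the marker-set asymmetry", {
  np <- generate_normal_pools(normal_pool_config(n_genes = 6000,
                                                 n_ft_markers = 1200,
                                                 n_ov_markers = 90,
                                                 n_per_markers = 90, seed = 3))
  counts <- count_tissue_de(log_normalize(np$expression), alpha = 0.05)
  expect_gt(counts[["FT"]], counts[["OV"]])
  expect_gt(counts[["FT"]], counts[["PER"]])
  # monotone in alpha
  stricter <- count_tissue_de(log_normalize(np$expression), alpha = 0.001)
  expect_true(all(stricter <= counts))
  expect_error(count_tissue_de(log_normalize(np$expression), alpha = 0), "\\(0, 1\\)")
})

test_that("tumor matching is exact on prototypes and invariant to monotone transforms", {
  mp <- marker_pools(seed = 4)
  sig <- derive_tissue_signature(mp$em, top_n = 20)
  # tumors equal to the derived prototypes (or monotone transforms of them)
  tum <- sig$prototypes[, c("FT", "FT", "OV"), drop = FALSE]
  tum[, 2] <- exp(tum[, 2] / 3)  # strictly monotone transform of the FT prototype
  colnames(tum) <- paste0("t", 1:3)
  em <- expression_matrix(tum, "log_normalized")
  res <- match_tissue(em, sig)
  expect_identical(res$call, c("FT", "FT", "OV"))
  expect_equal(res$rho_FT[1], 1)
  expect_equal(res$rho_FT[2], 1)
  expect_identical(res$ft_better_than_ov, c(TRUE, TRUE, FALSE))
  # pairwise winner is consistent with the argmax whenever argmax is FT or OV
  expect_true(all((res$call == "FT") == res$ft_better_than_ov |
                    !res$call %in% c("FT", "OV")))
  # correlating against individual pools then averaging calls the same way
  # on clean profiles
  res_cta <- match_tissue(em, sig, aggregate = "correlate_then_average")
  expect_identical(res_cta$call, res$call)
})

test_that("origin summary reports proportion, exact CI and mean correlations", {
  fake <- data.frame(sample_id = paste0("t", 1:4),
                     rho_FT = c(0.9, 0.8, 0.5, 0.7),
                     rho_OV = c(0.5, 0.9, 0.4, 0.6),
                     rho_PER = c(0.2, 0.3, 0.1, 0.2),
                     call = c("FT", "OV", "FT", "FT"),
                     ft_better_than_ov = c(TRUE, FALSE, TRUE, TRUE))
  s <- summarize_origin(fake)
  expect_equal(s$proportion, 0.75)
  expect_equal(unname(s$ci), unname(clopper_pearson_ci(3, 4)))
  expect_equal(unname(s$mean_rho), c(0.725, 0.6, 0.2))
  none <- fake; none$ft_better_than_ov <- FALSE
  expect_equal(summarize_origin(none)$ci[["lower"]], 0)
  all_ft <- fake; all_ft$ft_better_than_ov <- TRUE
  expect_equal(summarize_origin(all_ft)$ci[["upper"]], 1)
  expect_error(summarize_origin(fake[0, ]), "empty")
})

test_that("fallopian-tube tumors rank peritoneum lowest", {
  np <- generate_normal_pools(normal_pool_config(seed = 5))
  sig <- derive_tissue_signature(log_normalize(np$expression))
  frac <- vapply(1:3, function(s) {
    tum <- generate_tumors_from_tissue(np$prototypes, c(FT = 1, OV = 0, PER = 0),
                                       noise_sd = 0.6, n = 25, seed = s)
    res <- match_tissue(tum$expression, sig)
    mean(max.col(-as.matrix(res[c("rho_FT", "rho_OV", "rho_PER")])) == 3)
  }, numeric(1))
  expect_gte(mean(frac), 0.95)
})
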