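test_that("cohorts are deterministic given config and seed", {
  cfg <- cohort_config(n_cnv_loci = 80, n_genes = 60)
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_equal(a$depth, b$depth)
  expect_equal(a$calls, b$calls)
  expect_equal(a$cn_true, b$cn_true)
  expect_equal(nrow(a$manifest), 66)
  c2 <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$depth, c2$depth))

  expect_error(cohort_config(n_cnv_loci = 3, n_divergent = 5),
               "divergent loci exceed")
})

test_that("noise-free depth yields perfect genotype recovery", {
  cfg <- cohort_config(n_cnv_loci = 100, n_genes = 40, depth_sigma = 0,
                       prop_low_freq = 1)
  co <- simulate_cohort(cfg, seed = 3)
  norm <- suppressWarnings(normalize_depth(co$depth))
  cn <- round_copy_number(norm)
  expect_equal(unname(cn), unname(co$cn_true[rownames(cn), colnames(cn)]))
})

test_that("caller emission is exact at perfect sensitivity and silent at zero", {
  layout <- mk_layout()
  truth <- mk_calls(c(1000, 20000), c(2000, 26000))[, 1:5]
  exact <- emit_caller_calls(truth, "cnvnator",
                             list(sensitivity = 1, jitter = 0,
                                  fp_per_sample = 0), layout, seed = 1)
  expect_equal(exact[, 1:5], truth)

  none <- emit_caller_calls(truth, "pindel",
                            list(sensitivity = 0, jitter = 0,
                                 fp_per_sample = 4), layout, seed = 1)
  expect_true(nrow(none) > 0)      # only false calls remain
  expect_true(all(none$start != 1000))
})

test_that("jittered calls still reciprocally overlap the truth", {
  layout <- mk_layout()
  s <- seq(10000, 490000, by = 10000)
  truth <- mk_calls(s, s + 1000)[, 1:5]
  em <- emit_caller_calls(truth, "delly",
                          list(sensitivity = 1, jitter = 100,
                               fp_per_sample = 0), layout, seed = 5)
  expect_equal(nrow(em), nrow(truth))
  ov <- pmin(em$end, truth$end) - pmax(em$start, truth$start)
  expect_true(all(ov / 1000 >= 0.8))
  expect_true(all(ov / (em$end - em$start) >= 0.8))
})

test_that("engineered gene losses are exactly the zero-copy truth entries", {
  cfg <- cohort_config(n_cnv_loci = 100, n_genes = 60, n_loss_genes = 4)
  co <- simulate_cohort(cfg, seed = 9)
  norm <- suppressWarnings(normalize_depth(co$gene_depth))
  det <- detect_gene_loss(norm)
  key <- function(d) sort(paste(d$gene_id, d$sample))
  expect_equal(key(det), key(co$truth$gene_losses))
  expect_true(all(paste(co$losses$gene_id, co$losses$sample) %in%
                    paste(det$gene_id, det$sample)))
})

test_that("no losses are called when none are engineered and genes are diploid", {
  cfg <- cohort_config(n_cnv_loci = 50, n_genes = 40, n_loss_genes = 0,
                       base_cnv_rate = 0)
  co <- simulate_cohort(cfg, seed = 2)
  norm <- suppressWarnings(normalize_depth(co$gene_depth))
  expect_equal(nrow(detect_gene_loss(norm)), 0)
})

test_that("the diploid guard suppresses loss calls when everyone is low", {
  gene_cn <- matrix(0L, 1, 6, dimnames = list("g1", paste0("s", 1:6)))
  gd <- simulate_gene_depth(gene_cn, mu = 26, sigma = 0.5, seed = 4)
  # normalization cannot center a gene whose median depth is ~0 at CN 0
  # everywhere; feed the raw ratio directly: all entries far below diploid
  norm <- 2 * gd / 26
  expect_equal(nrow(detect_gene_loss(norm)), 0)
})

test_that("carrier sets built per level classify back to that level", {
  co <- simulate_cohort(cohort_config(n_cnv_loci = 20, n_genes = 10), seed = 1)
  levels <- rep(c("Population", "Country", "Continent", "Ancestral"), 10)
  sets <- simulate_carrier_sets(co$manifest, levels, seed = 6)
  got <- vapply(sets, sharing_level, "", manifest = co$manifest)
  expect_equal(unname(got), levels)
})

test_that("the frequency law concentrates mass below 0.05 as configured", {
  cfg <- cohort_config()
  co <- simulate_cohort(cfg, seed = 12)
  p0 <- co$truth$overall_freq
  # binomial tolerance around the configured 70% low-frequency mixture
  expect_lt(abs(mean(p0 < 0.05) - cfg$prop_low_freq),
            4 * sqrt(0.7 * 0.3 / length(p0)))
})

test_that("true biallelic loci are recovered with allele frequencies intact", {
  co <- simulate_cohort(cohort_config(), seed = 4)
  norm <- suppressWarnings(normalize_depth(co$depth))
  cn <- round_copy_number(norm)
  truth <- co$cn_true[rownames(cn), colnames(cn)]
  gt <- genotype_biallelic(cn, co$loci[match(rownames(cn), co$loci$locus_id), ])
  est <- apply(gt$codes, 1, allele_frequency)
  tru <- rowMeans(abs(truth[rownames(gt$codes), , drop = FALSE] - 2)) / 2
  expect_gt(cor(est, tru), 0.98)
})
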