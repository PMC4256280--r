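# independent V_ST oracle via a linear-model variance decomposition:
# 1 - SSW/SST from lm(x ~ group), signed by the mean difference
vst_oracle <- function(x, y) {
  v <- c(x, y)
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  fit <- stats::lm(v ~ g)
  sst <- sum((v - mean(v))^2)
  ssw <- sum(stats::residuals(fit)^2)
  if (sst == 0) return(0)
  mag <- 1 - ssw / sst
  s <- sign(mean(x) - mean(y)); if (s == 0) s <- 1
  mag * s
}

test_that("V_ST matches closed-form worked examples", {
  expect_equal(vst(c(4, 4, 4, 4, 4, 3), c(2, 2, 2, 2, 2, 3)), 5 / 6,
               tolerance = 1e-12)
  expect_equal(vst(c(2, 3, 2, 3), c(2, 3, 2, 3)), 0)
  expect_equal(vst(rep(4, 6), rep(2, 6)), 1)
  expect_equal(vst(rep(2, 6), rep(4, 6)), -1)
  expect_error(vst(1, c(2, 3)), "at least 2")
})

test_that("V_ST equals the ANOVA variance-decomposition oracle", {
  set.seed(101)
  for (rep in 1:1000) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1, sample(1:4, 1)); y <- rnorm(n2, sample(1:4, 1))
    expect_lt(abs(vst(x, y) - vst_oracle(x, y)), 1e-10)
  }
})

test_that("V_ST is invariant under affine transformations", {
  set.seed(33)
  for (rep in 1:50) {
    x <- rnorm(6, 2); y <- rnorm(6, 3)
    v0 <- vst(x, y)
    expect_equal(vst(x + 5, y + 5), v0, tolerance = 1e-10)
    expect_equal(vst(3 * x, 3 * y), v0, tolerance = 1e-10)
    expect_equal(vst(-2 * x + 1, -2 * y + 1), -v0, tolerance = 1e-10)
  }
})

test_that("V_ST scans rank a divergent feature first and sign by direction", {
  manifest <- mk_manifest()
  depth <- matrix(2, 2, 8, dimnames = list(c("flat", "divergent"),
                                           manifest$sample))
  # higher copy in the river (Ca_R: b1, b2) than the lake (Ca_L: a1, a2)
  depth["divergent", c("b1", "b2")] <- 4
  depth["flat", ] <- c(2.1, 1.9, 2.0, 2.0, 2.1, 1.9, 2.0, 2.0)
  scan <- vst_scan(depth, manifest, c("Ca_R", "Ca_L"))
  expect_equal(scan$feature_id[which.max(abs(scan$vst))], "divergent")
  expect_gt(scan$vst[scan$feature_id == "divergent"], 0)
  rev_scan <- vst_scan(depth, manifest, c("Ca_L", "Ca_R"))
  expect_lt(rev_scan$vst[rev_scan$feature_id == "divergent"], 0)

  same <- vst_scan(depth[, c("a1", "a2", "b1", "b2")], manifest,
                   c("Ca_L", "Ca_L"))
  expect_true(all(same$vst == 0))

  expect_error(vst_scan(depth, manifest, c("nope", "Ca_L")),
               "unknown population")
})

test_that("percentile thresholds use linear interpolation on |V_ST|", {
  v <- (1:1000) / 1000
  expect_equal(percentile_threshold(v, 0.999), 0.999, tolerance = 1e-3)
  expect_equal(percentile_threshold(rep(0.4, 10), 0.9), 0.4)
  expect_equal(percentile_threshold(c(0, 1), 0.5), 0.5)
  expect_equal(percentile_threshold(c(-0.8, 0.2), 0.5), 0.5)  # abs values
  expect_error(percentile_threshold(numeric(0), 0.5), "no V_ST")
})

test_that("sharing levels walk the geographic hierarchy", {
  manifest <- mk_manifest()
  expect_equal(sharing_level(c("a1", "a2"), manifest), "Population")
  expect_equal(sharing_level(c("a1", "b1"), manifest), "Country")
  expect_equal(sharing_level(c("a1", "c1"), manifest), "Continent")
  expect_equal(sharing_level(c("a1", "d1"), manifest), "Ancestral")
  expect_equal(sharing_level("a1", manifest), "Population")
  expect_error(sharing_level(character(0), manifest), "nonempty")
  expect_error(sharing_level("zz", manifest), "unknown sample")
})

test_that("adding carriers never moves the sharing level toward Population", {
  manifest <- mk_manifest()
  lev_rank <- function(carriers) match(sharing_level(carriers, manifest),
                                       c("Population", "Country",
                                         "Continent", "Ancestral"))
  set.seed(21)
  for (rep in 1:50) {
    base <- sample(manifest$sample, sample(1:4, 1))
    extra <- sample(setdiff(manifest$sample, base), 1)
    expect_gte(lev_rank(c(base, extra)), lev_rank(base))
  }
})

test_that("pairwise sharing proportions follow the Jaccard rule", {
  manifest <- mk_manifest()
  a <- mk_calls(c(0, 5000, 10000), c(1000, 6000, 11000), sample = "a1")
  b_match2 <- mk_calls(c(0, 5000, 20000), c(1000, 6000, 21000), sample = "a2")
  other <- do.call(rbind, lapply(setdiff(manifest$sample, c("a1", "a2")),
                                 function(s) mk_calls(50000, 51000, sample = s)))
  calls <- rbind(a, b_match2, other)
  res <- pairwise_sharing(calls, manifest)
  expect_equal(res$matrix["a1", "a2"], 2 / 4)   # 2 matched of 3 + 3 calls
  expect_equal(res$matrix["c1", "c2"], 1)       # identical single calls
  expect_equal(res$matrix["a1", "c1"], 0)       # disjoint
  expect_equal(unname(res$group_means["Within Populations"]),
               mean(c(0.5, 1, 1, 1)))
})

test_that("fixation summary flags fixed and fully present loci", {
  manifest <- mk_manifest()
  codes <- rbind(
    fixed = c(0L, 0L, rep(2L, 6)),               # Ca_L all hom-del
    present = c(0L, 1L, rep(2L, 6)),             # Ca_L all carry
    neither = c(1L, 2L, rep(2L, 6))
  )
  colnames(codes) <- manifest$sample
  loci <- data.frame(locus_id = rownames(codes), chrom = "groupI",
                     start = 1:3 * 1000L, end = 1:3 * 1000L + 100L,
                     allele_type = "DEL", stringsAsFactors = FALSE)
  fs <- fixation_summary(biallelic_genotypes(loci, codes), manifest)
  cal <- fs[fs$population == "Ca_L", ]
  expect_true(cal$fixed[cal$locus_id == "fixed"])
  expect_true(cal$present_in_all[cal$locus_id == "fixed"])
  expect_false(cal$fixed[cal$locus_id == "present"])
  expect_true(cal$present_in_all[cal$locus_id == "present"])
  expect_false(cal$present_in_all[cal$locus_id == "neither"])
  expect_true(all(fs$absent[fs$population == "Us_R"]))
})
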