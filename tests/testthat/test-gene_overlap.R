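# gene on groupI spanning [1000, 2000) with exons [1000,1200) and [1800,2000)
mk_ann <- function() {
  genes <- data.frame(gene_id = "g1", chrom = "groupI", start = 1000L,
                      end = 2000L, biotype = "protein_coding",
                      category = "non-LSG singleton", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = c(1000L, 1800L),
                      end = c(1200L, 2000L))
  gene_annotation(genes, exons)
}

mk_region <- function(start, end, svtypes = list("DEL"), chrom = "groupI") {
  data.frame(region_id = "r1", chrom = chrom, start = start, end = end,
             n_carriers = 1L, svtypes = I(svtypes),
             carriers = I(list("A")), stringsAsFactors = FALSE)
}

test_that("genomic context classes are assigned per the exon/gene rules", {
  ann <- mk_ann()
  # strictly inside the intron [1200, 1800)
  expect_equal(classify_genomic_context(mk_region(1300, 1600), ann), "intronic")
  # covers the gene completely
  expect_equal(classify_genomic_context(mk_region(900, 2100), ann), "full_gene")
  # touches an exon but covers only 40% of the gene
  expect_equal(classify_genomic_context(mk_region(1100, 1500), ann),
               "partial_exonic")
  # no gene base overlapped
  expect_equal(classify_genomic_context(mk_region(5000, 6000), ann),
               "intergenic")
  # the four classes partition any region set
  regions <- do.call(rbind, list(mk_region(1300, 1600), mk_region(900, 2100),
                                 mk_region(1100, 1500), mk_region(5000, 6000)))
  cls <- classify_genomic_context(regions, ann)
  expect_equal(length(cls), nrow(regions))
  expect_true(all(cls %in% c("intergenic", "intronic", "partial_exonic",
                             "full_gene")))
})

test_that("touching a second gene's exon forces partial_exonic", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "groupI",
                      start = c(1000L, 2000L), end = c(2000L, 2400L),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("g1", "g1", "g2"),
                      start = c(1000L, 1800L, 2000L),
                      end = c(1200L, 2000L, 2400L))
  ann <- gene_annotation(genes, exons)
  # intronic within g1 alone, but extends into g2's exon
  reg <- mk_region(1300, 2100)
  expect_equal(classify_genomic_context(reg, ann), "partial_exonic")
})

test_that("CNV genes require strictly more than 95% coverage by the union", {
  ann <- mk_ann()   # gene length 1000
  expect_equal(nrow(cnv_genes(mk_region(1000, 1960), ann)), 1)  # 96%
  expect_equal(nrow(cnv_genes(mk_region(1000, 1950), ann)), 0)  # exactly 95%
  # two adjacent regions jointly covering 100%
  two <- rbind(mk_region(900, 1500), mk_region(1500, 2050))
  two$region_id <- c("r1", "r2")
  expect_equal(nrow(cnv_genes(two, ann)), 1)
  # svtype aggregation across covering regions
  two$svtypes <- list("DEL", "DUP")
  expect_equal(cnv_genes(two, ann)$svtypes, "both")
})

test_that("adding regions never removes a CNV gene", {
  set.seed(13)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "groupI",
                      start = (0:19) * 5000L, end = (0:19) * 5000L + 2000L,
                      stringsAsFactors = FALSE)
  ann <- gene_annotation(genes)
  for (rep in 1:5) {
    s <- sort(sample.int(95000, 12))
    regions <- data.frame(region_id = sprintf("r%02d", 1:12), chrom = "groupI",
                          start = s, end = s + sample(1000:6000, 12, TRUE),
                          stringsAsFactors = FALSE)
    before <- cnv_genes(regions[1:6, ], ann)$gene_id
    after <- cnv_genes(regions, ann)$gene_id
    expect_true(all(before %in% after))
  }
})

test_that("category tallies conserve totals and proportions", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "groupI",
                      start = (0:19) * 5000L, end = (0:19) * 5000L + 1000L,
                      category = rep(c("LSG LSD", "non-LSG singleton"), 10),
                      stringsAsFactors = FALSE)
  ann <- gene_annotation(genes)
  # cover genes 1..3 fully (categories alternate starting at LSG LSD)
  regions <- data.frame(region_id = c("r1", "r2", "r3"), chrom = "groupI",
                        start = c(0L, 5000L, 10000L) - 10L,
                        end = c(1000L, 6000L, 11000L) + 10L,
                        svtypes = I(list("DEL", "DEL", "DUP")),
                        stringsAsFactors = FALSE)
  cg <- cnv_genes(regions, ann)
  tab <- category_counts(cg, ann)
  expect_equal(sum(tab$n_cnv), nrow(cg))
  expect_equal(tab$n_genes, c(10L, 10L))
  expect_equal(tab$proportion[tab$category == "LSG LSD"], 2 / 10)
  expect_equal(tab$proportion[tab$category == "non-LSG singleton"], 1 / 10)

  empty <- category_counts(cg[0, ], ann)
  expect_true(all(empty$n_cnv == 0))
})
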