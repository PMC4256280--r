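#' Genome layout
#'
#' Chromosome lengths and the set of sex chromosomes. The stickleback sex
#' chromosome is linkage group XIX; calls on sex chromosomes are removed
#' during filtering because male hemizygosity mimics deletion signal.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @param sex_chromosomes Character vector of sex chromosome names.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(lengths, sex_chromosomes = "groupXIX") {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("chromosome lengths must be named")
  }
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  extra <- setdiff(sex_chromosomes, names(lengths))
  sex_chromosomes <- intersect(sex_chromosomes, names(lengths))
  structure(list(lengths = lengths, sex_chromosomes = sex_chromosomes),
            class = "genome_layout")
}

#' Sample manifest
#'
#' The cohort hierarchy: each sample belongs to one population, each
#' population to one country, each country to one continent, and each sample
#' carries an ecotype (lake, river or marine). The hierarchy drives the
#' geographic sharing classification.
#'
#' @param df Data frame with columns `sample`, `population`, `country`,
#'   `continent`, `ecotype`.
#' @return An object of class `cnv_manifest` (a validated data frame).
#' @export
cnv_manifest <- function(df) {
  req <- c("sample", "population", "country", "continent", "ecotype")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, req]
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  if (!all(df$ecotype %in% ECOTYPES)) {
    stop("ecotype must be one of: ", paste(ECOTYPES, collapse = ", "))
  }
  p2c <- unique(df[, c("population", "country")])
  if (anyDuplicated(p2c$population)) {
    stop("population mapped to more than one country")
  }
  c2c <- unique(df[, c("country", "continent")])
  if (anyDuplicated(c2c$country)) {
    stop("country mapped to more than one continent")
  }
  rownames(df) <- df$sample
  class(df) <- c("cnv_manifest", "data.frame")
  df
}

#' Read a sample manifest from TSV
#'
#' @param path TSV file with header columns
#'   `sample`, `population`, `country`, `continent`, `ecotype`.
#' @return A `cnv_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  cnv_manifest(df)
}

#' Write a sample manifest to TSV
#'
#' @param manifest A `cnv_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(), con)
  utils::write.table(as.data.frame(manifest), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# population -> country / country -> continent lookups
.pop_country <- function(manifest) {
  u <- unique(as.data.frame(manifest)[, c("population", "country")])
  stats::setNames(u$country, u$population)
}
.country_continent <- function(manifest) {
  u <- unique(as.data.frame(manifest)[, c("country", "continent")])
  stats::setNames(u$continent, u$country)
}

#' Read genomic intervals
#'
#' Reads intervals from BED (0-based half-open), GFF3 (1-based closed) or a
#' caller call table (`caller_tsv`: TSV with columns chrom, start, end,
#' svtype, sample, caller). All coordinates are normalized to the internal
#' 0-based half-open convention. Records with non-positive length after
#' normalization are dropped with a warning.
#'
#' @param path Input file.
#' @param dialect One of `"bed"`, `"gff3"`, `"caller_tsv"`.
#' @param one_based For `caller_tsv` only: set `TRUE` if the file declares
#'   1-based closed coordinates.
#' @return A data frame of intervals; for `caller_tsv` a CNV call table with
#'   columns chrom, start, end, svtype, sample, caller.
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3", "caller_tsv"),
                           one_based = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    df <- .as_intervals(gr)
    if (!is.null(gr$name)) df$name <- gr$name
    if (!is.null(gr$score)) df$score <- as.numeric(gr$score)
  } else if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- .as_intervals(gr)
    df$type <- as.character(gr$type)
    if (!is.null(gr$ID)) df$id <- as.character(gr$ID)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if (one_based) df$start <- df$start - 1L
    df <- .check_calls(.check_intervals(df, "caller_tsv"))
  }
  .check_intervals(df, dialect)
}

#' Write caller calls to TSV
#'
#' @param calls CNV call table.
#' @param path Output path.
#' @param params Optional named list recorded in the header comment.
#' @export
write_calls <- function(calls, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(params), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene annotation set
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `biotype`, `category` and optionally `family_id`.
#' @param exons Data frame with columns `gene_id`, `start`, `end`; exons must
#'   lie within the gene span, be non-overlapping and sorted.
#' @return Object of class `gene_annotation`: list with elements `genes` and
#'   `exons`.
#' @export
gene_annotation <- function(genes, exons = NULL) {
  req <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0) stop("genes missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (any(genes$end <= genes$start)) stop("genes must satisfy end > start")
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (is.null(genes$category)) genes$category <- "unknown"
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  }
  span <- stats::setNames(split(genes[, c("start", "end")], genes$gene_id),
                          NULL)
  g <- genes[match(exons$gene_id, genes$gene_id), ]
  if (any(is.na(g$gene_id))) stop("exon references unknown gene_id")
  if (any(exons$start < g$start | exons$end > g$end)) {
    stop("exons must lie within the gene span")
  }
  ord <- order(exons$gene_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (idx in by_gene) {
    if (length(idx) > 1) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1] < e[-length(e)])) stop("exons within a gene must not overlap")
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' Read gene annotations from GFF3
#'
#' Gene features become gene records; exon features are attached to their
#' gene via the `Parent`/`ID` chain (transcript level is collapsed: exon
#' coordinates are unioned per gene). Orthology categories, when present, are
#' read from a `category` attribute.
#'
#' @param path GFF3 file.
#' @return A `gene_annotation`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- as.character(gr$type) == "gene"
  gdf <- .as_intervals(gr[is_gene])
  gdf$gene_id <- as.character(gr$ID[is_gene])
  gdf$biotype <- if (!is.null(gr$biotype)) as.character(gr$biotype[is_gene]) else "protein_coding"
  if (!is.null(gr$category)) gdf$category <- as.character(gr$category[is_gene])
  if (!is.null(gr$family_id)) gdf$family_id <- as.character(gr$family_id[is_gene])

  # map transcripts (mRNA etc.) to genes, then exons to genes
  parent_of <- function(x) vapply(x, function(p) if (length(p)) p[[1]] else NA_character_, "")
  ids <- as.character(gr$ID)
  parents <- parent_of(gr$Parent)
  tx2gene <- stats::setNames(parents, ids)
  is_exon <- as.character(gr$type) == "exon"
  exon_parent <- parents[is_exon]
  exon_gene <- ifelse(exon_parent %in% gdf$gene_id, exon_parent,
                      tx2gene[exon_parent])
  edf <- .as_intervals(gr[is_exon])
  edf$gene_id <- unname(exon_gene)
  edf <- edf[!is.na(edf$gene_id), c("gene_id", "start", "end")]
  if (nrow(edf) > 0) {
    # collapse overlapping exon copies from multiple transcripts
    parts <- split(edf, edf$gene_id)
    edf <- do.call(rbind, lapply(parts, function(p) {
      r <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
      data.frame(gene_id = p$gene_id[1], start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), stringsAsFactors = FALSE)
    }))
    rownames(edf) <- NULL
  } else {
    edf <- NULL
  }
  gene_annotation(gdf, edf)
}

GT_BY_CODE <- c("1/1", "0/1", "0/0", "0/1", "1/1")  # codes 0..4

#' Write bi-allelic CNV genotypes as VCF 4.2
#'
#' Loci are written with symbolic ALT `<DEL>` or `<DUP>`, INFO fields `END`
#' and `SVTYPE`, and per-sample `GT:CN`. Genotype codes 0 (hom del), 1 (het
#' del), 2 (wild type), 3 (het dup), 4 (hom dup) map to GT 1/1, 0/1, 0/0,
#' 0/1, 1/1; CN is the integer copy-number (equal to the code).
#'
#' @param genotypes A `cnv_genotypes` object (see [biallelic_genotypes()]).
#' @param manifest A `cnv_manifest` covering every genotyped sample.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(genotypes, manifest, path) {
  stopifnot(inherits(genotypes, "cnv_genotypes"))
  samples <- colnames(genotypes$codes)
  missing <- setdiff(samples, manifest$sample)
  if (length(missing) > 0) {
    stop("sample(s) absent from manifest: ", paste(missing, collapse = ", "))
  }
  loci <- genotypes$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=cnvpop %s",
            tryCatch(as.character(utils::packageVersion("cnvpop")),
                     error = function(e) "dev")),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Integer copy number\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(loci))) {
    codes <- genotypes$codes[i, ]
    if (any(!codes %in% 0:4)) stop("genotype codes must be in 0..4")
    gt <- paste(GT_BY_CODE[codes + 1L], codes, sep = ":")
    row <- c(loci$chrom[i],
             loci$start[i] + 1L,             # internal 0-based -> VCF POS
             loci$locus_id[i],
             "N",
             sprintf("<%s>", loci$allele_type[i]),
             ".", "PASS",
             sprintf("END=%d;SVTYPE=%s", loci$end[i], loci$allele_type[i]),
             "GT:CN",
             gt)
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cnvpop genotype VCF
#'
#' Inverse of [write_genotypes_vcf()]; recovers loci and integer genotype
#' codes from the `CN` FORMAT field.
#'
#' @param path VCF file.
#' @return A `cnv_genotypes` object.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ends <- as.integer(sub(".*END=([0-9]+).*", "\\1", fix$INFO))
  svtype <- sub(".*SVTYPE=([A-Z]+).*", "\\1", fix$INFO)
  cn <- vcfR::extract.gt(v, element = "CN", as.numeric = TRUE)
  loci <- data.frame(
    locus_id = fix$ID,
    chrom = fix$CHROM,
    start = as.integer(fix$POS) - 1L,
    end = ends,
    allele_type = svtype,
    stringsAsFactors = FALSE
  )
  codes <- matrix(as.integer(cn), nrow = nrow(cn),
                  dimnames = list(loci$locus_id, colnames(cn)))
  biallelic_genotypes(loci, codes)
}

#' Write CNV regions as BED
#'
#' BED6-style rows: name is the region id, score the carrier count, strand
#' ".", plus two extra columns with comma-joined SV types and carriers.
#'
#' @param regions A CNV region table from [delineate_regions()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  ord <- order(regions$chrom, regions$start)
  if (is.unsorted(ord)) {
    message("regions were not sorted by (chrom, start); sorting on write")
  }
  regions <- regions[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(), con)
  if (nrow(regions) > 0) {
    rows <- paste(regions$chrom, regions$start, regions$end,
                  regions$region_id, regions$n_carriers, ".",
                  vapply(regions$svtypes, paste, "", collapse = ","),
                  vapply(regions$carriers, paste, "", collapse = ","),
                  sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a cnvpop region BED
#'
#' @param path File written by [write_regions_bed()].
#' @return A CNV region table.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_carriers = integer(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    region_id = vapply(f, `[`, "", 4),
    chrom = vapply(f, `[`, "", 1),
    start = as.integer(vapply(f, `[`, "", 2)),
    end = as.integer(vapply(f, `[`, "", 3)),
    n_carriers = as.integer(vapply(f, `[`, "", 5)),
    stringsAsFactors = FALSE
  )
  df$svtypes <- lapply(f, function(x) strsplit(x[7], ",", fixed = TRUE)[[1]])
  df$carriers <- lapply(f, function(x) strsplit(x[8], ",", fixed = TRUE)[[1]])
  df
}

#' Write a depth or copy-number matrix to TSV
#'
#' @param mat loci x samples matrix with locus ids as rownames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(locus_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth or copy-number matrix from TSV
#'
#' @param path TSV with a `locus_id` column followed by one column per sample.
#' @return Numeric matrix with locus ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
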