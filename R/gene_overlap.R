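# Annotation of CNV regions against genes: genomic-context classes,
# CNV-gene calls under the >95% coverage rule, and category tallies.

CONTEXT_CLASSES <- c("intergenic", "intronic", "partial_exonic", "full_gene")

# per-gene exonic GRanges
.exon_granges <- function(annotation) {
  e <- annotation$exons
  g <- annotation$genes
  chrom <- g$chrom[match(e$gene_id, g$gene_id)]
  .as_granges(data.frame(chrom = chrom, start = e$start, end = e$end))
}

#' Classify the genomic context of CNV regions
#'
#' Four mutually exclusive classes: `full_gene` when the region covers more
#' than `gene_full_overlap_frac` of at least one gene; `intergenic` when it
#' overlaps no gene base; `intronic` when every overlapped base lies within
#' introns (no exon of any overlapping gene is touched); `partial_exonic`
#' otherwise.
#'
#' @param regions CNV region table.
#' @param annotation A [gene_annotation()].
#' @param thresholds A [cnv_thresholds()] list.
#' @return Character vector of classes, one per region.
#' @export
classify_genomic_context <- function(regions, annotation,
                                     thresholds = cnv_thresholds()) {
  if (nrow(regions) == 0) return(character())
  frac <- thresholds$gene_full_overlap_frac
  rgr <- .as_granges(regions)
  ggr <- .as_granges(annotation$genes)
  egr <- .exon_granges(annotation)

  gene_hits <- GenomicRanges::findOverlaps(rgr, ggr)
  qi <- S4Vectors::queryHits(gene_hits); si <- S4Vectors::subjectHits(gene_hits)
  ov <- .overlap_len(regions$start[qi], regions$end[qi],
                     annotation$genes$start[si], annotation$genes$end[si])
  glen <- annotation$genes$end[si] - annotation$genes$start[si]
  full <- tapply(ov > frac * glen, qi, any)

  touches_gene <- logical(nrow(regions))
  touches_gene[unique(qi)] <- TRUE
  touches_exon <- IRanges::overlapsAny(rgr, egr)

  out <- rep("intergenic", nrow(regions))
  out[touches_gene & !touches_exon] <- "intronic"
  out[touches_exon] <- "partial_exonic"
  out[as.integer(names(full))[unlist(full)]] <- "full_gene"
  out
}

#' Identify CNV genes
#'
#' A gene is a CNV gene when the union of CNV regions covers more than
#' `gene_full_overlap_frac` (default 0.95, a 5\% leeway for imperfect
#' breakpoints) of its span. SV types are aggregated over the covering
#' regions.
#'
#' @param regions CNV region table (needs list-column `svtypes`, as from
#'   [delineate_regions()]; a plain interval table is accepted and treated
#'   as type-less).
#' @param annotation A [gene_annotation()].
#' @param thresholds A [cnv_thresholds()] list.
#' @return Data frame of CNV genes: `gene_id`, `category`, `covered_frac`,
#'   and `svtypes` (`"DEL"`, `"DUP"` or `"both"`).
#' @export
cnv_genes <- function(regions, annotation, thresholds = cnv_thresholds()) {
  genes <- annotation$genes
  empty <- data.frame(gene_id = character(), category = character(),
                      covered_frac = numeric(), svtypes = character(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0 || nrow(genes) == 0) return(empty)
  frac <- thresholds$gene_full_overlap_frac
  rgr <- GenomicRanges::reduce(.as_granges(regions))
  ggr <- .as_granges(genes)
  hits <- GenomicRanges::findOverlaps(ggr, rgr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) return(empty)
  inter <- GenomicRanges::pintersect(ggr[qi], rgr[si])
  cov_bp <- tapply(GenomicRanges::width(inter), qi, sum)
  gidx <- as.integer(names(cov_bp))
  covered <- as.numeric(cov_bp) / (genes$end[gidx] - genes$start[gidx])
  keep <- covered > frac
  gidx <- gidx[keep]; covered <- covered[keep]
  if (length(gidx) == 0) return(empty)

  svtypes <- rep("unknown", length(gidx))
  if (!is.null(regions$svtypes)) {
    orig_rgr <- .as_granges(regions)
    gh <- GenomicRanges::findOverlaps(ggr[gidx], orig_rgr)
    tl <- lapply(split(S4Vectors::subjectHits(gh), S4Vectors::queryHits(gh)),
                 function(ri) sort(unique(unlist(regions$svtypes[ri]))))
    sv <- vapply(tl, function(x) {
      if (length(x) > 1) "both" else x
    }, "")
    svtypes <- rep(NA_character_, length(gidx))
    svtypes[as.integer(names(sv))] <- sv
  }
  data.frame(
    gene_id = genes$gene_id[gidx],
    category = genes$category[gidx],
    covered_frac = covered,
    svtypes = svtypes,
    stringsAsFactors = FALSE
  )
}

#' Tally CNV genes by orthology category
#'
#' @param cnv_gene_set Output of [cnv_genes()].
#' @param annotation A [gene_annotation()]; category sizes come from its
#'   full gene set.
#' @return Data frame with one row per category: total genes, CNV-gene
#'   counts split by SV type, and the CNV proportion.
#' @export
category_counts <- function(cnv_gene_set, annotation) {
  genes <- annotation$genes
  cat_col <- genes$category
  cat_col[is.na(cat_col) | !nzchar(cat_col)] <- "unknown"
  if (any(cat_col == "unknown")) {
    warning("genes without a category counted under 'unknown'")
  }
  cats <- sort(unique(cat_col))
  tot <- table(factor(cat_col, levels = cats))
  cg_cat <- cnv_gene_set$category
  cg_cat[is.na(cg_cat) | !nzchar(cg_cat)] <- "unknown"
  cnt <- table(factor(cg_cat, levels = cats))
  by_type <- function(type) {
    sel <- cnv_gene_set$svtypes == type
    table(factor(cg_cat[sel], levels = cats))
  }
  data.frame(
    category = cats,
    n_genes = as.integer(tot),
    n_cnv = as.integer(cnt),
    n_del = as.integer(by_type("DEL")),
    n_dup = as.integer(by_type("DUP")),
    n_both = as.integer(by_type("both")),
    proportion = ifelse(tot > 0, as.integer(cnt) / as.integer(tot), NA_real_),
    stringsAsFactors = FALSE
  )
}
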