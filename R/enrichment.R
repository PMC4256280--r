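# Length- and chromosome-matched permutation tests for over- and
# under-representation of gene categories among CNV regions.

#' Randomly place regions preserving counts and lengths
#'
#' For each chromosome and SV type the same number of intervals with exactly
#' the same lengths is placed with start positions uniform on
#' [0, L - length]. Permuted regions may overlap each other and ignore the
#' repeat mask unless `mask` is supplied, in which case placements
#' overlapping the mask by more than half their length are redrawn.
#'
#' @param regions Region table (chrom/start/end, optional `svtypes`).
#' @param layout A [genome_layout()].
#' @param seed Optional integer seed.
#' @param mask Optional masked intervals to avoid.
#' @return Region table with the same per-chromosome, per-type length
#'   multiset and random starts.
#' @export
permute_regions <- function(regions, layout, seed = NULL, mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(regions) == 0) return(regions)
  len <- regions$end - regions$start
  L <- layout$lengths[regions$chrom]
  if (any(is.na(L))) stop("region chromosome absent from layout")
  if (any(len > L)) stop("region longer than its chromosome")
  draw <- function() floor(stats::runif(nrow(regions), 0, L - len + 1))
  starts <- draw()
  if (!is.null(mask) && nrow(mask) > 0) {
    mask_gr <- GenomicRanges::reduce(.as_granges(mask))
    for (it in 1:100) {
      cand <- data.frame(chrom = regions$chrom, start = starts,
                         end = starts + len)
      gr <- .as_granges(cand)
      hits <- GenomicRanges::findOverlaps(gr, mask_gr)
      qi <- S4Vectors::queryHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        gr[qi], mask_gr[S4Vectors::subjectHits(hits)]))
      bad_bp <- tapply(ov, qi, sum)
      bad <- rep(FALSE, nrow(regions))
      bad[as.integer(names(bad_bp))] <- as.numeric(bad_bp) > 0.5 * len[as.integer(names(bad_bp))]
      if (!any(bad)) break
      redraw <- floor(stats::runif(sum(bad), 0, (L - len + 1)[bad]))
      starts[bad] <- redraw
    }
  }
  out <- regions
  out$start <- as.integer(starts)
  out$end <- as.integer(starts + len)
  out
}

#' Permutation enrichment of gene categories among CNVs
#'
#' The observed statistic is the CNV-gene count per category (genes covered
#' beyond the full-overlap threshold by the union of regions). Each
#' permutation redraws the regions with [permute_regions()] (preserving
#' per-chromosome counts and lengths) and recomputes the counts. P-values
#' use the add-one correction p = (1 + #{permuted >= observed}) / (n + 1),
#' so they are never zero at finite permutation numbers.
#'
#' @param regions Observed region table.
#' @param annotation A [gene_annotation()] with category labels.
#' @param layout A [genome_layout()].
#' @param thresholds A [cnv_thresholds()] list (uses `n_permutations` and
#'   `gene_full_overlap_frac`).
#' @param seed Integer seed for the permutation stream.
#' @param mask Optional masked intervals passed to the permuter.
#' @return Data frame with one row per category: observed count,
#'   permutation mean and sd, `p_over`, `p_under`, `n_permutations`, `seed`.
#' @export
enrichment_test <- function(regions, annotation, layout,
                            thresholds = cnv_thresholds(), seed = 1,
                            mask = NULL) {
  n_perm <- thresholds$n_permutations
  if (n_perm < 1) stop("need at least one permutation")
  cats <- sort(unique(annotation$genes$category))
  count_by_cat <- function(r) {
    cg <- cnv_genes(r, annotation, thresholds)
    table(factor(cg$category, levels = cats))
  }
  observed <- count_by_cat(regions)
  set.seed(seed)
  perm <- matrix(0L, n_perm, length(cats), dimnames = list(NULL, cats))
  for (b in seq_len(n_perm)) {
    rp <- permute_regions(regions, layout, seed = NULL, mask = mask)
    perm[b, ] <- as.integer(count_by_cat(rp))
  }
  obs <- as.integer(observed)
  p_over <- (1 + colSums(perm >= rep(obs, each = n_perm))) / (n_perm + 1)
  p_under <- (1 + colSums(perm <= rep(obs, each = n_perm))) / (n_perm + 1)
  data.frame(
    category = cats,
    observed = obs,
    perm_mean = colMeans(perm),
    perm_sd = apply(perm, 2, stats::sd),
    p_over = as.numeric(p_over),
    p_under = as.numeric(p_under),
    n_permutations = n_perm,
    seed = seed,
    stringsAsFactors = FALSE
  )
}
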