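# Multi-caller consensus: merge within caller, require cross-caller support
# for read-depth calls, apply length/sex-chromosome/repeat/all-individual
# filters, and delineate cross-individual CNV regions.

#' Merge overlapping calls within one caller
#'
#' Two calls from the same individual, caller and SV type merge when their
#' overlap exceeds `within_caller_merge_frac` of the shorter call; merging is
#' applied to transitive closure (the merged span is the union), so the
#' result is idempotent and independent of input order.
#'
#' @param calls Call table sharing sample, caller and svtype per chromosome
#'   group (mixed chromosomes are handled; mixed samples/callers are
#'   rejected).
#' @param thresholds A [cnv_thresholds()] list.
#' @return Merged call table, sorted by (chrom, start).
#' @export
merge_within_caller <- function(calls, thresholds = cnv_thresholds()) {
  calls <- .check_calls(calls)
  if (nrow(calls) == 0) return(calls)
  if (length(unique(calls$sample)) > 1 || length(unique(calls$caller)) > 1) {
    stop("merge_within_caller expects calls from a single sample and caller")
  }
  frac <- thresholds$within_caller_merge_frac
  parts <- split(calls, list(calls$chrom, calls$svtype), drop = TRUE)
  out <- lapply(parts, function(p) {
    repeat {
      n <- nrow(p)
      if (n < 2) break
      merged_any <- FALSE
      # greedy fixpoint: scan pairs, union qualifying ones, restart
      ord <- order(p$start, p$end)
      p <- p[ord, , drop = FALSE]
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          ov <- .overlap_len(p$start[i], p$end[i], p$start[j], p$end[j])
          shorter <- min(p$end[i] - p$start[i], p$end[j] - p$start[j])
          if (ov > frac * shorter) {
            p$start[i] <- min(p$start[i], p$start[j])
            p$end[i] <- max(p$end[i], p$end[j])
            p <- p[-j, , drop = FALSE]
            merged_any <- TRUE
            break
          }
        }
        if (merged_any) break
      }
      if (!merged_any) break
    }
    p
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep read-depth calls supported by another approach
#'
#' A primary (read-depth) call is retained when at least one call of the
#' same sample and SV type from a different approach overlaps more than
#' `cross_caller_support_frac` of the primary call's length.
#'
#' @param primary_calls Calls from the read-depth caller.
#' @param other_calls Calls from the paired-end / split-read approaches.
#' @param thresholds A [cnv_thresholds()] list.
#' @return The supported subset of `primary_calls`.
#' @export
cross_caller_support <- function(primary_calls, other_calls,
                                 thresholds = cnv_thresholds()) {
  primary_calls <- .check_calls(primary_calls)
  if (nrow(primary_calls) == 0) return(primary_calls)
  if (nrow(other_calls) == 0) {
    message("no supporting calls available; all primary calls dropped")
    return(primary_calls[0, , drop = FALSE])
  }
  other_calls <- .check_calls(other_calls)
  frac <- thresholds$cross_caller_support_frac
  keep <- logical(nrow(primary_calls))
  hits <- GenomicRanges::findOverlaps(.as_granges(primary_calls),
                                      .as_granges(other_calls))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ok <- primary_calls$sample[qi] == other_calls$sample[si] &
    primary_calls$svtype[qi] == other_calls$svtype[si]
  qi <- qi[ok]; si <- si[ok]
  ov <- .overlap_len(primary_calls$start[qi], primary_calls$end[qi],
                     other_calls$start[si], other_calls$end[si])
  plen <- primary_calls$end[qi] - primary_calls$start[qi]
  keep[unique(qi[ov > frac * plen])] <- TRUE
  primary_calls[keep, , drop = FALSE]
}

#' Filter merged, supported calls
#'
#' Applies, in order: minimum length, sex-chromosome removal, repeat-mask
#' overlap, and exclusion of call clusters present in all individuals
#' (reference-genome artifacts). Clusters are formed by reciprocal overlap
#' (> `reciprocal_share_frac` of both lengths, same SV type) across samples.
#'
#' @param calls Call table (all samples).
#' @param repeat_mask Data frame of masked intervals (chrom/start/end), or
#'   `NULL` to skip.
#' @param layout A [genome_layout()].
#' @param n_samples Number of individuals in the cohort.
#' @param thresholds A [cnv_thresholds()] list.
#' @return Filtered call table with an attribute `removed` tabulating the
#'   number of calls removed per rule.
#' @export
apply_filters <- function(calls, repeat_mask = NULL, layout, n_samples,
                          thresholds = cnv_thresholds()) {
  calls <- .check_calls(calls)
  removed <- c(short = 0L, sex_chromosome = 0L, repeat_mask = 0L,
               all_individuals = 0L)

  len <- calls$end - calls$start
  removed["short"] <- sum(len < thresholds$min_call_len)
  calls <- calls[len >= thresholds$min_call_len, , drop = FALSE]

  on_sex <- calls$chrom %in% layout$sex_chromosomes
  removed["sex_chromosome"] <- sum(on_sex)
  calls <- calls[!on_sex, , drop = FALSE]

  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0 && nrow(calls) > 0) {
    mask_gr <- GenomicRanges::reduce(.as_granges(repeat_mask))
    call_gr <- .as_granges(calls)
    hits <- GenomicRanges::findOverlaps(call_gr, mask_gr)
    inter <- GenomicRanges::pintersect(call_gr[S4Vectors::queryHits(hits)],
                                       mask_gr[S4Vectors::subjectHits(hits)])
    masked_bp <- tapply(GenomicRanges::width(inter),
                        S4Vectors::queryHits(hits), sum)
    frac_masked <- numeric(nrow(calls))
    frac_masked[as.integer(names(masked_bp))] <-
      masked_bp / (calls$end - calls$start)[as.integer(names(masked_bp))]
    drop <- frac_masked > thresholds$repeat_mask_frac
    removed["repeat_mask"] <- sum(drop)
    calls <- calls[!drop, , drop = FALSE]
  }

  if (nrow(calls) > 0) {
    comp <- .reciprocal_components(calls, thresholds$reciprocal_share_frac)
    carriers_per_comp <- tapply(calls$sample, comp,
                                function(s) length(unique(s)))
    in_all <- names(carriers_per_comp)[carriers_per_comp == n_samples]
    drop <- comp %in% in_all
    removed["all_individuals"] <- sum(drop)
    calls <- calls[!drop, , drop = FALSE]
  }

  rownames(calls) <- NULL
  attr(calls, "removed") <- removed
  calls
}

# connected components of the reciprocal-overlap graph (same svtype);
# used for the all-individuals exclusion
.reciprocal_components <- function(calls, frac) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  gr <- .as_granges(calls)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ok <- qi < si & calls$svtype[qi] == calls$svtype[si]
  qi <- qi[ok]; si <- si[ok]
  if (length(qi) > 0) {
    ov <- .overlap_len(calls$start[qi], calls$end[qi],
                       calls$start[si], calls$end[si])
    l1 <- calls$end[qi] - calls$start[qi]
    l2 <- calls$end[si] - calls$start[si]
    recip <- ov > frac * l1 & ov > frac * l2
    for (k in which(recip)) {
      a <- find(qi[k]); b <- find(si[k])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Delineate CNV regions across individuals
#'
#' CNV regions are contiguous chromosomal stretches encompassed by CNVs:
#' the union of calls from all samples and both SV types that share at least
#' one overlapping base. Book-ended calls (zero overlap) stay separate.
#'
#' @param calls Filtered call table from all samples.
#' @return Data frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `n_carriers` and list-columns `svtypes` and `carriers`.
#' @export
delineate_regions <- function(calls) {
  calls <- .check_calls(calls)
  if (nrow(calls) == 0) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_carriers = integer(), stringsAsFactors = FALSE))
  }
  gr <- .as_granges(calls)
  regions <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, regions)
  ri <- S4Vectors::subjectHits(hits); ci <- S4Vectors::queryHits(hits)
  df <- .as_intervals(regions)
  ord <- order(df$chrom, df$start)
  rank <- match(seq_len(nrow(df)), ord)
  df$region_id <- sprintf("cnvr_%05d", rank)
  df$svtypes <- unname(lapply(split(calls$svtype[ci], ri),
                              function(x) sort(unique(x))))
  df$carriers <- unname(lapply(split(calls$sample[ci], ri),
                               function(x) sort(unique(x))))
  df$n_carriers <- vapply(df$carriers, length, 0L)
  df <- df[ord, c("region_id", "chrom", "start", "end", "n_carriers",
                  "svtypes", "carriers")]
  rownames(df) <- NULL
  df
}

#' Match shared CNVs between two individuals
#'
#' Two calls of the same SV type are shared when their overlap exceeds
#' `reciprocal_share_frac` of BOTH lengths. Each call participates in at
#' most one pair; matching is greedy by decreasing overlap, ties broken by
#' leftmost position.
#'
#' @param calls_a,calls_b Call tables for two individuals.
#' @param thresholds A [cnv_thresholds()] list.
#' @return Data frame of matched pairs with indices into the two inputs and
#'   the overlap length.
#' @export
shared_between <- function(calls_a, calls_b, thresholds = cnv_thresholds()) {
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      overlap = integer())
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty)
  frac <- thresholds$reciprocal_share_frac
  hits <- GenomicRanges::findOverlaps(.as_granges(calls_a), .as_granges(calls_b))
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  ok <- calls_a$svtype[ai] == calls_b$svtype[bi]
  ai <- ai[ok]; bi <- bi[ok]
  if (length(ai) == 0) return(empty)
  ov <- .overlap_len(calls_a$start[ai], calls_a$end[ai],
                     calls_b$start[bi], calls_b$end[bi])
  la <- calls_a$end[ai] - calls_a$start[ai]
  lb <- calls_b$end[bi] - calls_b$start[bi]
  recip <- ov > frac * la & ov > frac * lb
  ai <- ai[recip]; bi <- bi[recip]; ov <- ov[recip]
  if (length(ai) == 0) return(empty)
  ord <- order(-ov, pmin(calls_a$start[ai], calls_b$start[bi]), ai, bi)
  used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
  keep <- logical(length(ord))
  for (k in ord) {
    if (!used_a[ai[k]] && !used_b[bi[k]]) {
      keep[k] <- TRUE
      used_a[ai[k]] <- TRUE
      used_b[bi[k]] <- TRUE
    }
  }
  data.frame(idx_a = ai[keep], idx_b = bi[keep], overlap = ov[keep])
}
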