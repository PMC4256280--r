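# Internal coordinate convention: 0-based half-open [start, end), as in BED.
# Conversion to the 1-based closed convention of GenomicRanges (and GFF3/VCF)
# happens only at these helpers and at the I/O boundary.

#' @importFrom GenomicRanges GRanges seqnames start end width reduce findOverlaps pintersect
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

# data.frame (chrom/start/end, 0-based half-open) -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# GRanges -> 0-based half-open data.frame
.as_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# pairwise overlap length between two interval rows (0-based half-open)
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

.check_intervals <- function(df, what = "interval") {
  bad <- df$end <= df$start
  if (any(bad)) {
    warning(sprintf("dropping %d %s record(s) with end <= start", sum(bad), what))
    df <- df[!bad, , drop = FALSE]
  }
  df
}

SV_TYPES <- c("DEL", "DUP")
CALLERS <- c("cnvnator", "breakdancer", "delly", "pindel", "other")
ECOTYPES <- c("lake", "river", "marine")

.check_calls <- function(calls) {
  req <- c("chrom", "start", "end", "svtype", "sample", "caller")
  miss <- setdiff(req, names(calls))
  if (length(miss) > 0) {
    stop("call table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(calls$svtype %in% SV_TYPES)) stop("svtype must be DEL or DUP")
  if (!all(calls$caller %in% CALLERS)) {
    stop("caller must be one of: ", paste(CALLERS, collapse = ", "))
  }
  if (any(calls$end <= calls$start)) stop("calls must satisfy end > start")
  calls
}

# round half away from zero (base round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

#' Default pipeline thresholds
#'
#' Bundle of the tuning constants used across the consensus, annotation and
#' statistics stages. Fractions are proportions of interval length; all
#' overlap comparisons are strict (`>`).
#'
#' @param within_caller_merge_frac Merge two same-caller calls when their
#'   overlap exceeds this fraction of the shorter call.
#' @param cross_caller_support_frac Keep a read-depth call when a call from
#'   another approach overlaps more than this fraction of its length.
#' @param reciprocal_share_frac Two individuals share a CNV when the overlap
#'   exceeds this fraction of both call lengths.
#' @param repeat_mask_frac Remove calls with more than this fraction of their
#'   length inside the repeat mask.
#' @param min_call_len Minimum call length in bp; shorter calls are removed.
#' @param gene_full_overlap_frac A gene is a CNV gene when CNV regions cover
#'   more than this fraction of its span (5\% breakpoint leeway).
#' @param loss_depth_max Normalized depth below which a gene copy is called
#'   lost in an individual.
#' @param loss_guard_min At least one individual must exceed this normalized
#'   depth for a loss call, guarding against regional mapping bias.
#' @param vst_top_quantile Quantile of |V_ST| used to flag extreme genes.
#' @param n_permutations Number of permutations for enrichment tests.
#' @param gamma_grid Inclusive range of the scaled selection coefficient
#'   searched by the PRF fit.
#' @param gamma_step Grid step for the PRF fit.
#' @return A named list of class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(within_caller_merge_frac = 0.5,
                           cross_caller_support_frac = 0.5,
                           reciprocal_share_frac = 0.5,
                           repeat_mask_frac = 0.5,
                           min_call_len = 500,
                           gene_full_overlap_frac = 0.95,
                           loss_depth_max = 0.25,
                           loss_guard_min = 2.0,
                           vst_top_quantile = 0.999,
                           n_permutations = 1000,
                           gamma_grid = c(-20, 10),
                           gamma_step = 0.1) {
  fr <- c(within_caller_merge_frac, cross_caller_support_frac,
          reciprocal_share_frac, repeat_mask_frac, gene_full_overlap_frac)
  if (any(fr <= 0 | fr > 1)) stop("fractions must lie in (0, 1]")
  if (min_call_len <= 0) stop("min_call_len must be > 0")
  if (gamma_grid[1] >= gamma_grid[2]) stop("gamma_grid must be increasing")
  structure(list(
    within_caller_merge_frac = within_caller_merge_frac,
    cross_caller_support_frac = cross_caller_support_frac,
    reciprocal_share_frac = reciprocal_share_frac,
    repeat_mask_frac = repeat_mask_frac,
    min_call_len = min_call_len,
    gene_full_overlap_frac = gene_full_overlap_frac,
    loss_depth_max = loss_depth_max,
    loss_guard_min = loss_guard_min,
    vst_top_quantile = vst_top_quantile,
    n_permutations = n_permutations,
    gamma_grid = gamma_grid,
    gamma_step = gamma_step
  ), class = "cnv_thresholds")
}

.header_comment <- function(params = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("cnvpop")), error = function(e) "dev")
  line <- sprintf("#cnvpop %s", v)
  if (!is.null(params) && length(params) > 0) {
    line <- paste0(line, " ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  }
  line
}
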