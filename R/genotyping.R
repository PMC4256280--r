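# Read-depth genotyping: normalize depth per locus, round to integer
# copy-number, classify bi-allelic loci, build allele-frequency spectra and
# call homozygous gene losses.

#' Normalize a depth matrix
#'
#' Read depth at each locus is divided by the per-locus median across all
#' individuals and multiplied by two, centering the typical individual at
#' the diploid value 2. Loci whose median depth is zero cannot be centered
#' and are excluded with a warning.
#'
#' @param depth loci x samples matrix of mean read depth (reads/bp).
#' @return Normalized matrix with per-locus median equal to 2; excluded loci
#'   are recorded in attribute `excluded`.
#' @export
normalize_depth <- function(depth) {
  if (ncol(depth) < 3) stop("need at least 3 samples to normalize")
  if (any(depth < 0)) stop("depth must be non-negative")
  med <- apply(depth, 1, stats::median)
  zero <- med == 0
  if (any(zero)) {
    warning(sprintf("excluding %d locus/loci with zero median depth", sum(zero)))
  }
  out <- 2 * depth[!zero, , drop = FALSE] / med[!zero]
  attr(out, "excluded") <- rownames(depth)[zero]
  out
}

#' Round normalized depth to integer copy-number
#'
#' Rounds half away from zero (2.5 becomes 3); values are floored at zero.
#'
#' @param normalized Normalized depth matrix from [normalize_depth()].
#' @return Integer copy-number matrix of the same shape.
#' @export
round_copy_number <- function(normalized) {
  cn <- .round_half_up(normalized)
  cn[cn < 0] <- 0
  storage.mode(cn) <- "integer"
  attr(cn, "excluded") <- NULL
  cn
}

#' Classify a copy-number vector as bi-allelic
#'
#' A locus is DEL-biallelic when its copy-numbers are a subset of \{0, 1, 2\}
#' with at least one below 2 (explainable by 0, 1 or 2 deletion alleles),
#' DUP-biallelic when a subset of \{2, 3, 4\} with at least one above 2,
#' monomorphic when all equal 2, and otherwise not bi-allelic (copy-numbers
#' above 4 or mixing deletion and duplication alleles violate the
#' one-copy-per-allele assumption).
#'
#' @param cn_row Integer copy-numbers for one locus.
#' @return One of `"DEL-biallelic"`, `"DUP-biallelic"`, `"monomorphic"`,
#'   `"not_biallelic"`.
#' @export
classify_biallelic <- function(cn_row) {
  v <- unique(cn_row)
  if (all(v == 2)) return("monomorphic")
  if (all(v %in% 0:2)) return("DEL-biallelic")
  if (all(v %in% 2:4)) return("DUP-biallelic")
  "not_biallelic"
}

#' Bi-allelic genotype table
#'
#' Container pairing a locus table (`locus_id`, `chrom`, `start`, `end`,
#' `allele_type`) with a loci x samples matrix of genotype codes. Codes are
#' 0 hom deletion, 1 het deletion, 2 wild type, 3 het duplication, 4 hom
#' duplication; for a bi-allelic locus the code equals the integer
#' copy-number. DEL loci use only codes \{0,1,2\}, DUP loci only \{2,3,4\}.
#'
#' @param loci Locus data frame.
#' @param codes Integer matrix, rows matching `loci`.
#' @return Object of class `cnv_genotypes`.
#' @export
biallelic_genotypes <- function(loci, codes) {
  if (nrow(loci) != nrow(codes)) stop("loci and codes disagree in length")
  if (!all(loci$allele_type %in% SV_TYPES)) stop("allele_type must be DEL or DUP")
  for (i in seq_len(nrow(loci))) {
    allowed <- if (loci$allele_type[i] == "DEL") 0:2 else 2:4
    if (!all(codes[i, ] %in% allowed)) {
      stop(sprintf("locus %s: codes outside %s range", loci$locus_id[i],
                   loci$allele_type[i]))
    }
  }
  rownames(codes) <- loci$locus_id
  structure(list(loci = loci, codes = codes), class = "cnv_genotypes")
}

#' Genotype bi-allelic loci from copy-number
#'
#' Classifies every locus of a copy-number matrix and returns the bi-allelic
#' subset as genotype codes, together with the per-locus classification.
#'
#' @param cn Copy-number matrix from [round_copy_number()].
#' @param loci Optional locus data frame (`locus_id`, `chrom`, `start`,
#'   `end`) matching the matrix rows; default uses rownames with dummy
#'   coordinates.
#' @return A `cnv_genotypes` object; attribute `classification` holds the
#'   class of every input locus.
#' @export
genotype_biallelic <- function(cn, loci = NULL) {
  classes <- apply(cn, 1, classify_biallelic)
  if (is.null(loci)) {
    loci <- data.frame(locus_id = rownames(cn), chrom = "unknown",
                       start = seq_len(nrow(cn)) - 1L,
                       end = seq_len(nrow(cn)), stringsAsFactors = FALSE)
  }
  keep <- classes %in% c("DEL-biallelic", "DUP-biallelic")
  loci <- loci[keep, , drop = FALSE]
  loci$allele_type <- ifelse(classes[keep] == "DEL-biallelic", "DEL", "DUP")
  gt <- biallelic_genotypes(loci, cn[keep, , drop = FALSE])
  attr(gt, "classification") <- classes
  gt
}

# non-reference allele count per locus: each het contributes 1, each
# non-reference homozygote 2 (code equals copy-number, so |code - 2| is the
# per-individual allele dose)
.allele_counts <- function(genotypes) {
  rowSums(abs(genotypes$codes - 2L))
}

#' Non-reference allele frequency of one bi-allelic locus
#'
#' With N diploid samples, frequency = (2 x hom-alt + het) / (2N).
#'
#' @param codes Genotype codes for one locus.
#' @return Frequency in `[0, 1]`.
#' @export
allele_frequency <- function(codes) {
  if (!all(codes %in% 0:4)) stop("codes must be in 0..4")
  sum(abs(codes - 2)) / (2 * length(codes))
}

#' Build the site-frequency spectrum of bi-allelic CNVs
#'
#' Counts loci by non-reference allele count i = 1 .. n-1 among n = 2N
#' sampled chromosomes. Monomorphic loci (count 0) and loci fixed for the
#' non-reference allele (count 2N) are excluded from the spectrum.
#'
#' @param genotypes A `cnv_genotypes` object.
#' @param allele_type Optionally restrict to `"DEL"` or `"DUP"` loci.
#' @return Object of class `cnv_sfs`: list with `n` (chromosomes) and `X`
#'   (counts for i = 1 .. n-1).
#' @export
build_afs <- function(genotypes, allele_type = NULL) {
  codes <- genotypes$codes
  loci <- genotypes$loci
  if (!is.null(allele_type)) {
    keep <- loci$allele_type == allele_type
    codes <- codes[keep, , drop = FALSE]
  }
  n <- 2L * ncol(codes)
  counts <- rowSums(abs(codes - 2L))
  seg <- counts > 0 & counts < n
  X <- tabulate(counts[seg], nbins = n - 1L)
  sfs(X, n)
}

#' Site-frequency spectrum object
#'
#' @param X Counts of loci with non-reference allele count i, i = 1 .. n-1.
#' @param n Number of sampled chromosomes (2 x individuals).
#' @return Object of class `cnv_sfs`.
#' @export
sfs <- function(X, n) {
  if (length(X) != n - 1) stop("X must have length n - 1")
  if (any(X < 0)) stop("spectrum counts must be non-negative")
  structure(list(n = as.integer(n), X = as.numeric(X)), class = "cnv_sfs")
}

#' Detect gene losses from normalized gene depth
#'
#' A gene is lost in an individual when that individual's normalized depth
#' falls below `loss_depth_max` (8-fold below diploid at the 0.25 default)
#' AND at least one individual exceeds `loss_guard_min`, guarding against
#' regional mapping biases that depress depth in everyone.
#'
#' @param gene_depth Normalized genes x samples depth matrix.
#' @param thresholds A [cnv_thresholds()] list.
#' @return Data frame of (`gene_id`, `sample`, `depth`) loss calls.
#' @export
detect_gene_loss <- function(gene_depth, thresholds = cnv_thresholds()) {
  guard <- apply(gene_depth, 1, max) > thresholds$loss_guard_min
  low <- gene_depth < thresholds$loss_depth_max & guard
  idx <- which(low, arr.ind = TRUE)
  data.frame(
    gene_id = rownames(gene_depth)[idx[, 1]],
    sample = colnames(gene_depth)[idx[, 2]],
    depth = gene_depth[low],
    stringsAsFactors = FALSE
  )
}

#' Genotype concordance between two call sets
#'
#' Compares genotype codes over the loci and samples common to both tables;
#' missing entries (NA) are skipped.
#'
#' @param codes_a,codes_b Genotype-code matrices with locus rownames and
#'   sample colnames.
#' @return List with `concordance`, `n_equal` and `n_compared`.
#' @export
genotype_concordance <- function(codes_a, codes_b) {
  loci <- intersect(rownames(codes_a), rownames(codes_b))
  samples <- intersect(colnames(codes_a), colnames(codes_b))
  a <- codes_a[loci, samples, drop = FALSE]
  b <- codes_b[loci, samples, drop = FALSE]
  comparable <- !is.na(a) & !is.na(b)
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable genotype entries")
  n_eq <- sum(a[comparable] == b[comparable])
  list(concordance = n_eq / n_comp, n_equal = n_eq, n_compared = n_comp)
}
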