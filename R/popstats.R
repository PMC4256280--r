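# Population statistics: signed V_ST differentiation, genome scans,
# geographic sharing classification, pairwise sharing proportions and
# within-population fixation summaries.

#' Signed V_ST copy-number differentiation
#'
#' V_ST compares copy-number variance between two populations:
#' magnitude = (V_T - (n1 V_1 + n2 V_2) / (n1 + n2)) / V_T, where V_T is the
#' variance of the pooled values and V_k the within-group variances
#' (population variance, divisor n, which makes the total/within
#' decomposition exact under size weighting). The sign is that of
#' mean(pop1) - mean(pop2); with the first population the river member of a
#' parapatric pair, positive values mean higher copy-number in the river.
#' When the pooled variance is zero the statistic is defined as 0.
#'
#' @param values_pop1,values_pop2 Numeric copy-number (or normalized depth)
#'   values, at least two per group.
#' @return Signed V_ST in `[-1, 1]`.
#' @export
vst <- function(values_pop1, values_pop2) {
  n1 <- length(values_pop1); n2 <- length(values_pop2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  pooled <- c(values_pop1, values_pop2)
  pvar <- function(x) mean((x - mean(x))^2)
  vt <- pvar(pooled)
  if (vt == 0) return(0)
  vs <- (n1 * pvar(values_pop1) + n2 * pvar(values_pop2)) / (n1 + n2)
  mag <- (vt - vs) / vt
  s <- sign(mean(values_pop1) - mean(values_pop2))
  if (s == 0) s <- 1
  mag * s
}

#' V_ST scan over a feature matrix
#'
#' Computes signed V_ST for every feature (gene or exon) of a normalized
#' depth matrix between two populations. The river population is listed
#' first and defines the sign. Features with fewer than two values in either
#' group are reported as missing (`NA`), not zero.
#'
#' @param gene_depth Normalized features x samples matrix.
#' @param manifest A `cnv_manifest`.
#' @param pair Character vector `c(pop_river, pop_lake)`.
#' @return Data frame with `feature_id`, `pair_id`, `vst`, `mean_pop1`,
#'   `mean_pop2`.
#' @export
vst_scan <- function(gene_depth, manifest, pair) {
  if (length(pair) != 2) stop("pair must name two populations")
  if (!all(pair %in% manifest$population)) {
    stop("unknown population label(s): ",
         paste(setdiff(pair, manifest$population), collapse = ", "))
  }
  s1 <- manifest$sample[manifest$population == pair[1]]
  s2 <- manifest$sample[manifest$population == pair[2]]
  s1 <- intersect(s1, colnames(gene_depth))
  s2 <- intersect(s2, colnames(gene_depth))
  m1 <- gene_depth[, s1, drop = FALSE]
  m2 <- gene_depth[, s2, drop = FALSE]
  v <- vapply(seq_len(nrow(gene_depth)), function(i) {
    x <- m1[i, ][!is.na(m1[i, ])]
    y <- m2[i, ][!is.na(m2[i, ])]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    vst(x, y)
  }, 0)
  pair_id <- sub("_[RLM]$", "", pair[1])
  data.frame(
    feature_id = rownames(gene_depth),
    pair_id = pair_id,
    vst = v,
    mean_pop1 = rowMeans(m1, na.rm = TRUE),
    mean_pop2 = rowMeans(m2, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Empirical quantile of |V_ST|
#'
#' Linear-interpolation quantile (R type 7) of the absolute values, used to
#' flag the most differentiated features of a scan.
#'
#' @param vst_values Signed V_ST values (NAs dropped).
#' @param q Quantile in (0, 1).
#' @return The threshold value.
#' @export
percentile_threshold <- function(vst_values, q) {
  v <- abs(vst_values[!is.na(vst_values)])
  if (length(v) == 0) stop("no V_ST values")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  unname(stats::quantile(v, q, type = 7))
}

SHARING_LEVELS <- c("Population", "Country", "Continent", "Ancestral")

#' Geographic sharing level of a carrier set
#'
#' Walks the manifest hierarchy: a variant found in one population is
#' `Population`-private; in several populations of one country, `Country`;
#' in several countries of one continent, `Continent`; across continents,
#' `Ancestral`.
#'
#' @param carriers Sample ids carrying the variant.
#' @param manifest A `cnv_manifest`.
#' @return One of `"Population"`, `"Country"`, `"Continent"`, `"Ancestral"`.
#' @export
sharing_level <- function(carriers, manifest) {
  if (length(carriers) == 0) stop("carriers must be nonempty")
  unknown <- setdiff(carriers, manifest$sample)
  if (length(unknown) > 0) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  }
  rows <- manifest[match(carriers, manifest$sample), ]
  if (length(unique(rows$continent)) > 1) return("Ancestral")
  if (length(unique(rows$country)) > 1) return("Continent")
  if (length(unique(rows$population)) > 1) return("Country")
  "Population"
}

#' Classify sharing for every CNV region
#'
#' @param regions Region table with a `carriers` list-column.
#' @param manifest A `cnv_manifest`.
#' @return Factor of sharing levels aligned with `regions`.
#' @export
classify_sharing <- function(regions, manifest) {
  lev <- vapply(regions$carriers, sharing_level, "", manifest = manifest)
  factor(lev, levels = SHARING_LEVELS)
}

#' Pairwise CNV sharing between individuals
#'
#' For each ordered pair of individuals the sharing proportion is the
#' Jaccard-style ratio |matched| / (|A| + |B| - |matched|) where matches are
#' reciprocal-overlap pairs from [shared_between()]. Group means are
#' reported over the four geographic relations: Within Populations, Between
#' Populations (same country), Between Countries (same continent), Between
#' Continents.
#'
#' @param calls Filtered call table for all samples.
#' @param manifest A `cnv_manifest`.
#' @param thresholds A [cnv_thresholds()] list.
#' @return List with `matrix` (sample x sample proportions) and
#'   `group_means` (named numeric vector).
#' @export
pairwise_sharing <- function(calls, manifest, thresholds = cnv_thresholds()) {
  samples <- manifest$sample
  per_sample <- lapply(samples, function(s) calls[calls$sample == s, , drop = FALSE])
  names(per_sample) <- samples
  n <- length(samples)
  prop <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  diag(prop) <- 1
  rel <- matrix(NA_character_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- per_sample[[i]]; b <- per_sample[[j]]
      na <- nrow(a); nb <- nrow(b)
      m <- if (na == 0 || nb == 0) 0 else nrow(shared_between(a, b, thresholds))
      denom <- na + nb - m
      prop[i, j] <- prop[j, i] <- if (denom == 0) NA_real_ else m / denom
      rel[i, j] <- .pair_relation(samples[i], samples[j], manifest)
    }
  }
  ut <- upper.tri(prop)
  groups <- c("Within Populations", "Between Populations",
              "Between Countries", "Between Continents")
  gm <- vapply(groups, function(g) {
    mean(prop[ut][rel[ut] == g], na.rm = TRUE)
  }, 0)
  list(matrix = prop, group_means = gm)
}

.pair_relation <- function(a, b, manifest) {
  ra <- manifest[manifest$sample == a, ]
  rb <- manifest[manifest$sample == b, ]
  if (ra$population == rb$population) return("Within Populations")
  if (ra$country == rb$country) return("Between Populations")
  if (ra$continent == rb$continent) return("Between Countries")
  "Between Continents"
}

#' Within-population fixation and presence summary
#'
#' For every bi-allelic locus and population: `fixed` when every member is
#' homozygous for the non-reference allele (codes 0 or 4); `present_in_all`
#' when every member carries at least one non-reference allele; `absent`
#' when no member carries one.
#'
#' @param genotypes A `cnv_genotypes` object.
#' @param manifest A `cnv_manifest`.
#' @return Data frame with one row per locus x population and logical
#'   columns `fixed`, `present_in_all`, `absent`.
#' @export
fixation_summary <- function(genotypes, manifest) {
  pops <- unique(manifest$population)
  codes <- genotypes$codes
  out <- lapply(pops, function(p) {
    s <- intersect(manifest$sample[manifest$population == p], colnames(codes))
    m <- codes[, s, drop = FALSE]
    nonref <- abs(m - 2L) > 0
    hom <- m == 0L | m == 4L
    data.frame(
      locus_id = genotypes$loci$locus_id,
      population = p,
      fixed = rowSums(hom) == length(s),
      present_in_all = rowSums(nonref) == length(s),
      absent = rowSums(nonref) == 0,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
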