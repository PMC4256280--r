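# End-to-end orchestration: consensus -> regions -> genotyping -> AFS ->
# annotation -> population statistics -> PRF -> enrichment, with file
# outputs carrying parameter provenance. The stages are pure functions of
# inputs + thresholds + seed, so identical configurations give identical
# outputs.

#' File-based pipeline configuration
#'
#' Validates that every referenced input exists before any work is done.
#'
#' @param calls Path to a caller_tsv call table (all callers, sample and
#'   caller columns).
#' @param depth Path to the loci x samples depth TSV.
#' @param manifest Path to the sample manifest TSV.
#' @param genes Path to a GFF3 gene annotation (optional).
#' @param mask Path to a repeat-mask BED (optional).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param stages Stages to run (subset of the default vector).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(calls, depth = NULL, manifest, genes = NULL,
                            mask = NULL, chrom_lengths,
                            stages = c("consensus", "genotype", "afs",
                                       "annotate", "popstats")) {
  need_depth <- any(c("genotype", "afs") %in% stages)
  if (need_depth && is.null(depth)) {
    stop("stage 'genotype' requested but no depth matrix configured")
  }
  if ("annotate" %in% stages && is.null(genes)) {
    stop("stage 'annotate' requested but no gene annotation configured")
  }
  for (p in c(calls, depth, manifest, genes, mask)) {
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", p)
  }
  structure(list(calls = calls, depth = depth, manifest = manifest,
                 genes = genes, mask = mask, chrom_lengths = chrom_lengths,
                 stages = stages), class = "pipeline_config")
}

#' Run the CNV population pipeline on a synthetic cohort
#'
#' Executes the full analysis in order: per-sample per-caller merging,
#' cross-caller support of the read-depth calls, filtering, region
#' delineation, depth normalization and bi-allelic genotyping, allele
#' frequency spectra, genomic-context and CNV-gene annotation, sharing
#' classification, V_ST scans over all parapatric pairs, gene-loss
#' detection, PRF selection fits for deletion and duplication spectra, and
#' permutation enrichment. When `out_dir` is given, every table is written
#' with a provenance header.
#'
#' @param cohort A `cnv_cohort` bundle from [simulate_cohort()], or inputs
#'   loaded from files with matching element names.
#' @param thresholds A [cnv_thresholds()] list.
#' @param out_dir Optional output directory.
#' @param seed Integer seed for the permutation stage.
#' @param n_perm_enrichment Permutations used in the enrichment stage
#'   (default taken from `thresholds`).
#' @return List of class `cnv_pipeline_result` with the stage outputs and a
#'   machine-readable `report`.
#' @export
run_pipeline <- function(cohort, thresholds = cnv_thresholds(),
                         out_dir = NULL, seed = 1,
                         n_perm_enrichment = thresholds$n_permutations) {
  manifest <- cohort$manifest
  layout <- cohort$layout
  n_samples <- nrow(manifest)

  # consensus: within-caller merging per sample/caller, then cross-caller
  # support of the read-depth caller, then filters
  calls <- cohort$calls
  parts <- split(calls, list(calls$sample, calls$caller), drop = TRUE)
  merged <- do.call(rbind, lapply(parts, merge_within_caller,
                                  thresholds = thresholds))
  rownames(merged) <- NULL
  primary <- merged[merged$caller == "cnvnator", , drop = FALSE]
  others <- merged[merged$caller != "cnvnator", , drop = FALSE]
  supported <- cross_caller_support(primary, others, thresholds)
  filtered <- apply_filters(supported, cohort$mask, layout, n_samples,
                            thresholds)
  regions <- delineate_regions(filtered)

  # genotyping on the locus depth matrix
  norm <- normalize_depth(cohort$depth)
  cnmat <- round_copy_number(norm)
  loci <- cohort$loci[match(rownames(cnmat), cohort$loci$locus_id), ]
  genotypes <- genotype_biallelic(cnmat, loci)
  afs_del <- build_afs(genotypes, "DEL")
  afs_dup <- build_afs(genotypes, "DUP")

  # annotation
  context <- classify_genomic_context(regions, cohort$annotation, thresholds)
  cgenes <- cnv_genes(regions, cohort$annotation, thresholds)
  cat_tab <- category_counts(cgenes, cohort$annotation)

  # population statistics
  sharing <- classify_sharing(regions, manifest)
  gene_norm <- normalize_depth(cohort$gene_depth)
  losses <- detect_gene_loss(gene_norm, thresholds)
  pairs_tab <- .parapatric_pairs(manifest)
  scans <- lapply(seq_len(nrow(pairs_tab)), function(i) {
    vst_scan(normalize_depth(cohort$depth), manifest,
             c(pairs_tab$river[i], pairs_tab$lake[i]))
  })
  vst_all <- do.call(rbind, scans)

  # selection
  fit_del <- if (sum(afs_del$X) > 0) fit_gamma(afs_del, thresholds$gamma_grid,
                                               thresholds$gamma_step) else NULL
  fit_dup <- if (sum(afs_dup$X) > 0) fit_gamma(afs_dup, thresholds$gamma_grid,
                                               thresholds$gamma_step) else NULL

  # enrichment
  thr_enr <- thresholds
  thr_enr$n_permutations <- n_perm_enrichment
  enr <- enrichment_test(regions, cohort$annotation, layout, thr_enr,
                         seed = seed)

  report <- list(
    n_samples = n_samples,
    n_calls_raw = nrow(calls),
    n_calls_filtered = nrow(filtered),
    n_regions = nrow(regions),
    n_biallelic = nrow(genotypes$loci),
    sharing_proportions = as.list(prop.table(table(sharing))),
    n_gene_losses = nrow(losses),
    gamma_del = if (!is.null(fit_del)) fit_del$gamma_hat else NA,
    gamma_dup = if (!is.null(fit_dup)) fit_dup$gamma_hat else NA,
    seed = seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(filtered, file.path(out_dir, "calls_filtered.tsv"),
                params = list(seed = seed))
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    write_matrix_tsv(cnmat, file.path(out_dir, "copy_number.tsv"))
    write_genotypes_vcf(genotypes, manifest,
                        file.path(out_dir, "genotypes.vcf"))
    utils::write.table(vst_all, file.path(out_dir, "vst_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(
    filtered_calls = filtered,
    regions = regions,
    normalized_depth = norm,
    copy_number = cnmat,
    genotypes = genotypes,
    afs = list(DEL = afs_del, DUP = afs_dup),
    context = context,
    cnv_genes = cgenes,
    category_counts = cat_tab,
    sharing = sharing,
    gene_losses = losses,
    vst = vst_all,
    prf = list(DEL = fit_del, DUP = fit_dup),
    enrichment = enr,
    report = report
  ), class = "cnv_pipeline_result")
}

# river/lake pairs sharing a pair prefix (G1_R + G1_L -> pair G1)
.parapatric_pairs <- function(manifest) {
  df <- unique(as.data.frame(manifest)[, c("population", "ecotype")])
  prefix <- sub("_[RLM]$", "", df$population)
  out <- do.call(rbind, lapply(unique(prefix), function(px) {
    r <- df$population[prefix == px & df$ecotype == "river"]
    l <- df$population[prefix == px & df$ecotype == "lake"]
    if (length(r) == 1 && length(l) == 1) {
      data.frame(pair = px, river = r, lake = l, stringsAsFactors = FALSE)
    }
  }))
  out
}
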