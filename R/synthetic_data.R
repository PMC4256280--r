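# Synthetic cohorts with the statistical structure the pipeline assumes:
# a hierarchical sampling design (continents > countries > populations),
# CNV loci with a skewed low-frequency allele law, diploid read-depth signal
# proportional to copy-number, multi-caller call emission with breakpoint
# jitter and false calls, and a gene complement with orthology categories
# preferentially associated with CNVs. All truth is recorded.

# default 11-population design: five parapatric lake-river pairs plus one
# marine population, six individuals each (66 genomes)
.default_population_table <- function() {
  data.frame(
    population = c("Dk_M", "G1_R", "G1_L", "G2_R", "G2_L",
                   "No_R", "No_L", "Us_R", "Us_L", "Ca_R", "Ca_L"),
    country = c("Dk", "Germany", "Germany", "Germany", "Germany",
                "No", "No", "Us", "Us", "Ca", "Ca"),
    continent = c("Atlantic", "Atlantic", "Atlantic", "Atlantic", "Atlantic",
                  "Atlantic", "Atlantic", "Pacific", "Pacific", "Pacific",
                  "Pacific"),
    ecotype = c("marine", "river", "lake", "river", "lake",
                "river", "lake", "river", "lake", "river", "lake"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the downstream products of a 66-genome stickleback
#' resequencing design: 11 populations (five lake-river pairs and one marine
#' population) of 6 individuals at 26x mean coverage, CNV loci dominated by
#' deletions with 70\% of loci below 0.05 overall allele frequency, a small
#' set of strongly divergent loci between one parapatric pair, four caller
#' profiles with breakpoint jitter and false calls, and a gene set whose
#' young-gene categories (lineage-specific genes and duplications) are
#' preferentially CNV-associated.
#'
#' @param populations Data frame with columns population/country/continent/
#'   ecotype (one row per population).
#' @param samples_per_population Individuals per population.
#' @param n_cnv_loci Number of CNV loci.
#' @param prop_del Proportion of loci that are deletions.
#' @param prop_low_freq Proportion of loci drawn from the low-frequency law.
#' @param low_freq_range,high_freq_range Overall allele-frequency ranges of
#'   the two mixture components.
#' @param max_pop_freq Upper bound on non-divergent population allele
#'   frequencies, keeping loci in the regime where the median individual is
#'   diploid (the assumption of median-based depth normalization).
#' @param kappa Concentration of the hierarchical beta model propagating
#'   overall frequency to country and population frequencies.
#' @param n_divergent Number of divergent loci between `divergent_pair`.
#' @param divergent_pair Two population labels.
#' @param divergent_freqs Allele frequencies at divergent loci (first
#'   population, second population).
#' @param depth_mu Mean diploid coverage.
#' @param depth_sigma Depth noise standard deviation at diploid copy-number
#'   (noise scales with sqrt(cn/2), the mean-variance relation of count
#'   data).
#' @param caller_profiles Named list of per-caller profiles: `sensitivity`,
#'   `jitter` (bp), `fp_per_sample` (expected false calls).
#' @param n_genes Number of genes.
#' @param gene_meanlog,gene_sdlog Log-normal gene length law.
#' @param category_props Named proportions of the five orthology categories.
#' @param base_cnv_rate Baseline probability that a gene is placed inside a
#'   CNV locus.
#' @param cnv_assoc_multiplier Multiplier of that probability for
#'   lineage-specific genes and duplications.
#' @param n_loss_genes Genes engineered as homozygous losses.
#' @param loss_epsilon Residual depth fraction of diploid at lost copies.
#' @param chrom_lengths Autosome lengths (a sex chromosome `groupXIX` is
#'   appended automatically).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(populations = .default_population_table(),
                          samples_per_population = 6,
                          n_cnv_loci = 400,
                          prop_del = 0.82,
                          prop_low_freq = 0.70,
                          low_freq_range = c(0.008, 0.05),
                          high_freq_range = c(0.05, 0.20),
                          max_pop_freq = 0.2,
                          kappa = 12,
                          n_divergent = 5,
                          divergent_pair = c("G1_R", "G1_L"),
                          divergent_freqs = c(0.9, 0.1),
                          depth_mu = 26,
                          depth_sigma = 0.8,
                          caller_profiles = list(
                            cnvnator = list(sensitivity = 0.95, jitter = 50, fp_per_sample = 3),
                            breakdancer = list(sensitivity = 0.80, jitter = 100, fp_per_sample = 5),
                            delly = list(sensitivity = 0.80, jitter = 100, fp_per_sample = 5),
                            pindel = list(sensitivity = 0.70, jitter = 50, fp_per_sample = 5)
                          ),
                          n_genes = 300,
                          gene_meanlog = log(3000),
                          gene_sdlog = 0.5,
                          category_props = c("non-LSG singleton" = 0.52,
                                             "non-LSG paralog" = 0.28,
                                             "non-LSG LSD" = 0.10,
                                             "LSG LSD" = 0.04,
                                             "LSG singleton" = 0.06),
                          base_cnv_rate = 0.08,
                          cnv_assoc_multiplier = 3,
                          n_loss_genes = 5,
                          loss_epsilon = 0.02,
                          chrom_lengths = c(groupI = 1e7, groupII = 1e7,
                                            groupIII = 1e7, groupIV = 1e7)) {
  if (n_divergent > n_cnv_loci) stop("divergent loci exceed total loci")
  if (!all(divergent_pair %in% populations$population)) {
    stop("divergent_pair populations not in design")
  }
  probs <- c(prop_del, prop_low_freq, unlist(lapply(caller_profiles, `[[`, "sensitivity")))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(category_props) - 1) > 1e-8) stop("category_props must sum to 1")
  structure(as.list(environment()), class = "cohort_config")
}

# hierarchical beta draw: mean m, concentration kappa; degenerate at 0/1
.beta_around <- function(n, m, kappa) {
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  stats::rbeta(n, m * kappa, (1 - m) * kappa)
}

#' Simulate depth from copy-number
#'
#' Depth is Normal with mean `mu * cn / 2`; the standard deviation scales as
#' `sigma * sqrt(cn / 2)` (zero copies use a residual fraction `epsilon` of
#' diploid signal, mimicking mismapping), and draws are truncated at zero.
#'
#' @param cn Integer copy-number matrix (loci x samples).
#' @param mu Mean diploid coverage.
#' @param sigma Depth sd at diploid copy-number.
#' @param epsilon Residual depth fraction at copy-number zero.
#' @return Depth matrix of the same shape.
#' @export
simulate_depth <- function(cn, mu, sigma, epsilon = 0.02) {
  dose <- pmax(cn / 2, epsilon)
  d <- stats::rnorm(length(cn), mean = mu * dose, sd = sigma * sqrt(dose))
  d[d < 0] <- 0
  matrix(d, nrow = nrow(cn), dimnames = dimnames(cn))
}

#' Emit caller calls from true CNV intervals
#'
#' Each true interval is kept with probability `sensitivity`, its endpoints
#' shifted independently by uniform +/- `jitter` bp (clamped to the
#' chromosome), and false calls are appended at a Poisson rate of
#' `fp_per_sample` per individual, placed uniformly with lengths resampled
#' from the true call lengths.
#'
#' @param true_calls Call table (chrom/start/end/svtype/sample).
#' @param caller Caller label for the emitted calls.
#' @param profile List with `sensitivity`, `jitter`, `fp_per_sample`.
#' @param layout A [genome_layout()].
#' @param seed Optional integer seed.
#' @return Emitted call table.
#' @export
emit_caller_calls <- function(true_calls, caller, profile, layout,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(profile$sensitivity >= 0, profile$sensitivity <= 1,
            profile$jitter >= 0)
  kept <- true_calls[stats::runif(nrow(true_calls)) < profile$sensitivity, ,
                     drop = FALSE]
  if (nrow(kept) > 0 && profile$jitter > 0) {
    j <- profile$jitter
    kept$start <- kept$start + round(stats::runif(nrow(kept), -j, j))
    kept$end <- kept$end + round(stats::runif(nrow(kept), -j, j))
    L <- layout$lengths[kept$chrom]
    kept$start <- pmax(0, kept$start)
    kept$end <- pmin(L, kept$end)
    kept <- kept[kept$end > kept$start, , drop = FALSE]
  }
  samples <- unique(true_calls$sample)
  fp <- NULL
  if (profile$fp_per_sample > 0 && length(samples) > 0) {
    n_fp <- stats::rpois(length(samples), profile$fp_per_sample)
    if (sum(n_fp) > 0) {
      lens <- if (nrow(true_calls) > 0) {
        sample(true_calls$end - true_calls$start, sum(n_fp), replace = TRUE)
      } else {
        round(stats::runif(sum(n_fp), 500, 10000))
      }
      autos <- setdiff(names(layout$lengths), layout$sex_chromosomes)
      chrom <- sample(autos, sum(n_fp), replace = TRUE)
      start <- floor(stats::runif(sum(n_fp), 0,
                                  layout$lengths[chrom] - lens))
      fp <- data.frame(
        chrom = chrom,
        start = as.integer(start),
        end = as.integer(start + lens),
        svtype = sample(SV_TYPES, sum(n_fp), replace = TRUE),
        sample = rep(samples, n_fp),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind(kept[, c("chrom", "start", "end", "svtype", "sample")], fp)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), svtype = character(),
                      sample = character(), stringsAsFactors = FALSE)
  }
  out$caller <- caller
  rownames(out) <- NULL
  out
}

#' Simulate gene-level depth with engineered losses
#'
#' Genes inside CNV loci inherit the locus copy-number; other genes are
#' diploid. Engineered loss entries are set to copy-number zero (residual
#' depth `loss_epsilon` of diploid); by construction at least one
#' individual per loss gene remains at diploid depth.
#'
#' @param gene_cn Genes x samples copy-number matrix.
#' @param losses Data frame (`gene_id`, `sample`) of engineered losses.
#' @param mu,sigma Depth model as in [simulate_depth()].
#' @param loss_epsilon Residual depth fraction at lost copies.
#' @param seed Optional integer seed.
#' @return Genes x samples raw depth matrix.
#' @export
simulate_gene_depth <- function(gene_cn, losses = NULL, mu = 26, sigma = 2.6,
                                loss_epsilon = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(losses) && nrow(losses) > 0) {
    for (i in seq_len(nrow(losses))) {
      gene_cn[losses$gene_id[i], losses$sample[i]] <- 0L
    }
  }
  simulate_depth(gene_cn, mu, sigma, epsilon = loss_epsilon)
}

#' Draw carrier sets with prescribed sharing levels
#'
#' Constructs carrier sets whose geographic sharing classification is known
#' by construction: `Population` picks carriers from one population,
#' `Country` from two populations of one country, `Continent` from two
#' countries of one continent, `Ancestral` from two continents.
#'
#' @param manifest A `cnv_manifest`.
#' @param levels Character vector of requested levels.
#' @param seed Optional integer seed.
#' @return List of carrier-set character vectors, named by requested level.
#' @export
simulate_carrier_sets <- function(manifest, levels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(manifest)
  pick <- function(pops) {
    unlist(lapply(pops, function(p) {
      s <- df$sample[df$population == p]
      sample(s, min(2, length(s)))
    }))
  }
  out <- lapply(levels, function(lev) {
    if (lev == "Population") {
      pick(sample(unique(df$population), 1))
    } else if (lev == "Country") {
      multi <- names(which(table(unique(df[, c("population", "country")])$country) > 1))
      ctry <- sample(multi, 1)
      pops <- unique(df$population[df$country == ctry])
      pick(sample(pops, 2))
    } else if (lev == "Continent") {
      cc <- unique(df[, c("country", "continent")])
      multi <- names(which(table(cc$continent) > 1))
      cont <- sample(multi, 1)
      ctrys <- sample(unique(df$country[df$continent == cont]), 2)
      pick(vapply(ctrys, function(ct) sample(unique(df$population[df$country == ct]), 1), ""))
    } else if (lev == "Ancestral") {
      conts <- sample(unique(df$continent), 2)
      pick(vapply(conts, function(cn) sample(unique(df$population[df$continent == cn]), 1), ""))
    } else {
      stop("unknown sharing level: ", lev)
    }
  })
  names(out) <- levels
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws population allele frequencies from a hierarchical beta model
#' (overall frequency propagated through country to population, so the
#' geographic sharing hierarchy is non-degenerate), genotypes each
#' individual under Hardy-Weinberg at its population frequency, simulates
#' read depth proportional to copy-number, emits per-caller call tables with
#' jitter and false calls, places a gene complement with category-dependent
#' CNV association, and records all truth.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the bundle is a pure function of config + seed.
#' @return List of class `cnv_cohort` with elements `manifest`, `layout`,
#'   `loci`, `cn_true`, `depth`, `calls`, `annotation`, `gene_cn_true`,
#'   `gene_depth`, `losses`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)

  pops <- config$populations
  manifest <- cnv_manifest(do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    data.frame(
      sample = sprintf("%s_%02d", pops$population[i],
                       seq_len(config$samples_per_population)),
      population = pops$population[i],
      country = pops$country[i],
      continent = pops$continent[i],
      ecotype = pops$ecotype[i],
      stringsAsFactors = FALSE
    )
  })))
  n_samples <- nrow(manifest)

  lengths <- c(config$chrom_lengths, groupXIX = 5e6)
  layout <- genome_layout(lengths, sex_chromosomes = "groupXIX")
  autos <- setdiff(names(lengths), layout$sex_chromosomes)

  # non-overlapping CNV loci on a 25 kb slot grid (even slots; odd slots are
  # reserved for intergenic gene placement)
  slot <- 25000
  slots_per_chrom <- floor(config$chrom_lengths / slot)
  slot_tab <- data.frame(
    chrom = rep(autos, slots_per_chrom),
    idx = unlist(lapply(slots_per_chrom, seq_len)) - 1L,
    stringsAsFactors = FALSE
  )
  even <- slot_tab[slot_tab$idx %% 2 == 0, ]
  if (nrow(even) < config$n_cnv_loci) stop("genome too small for n_cnv_loci")
  pick <- even[sample(nrow(even), config$n_cnv_loci), ]
  len <- pmin(pmax(round(stats::rlnorm(config$n_cnv_loci,
                                       meanlog = log(6000), sdlog = 0.7)),
                   600), slot - 2000)
  start <- pick$idx * slot + floor(stats::runif(config$n_cnv_loci, 500, 1500))
  loci <- data.frame(
    locus_id = sprintf("locus_%04d", seq_len(config$n_cnv_loci)),
    chrom = pick$chrom,
    start = as.integer(start),
    end = as.integer(start + len),
    svtype = sample(SV_TYPES, config$n_cnv_loci, replace = TRUE,
                    prob = c(config$prop_del, 1 - config$prop_del)),
    stringsAsFactors = FALSE
  )

  # overall -> country -> population allele frequencies
  n_loci <- config$n_cnv_loci
  low <- stats::runif(n_loci, config$low_freq_range[1], config$low_freq_range[2])
  high <- stats::runif(n_loci, config$high_freq_range[1], config$high_freq_range[2])
  p0 <- ifelse(stats::runif(n_loci) < config$prop_low_freq, low, high)
  pop_freq <- matrix(0, nrow(pops), n_loci,
                     dimnames = list(pops$population, loci$locus_id))
  for (cont in unique(pops$continent)) {
    fcont <- .beta_around(n_loci, p0, config$kappa)
    for (ct in unique(pops$country[pops$continent == cont])) {
      fc <- .beta_around(n_loci, fcont, config$kappa)
      for (p in pops$population[pops$country == ct]) {
        pop_freq[p, ] <- .beta_around(n_loci, fc, config$kappa)
      }
    }
  }
  # read-depth genotyping assumes the median individual is diploid at every
  # locus; bound non-divergent population frequencies to stay within that
  # regime (empirically, bi-allelic CNVs in such cohorts sit well below 0.3)
  pop_freq <- pmin(pop_freq, config$max_pop_freq)
  divergent <- integer(0)
  if (config$n_divergent > 0) {
    divergent <- sample(n_loci, config$n_divergent)
    pop_freq[config$divergent_pair[1], divergent] <- config$divergent_freqs[1]
    pop_freq[config$divergent_pair[2], divergent] <- config$divergent_freqs[2]
    other <- setdiff(rownames(pop_freq), config$divergent_pair)
    pop_freq[other, divergent] <- 0.02
  }

  # Hardy-Weinberg genotypes: copy-number = 2 -/+ allele dose
  cn <- matrix(2L, n_loci, n_samples,
               dimnames = list(loci$locus_id, manifest$sample))
  for (s in seq_len(n_samples)) {
    p <- pop_freq[manifest$population[s], ]
    dose <- stats::rbinom(n_loci, 2, p)
    cn[, s] <- ifelse(loci$svtype == "DEL", 2L - dose, 2L + dose)
  }

  depth <- simulate_depth(cn, config$depth_mu, config$depth_sigma)

  # true per-sample intervals where copy-number deviates from diploid
  carrier_idx <- which(cn != 2L, arr.ind = TRUE)
  true_calls <- data.frame(
    chrom = loci$chrom[carrier_idx[, 1]],
    start = loci$start[carrier_idx[, 1]],
    end = loci$end[carrier_idx[, 1]],
    svtype = loci$svtype[carrier_idx[, 1]],
    sample = manifest$sample[carrier_idx[, 2]],
    stringsAsFactors = FALSE
  )
  calls <- do.call(rbind, lapply(names(config$caller_profiles), function(cl) {
    emit_caller_calls(true_calls, cl, config$caller_profiles[[cl]], layout)
  }))
  rownames(calls) <- NULL

  # gene complement: categories, CNV association, placement
  cats <- names(config$category_props)
  category <- sample(cats, config$n_genes, replace = TRUE,
                     prob = config$category_props)
  young <- category %in% c("non-LSG LSD", "LSG LSD", "LSG singleton")
  p_cnv <- pmin(config$base_cnv_rate *
                  ifelse(young, config$cnv_assoc_multiplier, 1), 1)
  in_cnv <- stats::runif(config$n_genes) < p_cnv
  glen <- pmin(pmax(round(stats::rlnorm(config$n_genes, config$gene_meanlog,
                                        config$gene_sdlog)), 300), 15000)
  odd <- slot_tab[slot_tab$idx %% 2 == 1, ]
  free <- odd[sample(nrow(odd), config$n_genes), ]
  gchrom <- free$chrom
  gstart <- free$idx * slot + 1000L
  host_locus <- rep(NA_character_, config$n_genes)
  cnv_idx <- which(in_cnv)
  if (length(cnv_idx) > 0) {
    hosts <- sample(n_loci, length(cnv_idx), replace = TRUE)
    for (k in seq_along(cnv_idx)) {
      g <- cnv_idx[k]; l <- hosts[k]
      span <- loci$end[l] - loci$start[l]
      glen[g] <- min(glen[g], max(300, floor(0.8 * span)))
      gchrom[g] <- loci$chrom[l]
      gstart[g] <- loci$start[l] +
        floor(stats::runif(1, 0, span - glen[g] + 1))
      host_locus[g] <- loci$locus_id[l]
    }
  }
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    chrom = gchrom,
    start = as.integer(gstart),
    end = as.integer(gstart + glen),
    biotype = "protein_coding",
    category = category,
    stringsAsFactors = FALSE
  )
  # two exons per gene: first and last third of the span
  third <- pmax(1L, (genes$end - genes$start) %/% 3L)
  exons <- rbind(
    data.frame(gene_id = genes$gene_id, start = genes$start,
               end = genes$start + third, stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, start = genes$end - third,
               end = genes$end, stringsAsFactors = FALSE)
  )
  annotation <- gene_annotation(genes, exons)

  gene_cn <- matrix(2L, config$n_genes, n_samples,
                    dimnames = list(genes$gene_id, manifest$sample))
  hosted <- !is.na(host_locus)
  gene_cn[hosted, ] <- cn[host_locus[hosted], , drop = FALSE]

  # engineered losses among diploid genes: 1-2 individuals each
  losses <- NULL
  if (config$n_loss_genes > 0) {
    eligible <- genes$gene_id[!hosted]
    loss_genes <- sample(eligible, min(config$n_loss_genes, length(eligible)))
    losses <- do.call(rbind, lapply(loss_genes, function(g) {
      data.frame(gene_id = g,
                 sample = sample(manifest$sample, sample(1:2, 1)),
                 stringsAsFactors = FALSE)
    }))
  }
  gene_depth <- simulate_gene_depth(gene_cn, losses, config$depth_mu,
                                    config$depth_sigma,
                                    loss_epsilon = config$loss_epsilon)

  # complete loss truth: every zero-copy (gene, sample) entry, engineered or
  # arising from homozygous deletion of a CNV-hosted gene
  gene_cn_final <- gene_cn
  if (!is.null(losses)) {
    for (i in seq_len(nrow(losses))) {
      gene_cn_final[losses$gene_id[i], losses$sample[i]] <- 0L
    }
  }
  zero_idx <- which(gene_cn_final == 0L, arr.ind = TRUE)
  gene_losses_truth <- data.frame(
    gene_id = rownames(gene_cn_final)[zero_idx[, 1]],
    sample = colnames(gene_cn_final)[zero_idx[, 2]],
    stringsAsFactors = FALSE
  )

  structure(list(
    manifest = manifest,
    layout = layout,
    loci = loci,
    cn_true = cn,
    depth = depth,
    calls = calls,
    annotation = annotation,
    gene_cn_true = gene_cn_final,
    gene_depth = gene_depth,
    losses = losses,
    truth = list(
      pop_freq = pop_freq,
      overall_freq = p0,
      divergent_loci = loci$locus_id[divergent],
      host_locus = host_locus,
      gene_losses = gene_losses_truth,
      seed = seed
    )
  ), class = "cnv_cohort")
}
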