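# Deterministic synthetic data with known ground truth: mosaic-of-founders
# haplotypes with implanted hard sweeps, genotype panels with planted QC
# violations, toy gene annotations and stage-structured expression.
#
# The generator is a stand-in for a coalescent simulator: founder pools per
# population (Balding-Nichols drifted allele frequencies) recombined as
# geometric-length mosaics give distance-decaying LD and tunable FST -- the
# two properties the tests need -- without claiming population-genetic
# realism. Hard sweeps are implanted mechanically by overwriting a fraction
# of one population's haplotypes with a single donor haplotype over a
# window, which produces the long-shared-haplotype signature the EHH-family
# statistics detect.

#' Simulation configuration
#'
#' Defaults encode the stated test world: 2 populations x 50 diploid
#' samples, 5,000 SNPs on a 10-Mb chromosome (2-kb marker spacing, chip
#' density scaled down), mosaic segments of 20 kb giving short-range LD,
#' between-population differentiation targeting FST 0.10, and a 4-stage x
#' 3-replicate expression design with 4-fold effects and 10% multiplicative
#' noise.
#'
#' @param seed integer RNG seed; fixed seed means byte-identical outputs.
#' @param n_pops,n_samples_per_pop population count and diploid samples per
#'   population.
#' @param n_snps,chrom_length_bp marker count and chromosome length.
#' @param mosaic_segment_len_bp mean founder-mosaic segment length
#'   (controls background LD range).
#' @param n_founders founder haplotypes per population pool.
#' @param drift_fst_target desired mean Weir-Cockerham FST between
#'   populations at neutral SNPs.
#' @param sweep_specs list of `list(pop=, pos_bp=, carrier_fraction=,
#'   width_bp=)` hard sweeps (carrier_fraction in (0,1]).
#' @param qc planted-violation counts for the QC panel:
#'   `list(n_snps, n_callrate, n_maf, n_hwe)`.
#' @param expression list: `n_genes`, `stages`, `reps_per_stage`,
#'   `n_de_per_stage`, `effect_fold`, `noise_cv`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_pops = 2, n_samples_per_pop = 50,
                       n_snps = 5000, chrom_length_bp = 1e7,
                       mosaic_segment_len_bp = 2e4, n_founders = 50,
                       drift_fst_target = 0.10, sweep_specs = list(),
                       qc = list(n_snps = 200, n_callrate = 10, n_maf = 10,
                                 n_hwe = 5),
                       expression = list(n_genes = 1000,
                                         stages = c("FP", "LP", "P30", "P45"),
                                         reps_per_stage = 3,
                                         n_de_per_stage = 20,
                                         effect_fold = 4, noise_cv = 0.1)) {
  for (sw in sweep_specs) {
    stopifnot(sw$carrier_fraction > 0, sw$carrier_fraction <= 1)
    if (sw$pos_bp < 1 || sw$pos_bp > chrom_length_bp)
      stop("sweep position outside the chromosome")
  }
  structure(list(seed = as.integer(seed), n_pops = n_pops,
                 n_samples_per_pop = n_samples_per_pop, n_snps = n_snps,
                 chrom_length_bp = chrom_length_bp,
                 mosaic_segment_len_bp = mosaic_segment_len_bp,
                 n_founders = n_founders,
                 drift_fst_target = drift_fst_target,
                 sweep_specs = sweep_specs, qc = qc,
                 expression = expression), class = "sim_config")
}

mosaic_hap <- function(founders, pos, seg_len) {
  n_snp <- length(pos)
  p_switch <- 1 - exp(-diff(pos) / seg_len)
  seg <- cumsum(c(0L, as.integer(stats::runif(n_snp - 1) < p_switch)))
  fids <- sample.int(nrow(founders), max(seg) + 1L, replace = TRUE)
  founders[cbind(fids[seg + 1L], seq_len(n_snp))]
}

#' Simulate phased multi-population haplotypes with implanted sweeps
#'
#' Founder allele frequencies are drawn from a U-shaped Beta(0.2, 0.2)
#' clipped to `[0.05, 0.95]`; per-population frequencies drift around them
#' via a Balding-Nichols Beta draw whose variance parameter is
#' `drift_fst_target - 1/n_founders` (the founder-pool sampling itself
#' contributes roughly `1/n_founders` of differentiation). Haplotypes are
#' recombinant mosaics of the population's founder pool with geometric
#' segment lengths. Each sweep overwrites `carrier_fraction` of the focal
#' population's haplotypes with one donor haplotype over the window
#' centered at the sweep position.
#'
#' @param config a [sim_config()].
#' @return list: `haplotypes` (merged [haplotype_matrix()], alleles already
#'   polarized as 0 = ancestral), `truth` (sweep table with the nearest SNP
#'   index per sweep).
#' @export
simulate_haplotypes <- function(config) {
  set.seed(config$seed)
  n_snp <- config$n_snps
  pos <- sort(sample.int(config$chrom_length_bp, n_snp))
  p_anc <- pmin(0.95, pmax(0.05, stats::rbeta(n_snp, 0.2, 0.2)))
  f_bn <- max(config$drift_fst_target - 1 / config$n_founders, 1e-4)
  n_hap_pop <- 2 * config$n_samples_per_pop

  pops <- paste0("POP", seq_len(config$n_pops))
  hap_blocks <- list()
  for (k in seq_len(config$n_pops)) {
    p_pop <- stats::rbeta(n_snp, p_anc * (1 - f_bn) / f_bn,
                          (1 - p_anc) * (1 - f_bn) / f_bn)
    founders <- matrix(
      as.integer(stats::runif(config$n_founders * n_snp) <
                   rep(p_pop, each = config$n_founders)),
      nrow = config$n_founders)
    block <- matrix(0L, n_hap_pop, n_snp)
    for (i in seq_len(n_hap_pop))
      block[i, ] <- mosaic_hap(founders, pos, config$mosaic_segment_len_bp)
    hap_blocks[[k]] <- block
  }

  sweeps <- NULL
  for (sw in config$sweep_specs) {
    k <- if (is.character(sw$pop)) match(sw$pop, pops) else sw$pop
    width <- if (is.null(sw$width_bp)) 2e5 else sw$width_bp
    win <- which(abs(pos - sw$pos_bp) <= width / 2)
    if (!length(win)) stop("sweep window contains no SNPs")
    donor <- hap_blocks[[k]][sample.int(n_hap_pop, 1), win]
    n_carr <- max(1L, round(sw$carrier_fraction * n_hap_pop))
    carriers <- sample.int(n_hap_pop, n_carr)
    hap_blocks[[k]][carriers, win] <-
      matrix(donor, n_carr, length(win), byrow = TRUE)
    sweeps <- rbind(sweeps, data.frame(
      pop = pops[k], pos_bp = sw$pos_bp,
      snp_index = which.min(abs(pos - sw$pos_bp)),
      carrier_fraction = sw$carrier_fraction, width_bp = width))
  }

  haps <- do.call(rbind, hap_blocks)
  samples <- paste0(rep(pops, each = config$n_samples_per_pop), "_S",
                    rep(seq_len(config$n_samples_per_pop), config$n_pops))
  snps <- data.frame(chrom = "chr1", pos = pos,
                     id = sprintf("snp%05d", seq_len(n_snp)),
                     ref = "A", alt = "G", anc = "ref",
                     stringsAsFactors = FALSE)
  h <- haplotype_matrix(snps, haps,
                        sample_of_haplotype = rep(samples, each = 2),
                        pops = rep(rep(pops, each = config$n_samples_per_pop),
                                   each = 2),
                        anc_policy = "alt_is_derived")
  list(haplotypes = h, truth = list(sweeps = sweeps, seed = config$seed))
}

#' Collapse a haplotype matrix to a phased genotype matrix
#' @param h [haplotype_matrix()] with haplotype pairs in sample order.
#' @return [genotype_matrix()] carrying full phase information.
#' @export
haps_to_genotypes <- function(h) {
  n_hap <- nrow(h$haps)
  stopifnot(n_hap %% 2 == 0)
  odd <- seq(1, n_hap, by = 2)
  a1 <- h$haps[odd, , drop = FALSE]
  a2 <- h$haps[odd + 1, , drop = FALSE]
  samples <- h$sample_of_haplotype[odd]
  genotype_matrix(h$snps, samples, h$pops[odd], a1 + a2, a1 = a1, a2 = a2,
                  phased = matrix(TRUE, length(odd), ncol(h$haps)))
}

# deterministic near-HWE genotype column: rounded expected counts, shuffled
hwe_column <- function(n, p) {
  n2 <- round(n * p^2)
  n1 <- round(2 * n * p * (1 - p))
  n0 <- n - n1 - n2
  sample(rep(c(0L, 1L, 2L), c(n0, n1, n2)))
}

#' Simulate a genotype panel with planted QC violations
#'
#' Clean SNPs are built from rounded Hardy-Weinberg expected counts at
#' frequencies in `[0.2, 0.45]`, so they pass all three filters with
#' margin. Planted violations (disjoint SNP classes): call-rate SNPs with
#' 15% missing calls; MAF SNPs monomorphic or with a single heterozygote;
#' HWE SNPs with a total heterozygote deficit at frequency ~0.5 (exact-test
#' p far below 1e-6 for the default sample sizes).
#'
#' @param config a [sim_config()] (uses `seed`, `qc`, and the sample
#'   layout).
#' @return list: `genotypes` ([genotype_matrix()]), `truth` (violating SNP
#'   indices by reason).
#' @export
simulate_genotypes_for_qc <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_pops * config$n_samples_per_pop
  qc <- config$qc
  n_snp <- qc$n_snps
  n_bad <- qc$n_callrate + qc$n_maf + qc$n_hwe
  # below 22 diploid samples the exact test cannot reach p < 1e-6 at all
  # (the fully split (n/2, 0, n/2) table has p ~ 1.3e-6 at n = 20)
  stopifnot(n_bad <= n_snp, n >= 24)
  bad_idx <- sort(sample.int(n_snp, n_bad))
  idx_cr <- bad_idx[seq_len(qc$n_callrate)]
  idx_maf <- bad_idx[qc$n_callrate + seq_len(qc$n_maf)]
  idx_hwe <- bad_idx[qc$n_callrate + qc$n_maf + seq_len(qc$n_hwe)]

  calls <- matrix(0L, n, n_snp)
  for (j in seq_len(n_snp)) {
    if (j %in% idx_cr) {
      n_miss <- ceiling(0.15 * n)
      col <- c(rep(NA_integer_, n_miss),
               hwe_column(n - n_miss, stats::runif(1, 0.2, 0.45)))
      calls[, j] <- sample(col)
    } else if (j %in% idx_maf) {
      col <- rep(0L, n)
      if (stats::runif(1) < 0.5) col[sample.int(n, 1)] <- 1L  # singleton het
      calls[, j] <- col
    } else if (j %in% idx_hwe) {
      n2 <- floor(n / 2)
      calls[, j] <- sample(rep(c(0L, 2L), c(n - n2, n2)))
    } else {
      calls[, j] <- hwe_column(n, stats::runif(1, 0.2, 0.45))
    }
  }
  # orient every SNP so the first non-missing call is 0 or 1: the PLINK
  # text dialect carries no allele labels, so the reader's "first allele
  # seen is the reference" rule then round-trips calls exactly
  for (j in seq_len(n_snp)) {
    first <- calls[which(!is.na(calls[, j]))[1], j]
    if (first == 2L) calls[, j] <- 2L - calls[, j]
  }
  pops <- rep(paste0("POP", seq_len(config$n_pops)),
              each = config$n_samples_per_pop)
  samples <- paste0(pops, "_S",
                    rep(seq_len(config$n_samples_per_pop), config$n_pops))
  snps <- data.frame(chrom = "chr1", pos = 1000L * seq_len(n_snp),
                     id = sprintf("qc%05d", seq_len(n_snp)),
                     ref = "A", alt = "G", anc = "unknown",
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(snps, samples, pops, calls)
  list(genotypes = g,
       truth = list(fail_callrate = idx_cr, fail_maf = idx_maf,
                    fail_hwe = idx_hwe, seed = config$seed))
}

#' Simulate stage-structured expression with known DE genes
#'
#' Integer fragment counts are generated first -- per-gene log-normal
#' baselines, a multiplicative `effect_fold` for each planted gene in its
#' focal stage, and log-normal noise with coefficient of variation
#' `noise_cv` -- and the FPKM matrix is then *defined* as [fpkm_matrix()]
#' of those counts, so the count/FPKM round trip is exact by construction.
#'
#' @param config a [sim_config()] (uses `seed` and `expression`).
#' @return list: `expression` ([expression_matrix()]), `counts`, `lengths`,
#'   `truth` (data.frame gene_id, stage of planted DE genes).
#' @export
simulate_expression <- function(config) {
  set.seed(config$seed + 2L)
  ex <- config$expression
  n_g <- ex$n_genes
  stages <- ex$stages
  n_s <- length(stages) * ex$reps_per_stage
  stage_of_sample <- rep(stages, each = ex$reps_per_stage)
  sample_ids <- paste0(stage_of_sample, "_R",
                       rep(seq_len(ex$reps_per_stage), length(stages)))
  gene_ids <- sprintf("GENE%05d", seq_len(n_g))
  lengths <- sample(500:5000, n_g, replace = TRUE)
  mu <- stats::rlnorm(n_g, meanlog = log(50), sdlog = 1)

  de_idx <- sample.int(n_g, ex$n_de_per_stage * length(stages))
  de <- data.frame(gene_id = gene_ids[de_idx],
                   stage = rep(stages, each = ex$n_de_per_stage),
                   stringsAsFactors = FALSE)
  fold <- matrix(1, n_g, n_s)
  for (s in seq_along(stages))
    fold[de_idx[(s - 1) * ex$n_de_per_stage + seq_len(ex$n_de_per_stage)],
         stage_of_sample == stages[s]] <- ex$effect_fold

  sdlog <- sqrt(log(1 + ex$noise_cv^2))
  noise <- if (ex$noise_cv > 0)
    matrix(stats::rlnorm(n_g * n_s, -sdlog^2 / 2, sdlog), n_g, n_s)
  else matrix(1, n_g, n_s)
  depth <- 2e7 / 1e6                       # nominal 20M fragments, per-FPKM
  counts <- round(mu * fold * noise * (lengths / 1e3) * depth)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)
  expr <- fpkm_matrix(counts, lengths, stage_of_sample = stage_of_sample)
  list(expression = expr, counts = counts,
       lengths = stats::setNames(lengths, gene_ids),
       truth = list(de_genes = de, seed = config$seed))
}

#' Tile toy genes over a SNP panel
#' @param snps SNP table.
#' @param snps_per_gene genes span consecutive blocks of this many SNPs;
#'   the gene count is `ceiling(n_snps / snps_per_gene)`.
#' @return [gene_annotation()].
#' @export
tile_genes <- function(snps, snps_per_gene = 10) {
  n <- nrow(snps)
  n_gene <- ceiling(n / snps_per_gene)
  idx_lo <- (seq_len(n_gene) - 1) * snps_per_gene + 1
  idx_hi <- pmin(seq_len(n_gene) * snps_per_gene, n)
  gene_annotation(data.frame(
    gene_id = sprintf("GENE%05d", seq_len(n_gene)),
    chrom = snps$chrom[idx_lo], start = snps$pos[idx_lo],
    end = snps$pos[idx_hi], stringsAsFactors = FALSE))
}

#' Emit a complete fixture bundle
#'
#' Writes, deterministically for a fixed seed: a merged phased VCF plus
#' sample-to-population map, a PLINK .ped/.map pair of the QC panel, a GFF3
#' of tiled toy genes, expression TSVs (FPKM, counts, gene lengths, stage
#' map) and a ground-truth JSON.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
emit_fixture_bundle <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)

  sim <- simulate_haplotypes(config)
  g <- haps_to_genotypes(sim$haplotypes)
  write_vcf(g, fp("genotypes.vcf"))
  utils::write.table(data.frame(sample = g$samples, pop = g$pops),
                     fp("pop_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  qc_sim <- simulate_genotypes_for_qc(config)
  write_plink(qc_sim$genotypes, fp("qc_panel.ped"), fp("qc_panel.map"))

  ann <- tile_genes(sim$haplotypes$snps)
  write_gff(ann, fp("genes.gff3"))

  ex <- simulate_expression(config)
  dt_num <- function(m) data.frame(gene_id = rownames(m), m,
                                   check.names = FALSE)
  data.table::fwrite(dt_num(ex$expression$values), fp("fpkm.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(dt_num(ex$counts), fp("counts.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(data.frame(gene_id = names(ex$lengths),
                                length_bp = as.integer(ex$lengths)),
                     fp("gene_lengths.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(data.frame(sample = ex$expression$sample_ids,
                                stage = ex$expression$stage_of_sample),
                     fp("stages.tsv"), sep = "\t", quote = FALSE)

  truth <- list(seed = config$seed, sweeps = sim$truth$sweeps,
                qc = qc_sim$truth[c("fail_callrate", "fail_maf", "fail_hwe")],
                de_genes = ex$truth$de_genes)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(config), fp("sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(vcf = fp("genotypes.vcf"), pop_map = fp("pop_map.tsv"),
             ped = fp("qc_panel.ped"), map = fp("qc_panel.map"),
             gff = fp("genes.gff3"), fpkm = fp("fpkm.tsv"),
             counts = fp("counts.tsv"), lengths = fp("gene_lengths.tsv"),
             stages = fp("stages.tsv"), truth = fp("truth.json"),
             config = fp("sim_config.json"))
  invisible(files)
}
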