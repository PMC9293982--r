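#' @useDynLib desertsweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# SNP tables are plain data.frames with columns chrom, pos, id, ref, alt, anc
# (anc in {"ref","alt","unknown"}); 1-based inclusive coordinates throughout.

validate_snp_table <- function(snps) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "id", "ref", "alt", "anc") %in% names(snps)))
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  if (any(snps$ref == snps$alt)) stop("ref and alt allele must differ")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop("SNPs on chromosome ", ch,
           " must be sorted by strictly increasing position")
  }
  invisible(snps)
}

#' Construct a diploid genotype matrix
#'
#' The central container of the QC/structure arm: per-sample counts of the
#' alternate allele (0/1/2, `NA` = missing) at biallelic SNPs, plus an
#' explicit population label per sample. Optional phase information (the two
#' per-haplotype alleles and a phased flag) is carried along so phased VCF
#' input can later be expanded to haplotypes.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `anc`; positions 1-based, strictly increasing within chromosome.
#' @param samples character vector of sample identifiers.
#' @param pops population label per sample (same length as `samples`).
#' @param calls integer matrix, samples x SNPs, values in `c(0,1,2,NA)`.
#' @param a1,a2 optional integer matrices (samples x SNPs) with the 0/1
#'   allele carried on the first/second haplotype.
#' @param phased optional logical matrix marking phased genotypes.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, samples, pops, calls,
                            a1 = NULL, a2 = NULL, phased = NULL) {
  validate_snp_table(snps)
  samples <- as.character(samples)
  pops <- as.character(pops)
  if (length(pops) != length(samples))
    stop("need exactly one population label per sample")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(snps))
    stop("calls must be |samples| x |snps|")
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("calls must be 0, 1, 2 or NA")
  rownames(calls) <- samples
  colnames(calls) <- snps$id
  structure(list(snps = snps, samples = samples, pops = pops, calls = calls,
                 a1 = a1, a2 = a2, phased = phased),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs; populations: %s\n",
              length(x$samples), nrow(x$snps),
              paste(sprintf("%s(%d)", names(table(x$pops)), table(x$pops)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Construct a phased haplotype matrix
#'
#' Substrate of all EHH-family statistics: one row per haplotype, alleles
#' coded 0 = ancestral / 1 = derived, no missing entries.
#'
#' @param snps SNP table as in [genotype_matrix()].
#' @param haps integer matrix haplotypes x SNPs with values 0/1.
#' @param sample_of_haplotype owning sample id per haplotype row.
#' @param pops population label per haplotype row.
#' @param anc_policy how alleles were polarized (recorded metadata).
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(snps, haps, sample_of_haplotype, pops,
                             anc_policy = "unknown") {
  validate_snp_table(snps)
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (anyNA(haps)) stop("haplotypes must not contain missing entries")
  if (!all(haps %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  if (ncol(haps) != nrow(snps)) stop("haps must have one column per SNP")
  if (nrow(haps) != length(sample_of_haplotype) ||
      nrow(haps) != length(pops))
    stop("need sample and population labels for every haplotype row")
  structure(list(snps = snps, haps = haps,
                 sample_of_haplotype = as.character(sample_of_haplotype),
                 pops = as.character(pops), anc_policy = anc_policy),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<haplotype_matrix> %d haplotypes x %d SNPs (anc_policy=%s)\n",
    nrow(x$haps), nrow(x$snps), x$anc_policy))
  invisible(x)
}

#' Subset a haplotype matrix to one population
#' @param h `haplotype_matrix`
#' @param pop population label to keep
#' @return `haplotype_matrix` with only that population's haplotypes.
#' @export
hap_subset <- function(h, pop) {
  keep <- h$pops %in% pop
  if (!any(keep)) stop("no haplotypes in population ", paste(pop, collapse = "+"))
  haplotype_matrix(h$snps, h$haps[keep, , drop = FALSE],
                   h$sample_of_haplotype[keep], h$pops[keep], h$anc_policy)
}

#' Construct a per-SNP score table
#'
#' Shared result container for FST/iHS/xp-EHH/Rsb: raw and standardized
#' statistic per SNP with a validity flag and significance indicators filled
#' by [select_top()]-based thresholding.
#'
#' @param snps SNP table (chrom/pos/id used).
#' @param stat statistic name, e.g. `"ihs"`.
#' @param raw raw per-SNP values.
#' @param std standardized values (`NA` where invalid).
#' @param freq_der derived-allele frequency per SNP (or `NA`).
#' @param flag per-SNP validity flag: one of `"ok"`, `"maf_fail"`,
#'   `"edge_truncated"`, `"undefined"`.
#' @return data.frame of class `score_table`.
#' @export
score_table <- function(snps, stat, raw, std, freq_der = NA_real_,
                        flag = "ok") {
  df <- data.frame(chrom = snps$chrom, pos = snps$pos, id = snps$id,
                   stat = stat, raw = as.numeric(raw), std = as.numeric(std),
                   freq_der = freq_der, flag = flag,
                   sig_1pct = FALSE, sig_5pct = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Construct a gene annotation table
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  if (anyDuplicated(genes$gene_id)) stop("gene_id must be unique")
  genes <- as.data.frame(genes)[, c("gene_id", "chrom", "start", "end")]
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Construct a named gene set with provenance
#' @param name set label.
#' @param gene_ids character vector (deduplicated, sorted).
#' @param statistic,comparison,threshold provenance fields.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, gene_ids, statistic = NA_character_,
                     comparison = NA_character_, threshold = NA_real_) {
  structure(list(name = name, gene_ids = sort(unique(as.character(gene_ids))),
                 provenance = list(statistic = statistic,
                                   comparison = comparison,
                                   threshold = threshold)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes (stat=%s, comparison=%s, threshold=%s)\n",
              x$name, length(x$gene_ids), x$provenance$statistic,
              x$provenance$comparison, format(x$provenance$threshold)))
  invisible(x)
}

#' Construct an expression matrix with stage labels
#' @param values numeric matrix genes x samples, FPKM, non-negative.
#' @param gene_ids,sample_ids identifiers.
#' @param stage_of_sample stage label per sample (e.g. FP/LP/P30/P45).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids, sample_ids, stage_of_sample) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("values must be |genes| x |samples|")
  if (length(stage_of_sample) != length(sample_ids))
    stop("need one stage label per sample")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 stage_of_sample = as.character(stage_of_sample)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples; stages: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$stage_of_sample), collapse = ", ")))
  invisible(x)
}
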