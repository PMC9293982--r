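# Readers/writers for the formats the pipeline touches: VCF (GT-only,
# biallelic SNPs), PLINK .ped/.map (whitespace dialect), GFF3 gene models,
# Newick trees and TSV score tables.

normalize_pop_map <- function(pop_map) {
  if (is.null(pop_map)) stop("pop_map is required")
  if (is.data.frame(pop_map)) {
    stopifnot(ncol(pop_map) >= 2)
    stats::setNames(as.character(pop_map[[2]]), as.character(pop_map[[1]]))
  } else if (!is.null(names(pop_map))) {
    stats::setNames(as.character(pop_map), names(pop_map))
  } else stop("pop_map must be a data.frame(sample, pop) or named vector")
}

#' Read a VCF into a genotype matrix
#'
#' Only biallelic SNP records are kept; multiallelic or non-SNP (indel)
#' records are skipped with a message reporting the count. `./.` genotypes
#' become missing. Phase (the `|` separator) is preserved so the matrix can
#' later be expanded to haplotypes. The ancestral allele is taken from an
#' `AA` INFO tag when present, otherwise marked `"unknown"`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param pop_map sample-to-population table: a `data.frame(sample, pop)` or
#'   a named character vector. Every VCF sample must be covered.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, pop_map) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  pm <- normalize_pop_map(pop_map)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  is_snp <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref != alt1
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " multiallelic/non-SNP record(s)")
  vcf <- vcf[is_snp, ]
  rr <- rr[is_snp]
  samples <- colnames(vcf)
  missing_pop <- setdiff(samples, names(pm))
  if (length(missing_pop))
    stop("samples absent from pop_map: ", paste(missing_pop, collapse = ", "))

  gt <- VariantAnnotation::geno(vcf)$GT  # SNPs x samples, strings
  parse_allele <- function(idx) {
    a <- substr(gt, idx, idx)
    m <- matrix(suppressWarnings(as.integer(a)), nrow = nrow(gt))
    m
  }
  a1 <- t(parse_allele(1L))
  a2 <- t(parse_allele(3L))
  phased <- t(substr(gt, 2, 2) == "|")
  calls <- a1 + a2

  anc <- rep("unknown", sum(is_snp))
  info <- VariantAnnotation::info(vcf)
  if ("AA" %in% names(info)) {
    aa <- as.character(info$AA)
    anc[!is.na(aa) & aa == ref[is_snp]] <- "ref"
    anc[!is.na(aa) & aa == alt1[is_snp]] <- "alt"
  }
  snps <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     id = make.unique(names(rr)),
                     ref = ref[is_snp], alt = alt1[is_snp], anc = anc,
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, samples, unname(pm[samples]), calls,
                  a1 = a1, a2 = a2, phased = phased)
}

#' Write a genotype matrix as a GT-only VCF
#'
#' Emits VCFv4.2 with one `GT` FORMAT field. Phased genotypes (when the
#' matrix carries phase) use `|`, otherwise `/`; missing calls become `./.`.
#'
#' @param g [genotype_matrix()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  s <- g$snps
  hdr <- c("##fileformat=VCFv4.2",
           "##source=desertsweep",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##contig=<ID=", unique(s$chrom), ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples), collapse = "\t"))
  n_snp <- nrow(s)
  if (is.null(g$a1)) {
    gt1 <- matrix(c("0", "0", "1")[g$calls + 1L], nrow = nrow(g$calls))
    gt2 <- matrix(c("0", "1", "1")[g$calls + 1L], nrow = nrow(g$calls))
    sep <- matrix("/", nrow(g$calls), n_snp)
  } else {
    gt1 <- matrix(as.character(g$a1), nrow = nrow(g$calls))
    gt2 <- matrix(as.character(g$a2), nrow = nrow(g$calls))
    sep <- matrix(ifelse(g$phased, "|", "/"), nrow(g$calls), n_snp)
  }
  gt <- matrix(paste0(gt1, sep, gt2), nrow = nrow(g$calls))
  gt[is.na(g$calls)] <- "./."
  info <- ifelse(s$anc == "ref", paste0("AA=", s$ref),
                 ifelse(s$anc == "alt", paste0("AA=", s$alt), "."))
  body <- apply(cbind(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS",
                      info, "GT", t(gt)), 1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a PLINK .ped/.map pair
#'
#' Whitespace-delimited text dialect: six leading .ped columns
#' (FID IID PID MID SEX PHENO) then two allele columns per SNP; the family
#' ID is used as the population label and `0` alleles are missing. The
#' first allele encountered (in sample order) at each SNP is taken as the
#' reference; calls count the other (alternate) allele.
#'
#' @param ped_path,map_path file paths.
#' @return A [genotype_matrix()] (unphased).
#' @export
read_plink <- function(ped_path, map_path) {
  map <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(map) != 4) stop("malformed .map: expected 4 columns")
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp)
    stop(".ped/.map SNP-count mismatch: .ped implies ",
         (ncol(ped) - 6) / 2, " SNPs, .map lists ", n_snp)
  al1 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE])
  al2 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp), drop = FALSE])
  al1[al1 == "0"] <- NA
  al2[al2 == "0"] <- NA

  ref <- alt <- character(n_snp)
  calls <- matrix(NA_integer_, nrow(ped), n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(rbind(al1[, j], al2[, j]))  # sample-major order of alleles
    obs_nm <- obs[!is.na(obs)]
    if (!length(obs_nm)) stop("SNP ", map[[2]][j], " has no non-missing calls")
    ref[j] <- obs_nm[1]
    others <- setdiff(unique(obs_nm), ref[j])
    if (length(others) > 1)
      stop("SNP ", map[[2]][j], " has more than two alleles")
    alt[j] <- if (length(others)) others else "N"
    calls[, j] <- (al1[, j] != ref[j]) + (al2[, j] != ref[j])
  }
  snps <- data.frame(chrom = map[[1]], pos = as.integer(map[[4]]),
                     id = map[[2]], ref = ref, alt = alt, anc = "unknown",
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, ped[[2]], ped[[1]], calls)
}

#' Write a genotype matrix as a PLINK .ped/.map pair
#' @param g [genotype_matrix()]
#' @param ped_path,map_path output files.
#' @return invisibly, `c(ped_path, map_path)`.
#' @export
write_plink <- function(g, ped_path, map_path) {
  s <- g$snps
  utils::write.table(
    data.frame(s$chrom, s$id, 0, s$pos),
    map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  n_snp <- nrow(s)
  out <- matrix("", nrow(g$calls), 2 * n_snp)
  for (j in seq_len(n_snp)) {
    c_j <- g$calls[, j]
    a1 <- ifelse(is.na(c_j), "0", ifelse(c_j == 2, s$alt[j], s$ref[j]))
    a2 <- ifelse(is.na(c_j), "0", ifelse(c_j >= 1, s$alt[j], s$ref[j]))
    out[, 2 * j - 1] <- a1
    out[, 2 * j] <- a2
  }
  lead <- cbind(g$pops, g$samples, "0", "0", "0", "-9")
  utils::write.table(cbind(lead, out), ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Expand a phased genotype matrix to haplotypes
#'
#' All genotypes must be phased and non-missing (QC runs first; no
#' imputation). Alleles are recoded so that 0 = ancestral under the chosen
#' polarization policy:
#' * `major_allele` (default): the genome-wide major allele, pooled over all
#'   populations, is ancestral; 50/50 ties break toward the reference allele.
#' * `alt_is_derived`: keep the ref=0/alt=1 coding unchanged.
#' * `from_info_tag`: use the SNP table's `anc` column (e.g. a VCF `AA`
#'   tag); SNPs with unknown ancestral state raise an error.
#'
#' @param g phased [genotype_matrix()].
#' @param anc_policy one of `"major_allele"`, `"alt_is_derived"`,
#'   `"from_info_tag"`.
#' @return A [haplotype_matrix()] with 2 rows per sample.
#' @export
to_haplotypes <- function(g, anc_policy = c("major_allele", "alt_is_derived",
                                            "from_info_tag")) {
  anc_policy <- match.arg(anc_policy)
  if (is.null(g$a1) || is.null(g$phased))
    stop("genotype matrix carries no phase information ",
         "(read from a phased VCF)")
  bad <- which(!g$phased | is.na(g$a1) | is.na(g$a2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("unphased or missing genotype at sample ",
         g$samples[bad[1, 1]], ", SNP ", g$snps$id[bad[1, 2]])

  n_s <- length(g$samples)
  haps <- matrix(0L, 2 * n_s, nrow(g$snps))
  haps[2 * seq_len(n_s) - 1, ] <- g$a1
  haps[2 * seq_len(n_s), ] <- g$a2

  flip <- switch(anc_policy,
    alt_is_derived = rep(FALSE, nrow(g$snps)),
    major_allele = colMeans(haps) > 0.5,  # ties (=0.5) keep ref ancestral
    from_info_tag = {
      if (any(g$snps$anc == "unknown"))
        stop("ancestral allele unknown for ",
             sum(g$snps$anc == "unknown"), " SNP(s)")
      g$snps$anc == "alt"
    })
  if (any(flip)) haps[, flip] <- 1L - haps[, flip]

  haplotype_matrix(g$snps, haps,
                   sample_of_haplotype = rep(g$samples, each = 2),
                   pops = rep(g$pops, each = 2), anc_policy = anc_policy)
}

#' Read gene models from a GFF3 file
#'
#' Only `gene` features are retained; the gene identifier comes from the
#' `ID` attribute (falling back to `gene_id`/`Name`). Structural problems
#' (non-comment lines without 9 tab-separated fields) raise an error naming
#' the offending line.
#'
#' @param path GFF3 file.
#' @return A [gene_annotation()].
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  data_lines <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[data_lines], "\t", fixed = TRUE))
  if (any(nfield != 9))
    stop("malformed GFF line ", data_lines[which(nfield != 9)[1]],
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$gene_id
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) stop("GFF gene features carry no ID attribute")
  gene_annotation(data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Write a GFF3 file of gene features
#' @param ann [gene_annotation()]
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(ann, path) {
  writeLines(c("##gff-version 3",
               sprintf("%s\tdesertsweep\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       ann$chrom, ann$start, ann$end, ann$gene_id)), path)
  invisible(path)
}

# Recursive Newick serializer with fixed 6-decimal branch lengths. `tree` is
# an ape-compatible "phylo" list (edge, edge.length, tip.label, Nnode) or a
# single leaf label.
format_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1) return(paste0(tree, ";"))
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    e <- kids[[as.character(node)]]
    parts <- vapply(e, function(i) {
      paste0(rec(tree$edge[i, 2]),
             ":", sprintf("%.6f", tree$edge.length[i]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Serialize a tree to a Newick file
#'
#' Branch lengths are written with fixed 6-decimal formatting. A single
#' label (degenerate one-leaf tree) serializes as `"label;"`.
#'
#' @param tree an ape-style `phylo` object (as returned by
#'   [neighbor_joining()]) or a single leaf label.
#' @param path output file; `NULL` returns the string.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- format_newick(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write / read a score table TSV
#'
#' The on-disk schema is the fixed header
#' `chrom,pos,id,stat,raw,std,sig_1pct,sig_5pct` (tab-separated).
#'
#' @param scores a [score_table()].
#' @param path file path.
#' @return `path` invisibly (writer); a `score_table` (reader).
#' @export
write_score_table <- function(scores, path) {
  out <- scores[, c("chrom", "pos", "id", "stat", "raw", "std",
                    "sig_1pct", "sig_5pct")]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  expected <- c("chrom", "pos", "id", "stat", "raw", "std",
                "sig_1pct", "sig_5pct")
  if (!identical(names(df), expected))
    stop("unexpected score-table header in ", path)
  df$chrom <- as.character(df$chrom)
  df$id <- as.character(df$id)
  df$freq_der <- NA_real_
  df$flag <- ifelse(is.na(df$std), "undefined", "ok")
  df <- df[, c("chrom", "pos", "id", "stat", "raw", "std", "freq_der",
               "flag", "sig_1pct", "sig_5pct")]
  class(df) <- c("score_table", "data.frame")
  df
}
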