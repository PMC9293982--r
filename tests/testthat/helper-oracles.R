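# Independent oracles and tiny fixture builders shared across the suite.
# Every oracle is deliberately coded on a different path than the package
# implementation it checks.

# --- fixture builders -------------------------------------------------------

make_snps <- function(n, pos = NULL, chrom = "chr1") {
  data.frame(chrom = chrom, pos = if (is.null(pos)) seq_len(n) * 1000L
             else as.integer(pos),
             id = sprintf("s%03d", seq_len(n)), ref = "A", alt = "G",
             anc = "ref", stringsAsFactors = FALSE)
}

make_g <- function(calls, pos = NULL, pops = NULL, chrom = "chr1") {
  calls <- as.matrix(calls)
  n_s <- nrow(calls)
  genotype_matrix(make_snps(ncol(calls), pos, chrom),
                  samples = paste0("S", seq_len(n_s)),
                  pops = if (is.null(pops)) rep("P1", n_s) else pops,
                  calls = calls)
}

make_h <- function(haps, pos = NULL, pops = NULL, chrom = "chr1") {
  haps <- as.matrix(haps)
  n_h <- nrow(haps)
  stopifnot(n_h %% 2 == 0)
  haplotype_matrix(make_snps(ncol(haps), pos, chrom), haps,
                   sample_of_haplotype = rep(paste0("S", seq_len(n_h / 2)),
                                             each = 2),
                   pops = if (is.null(pops)) rep("P1", n_h) else pops,
                   anc_policy = "alt_is_derived")
}

# --- Hardy-Weinberg enumeration oracle --------------------------------------

# Direct log-multinomial enumeration of the conditional distribution of the
# heterozygote count given allele totals.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hmax <- min(nA, 2 * n - nA)
  hets <- seq(nA %% 2, hmax, by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (2 * n - nA - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# --- Weir-Cockerham textbook oracle -----------------------------------------

# Scalar, loop-free-of-vectorization transliteration of the 1984 variance
# component equations for r = 2 populations at one SNP.
wc_oracle <- function(calls_a, calls_b) {
  calls_a <- calls_a[!is.na(calls_a)]
  calls_b <- calls_b[!is.na(calls_b)]
  n <- c(length(calls_a), length(calls_b))
  p <- c(sum(calls_a) / (2 * n[1]), sum(calls_b) / (2 * n[2]))
  h <- c(mean(calls_a == 1), mean(calls_b == 1))
  r <- 2
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA else a / (a + b + cc))
}

# --- brute-force EHH / EHHS over haplotype strings --------------------------

ehh_brute <- function(haps, core, allele, s) {
  carriers <- which(haps[, core] == allele)
  nc <- length(carriers)
  seg <- apply(haps[carriers, min(core, s):max(core, s), drop = FALSE], 1,
               paste, collapse = "")
  nk <- table(seg)
  sum(nk * (nk - 1)) / (nc * (nc - 1))
}

ehhs_brute <- function(haps, core, s) {
  hom <- function(upto) {
    seg <- apply(haps[, min(core, upto):max(core, upto), drop = FALSE], 1,
                 paste, collapse = "")
    nk <- table(seg)
    n <- nrow(haps)
    sum(nk * (nk - 1)) / (n * (n - 1))
  }
  hom(s) / hom(core)
}

# --- misc -------------------------------------------------------------------

pooled_t_oracle <- function(y1, y2) {
  unname(stats::t.test(y1, y2, var.equal = TRUE)$statistic)
}

# all-pairs SNP-in-gene overlap
overlap_oracle <- function(snp_set, ann, flank) {
  hits <- character(0)
  for (k in seq_len(nrow(ann))) {
    for (i in seq_len(nrow(snp_set))) {
      if (snp_set$chrom[i] == ann$chrom[k] &&
          snp_set$pos[i] >= ann$start[k] - flank &&
          snp_set$pos[i] <= ann$end[k] + flank) {
        hits <- c(hits, ann$gene_id[k])
        break
      }
    }
  }
  sort(unique(hits))
}

mean_silhouette <- function(coords, labels) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  mean(vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# brute-force post-check of the pruning contract: within every window the
# pruner visited, no retained pair exceeds the threshold
prune_violations <- function(g, kept, window_snps = 50, step_snps = 10,
                             r2_max = 0.1) {
  bad <- 0L
  for (ch in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == ch)
    for (s in seq(1, length(idx), by = step_snps)) {
      win <- intersect(idx[s:min(s + window_snps - 1, length(idx))], kept)
      if (length(win) < 2) next
      for (i in seq_len(length(win) - 1)) for (j in (i + 1):length(win)) {
        r2 <- tryCatch(ld_r2(g, win[i], win[j], mode = "composite"),
                       error = function(e) 0)
        if (r2 > r2_max) bad <- bad + 1L
      }
    }
  }
  bad
}
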