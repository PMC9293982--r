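# Selection-sweep statistics: EHH curves and their integrals (iHH, iES),
# iHS, xp-EHH, Rsb and per-SNP Weir-Cockerham FST, each with genome-wide
# standardization.

#' Sweep-scan configuration
#'
#' @param ehh_cutoff truncation level for EHH extension (default 0.05).
#' @param core_maf_min minimum core-SNP MAF for iHS (default 0.05).
#' @param freq_bins number of equal-width derived-frequency bins for iHS
#'   standardization (default 20; bins with < 10 scores merge with a
#'   neighbor).
#' @param edge_policy what to do with cores whose EHH never reaches the
#'   cutoff before the chromosome end: `"discard"` (flag and exclude from
#'   standardization, default) or `"truncate"` (keep the partial integral).
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(ehh_cutoff = 0.05, core_maf_min = 0.05,
                         freq_bins = 20,
                         edge_policy = c("discard", "truncate")) {
  stopifnot(ehh_cutoff > 0, ehh_cutoff < 1, freq_bins >= 2)
  structure(list(ehh_cutoff = ehh_cutoff, core_maf_min = core_maf_min,
                 freq_bins = freq_bins,
                 edge_policy = match.arg(edge_policy)),
            class = "sweep_config")
}

check_same_panel <- function(a, b) {
  if (!identical(a$snps$id, b$snps$id) || !identical(a$snps$pos, b$snps$pos))
    stop("the two populations must share the same SNP panel")
}

#' Extended haplotype homozygosity curve
#'
#' EHH at a flanking SNP s is the probability that two randomly chosen
#' carrier haplotypes of the core allele are identical over the interval
#' from the core to s: `sum_k n_k (n_k - 1) / (n_c (n_c - 1))` over the
#' distinct extended haplotypes. It equals 1 at the core and is
#' non-increasing outward; extension stops when it drops below
#' `config$ehh_cutoff` or the chromosome ends.
#'
#' @param haps [haplotype_matrix()]
#' @param core core SNP column index.
#' @param allele core allele (0 = ancestral, 1 = derived).
#' @param config [sweep_config()]
#' @return list of class `ehh_curve` with `core_index`, `allele_partition`
#'   and `points` (data.frame `pos`, `ehh`, ordered left to right; the core
#'   point carries ehh = 1).
#' @export
ehh <- function(haps, core, allele, config = sweep_config()) {
  l <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, allele, FALSE,
                     config$ehh_cutoff, -1L)
  r <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, allele, FALSE,
                     config$ehh_cutoff, 1L)
  pts <- data.frame(
    pos = c(rev(haps$snps$pos[l$snp + 1L]), haps$snps$pos[core],
            haps$snps$pos[r$snp + 1L]),
    ehh = c(rev(l$ehh), 1, r$ehh))
  structure(list(core_index = core, side = "both",
                 allele_partition = if (allele == 0) "ancestral" else "derived",
                 points = pts), class = "ehh_curve")
}

#' Site-specific EHH (EHHS) curve
#'
#' EHHS pools all haplotypes regardless of core allele: haplotype
#' homozygosity over `[core..s]` normalized to 1 at the core (Tang
#' convention). The unnormalized homozygosity (Sabeti convention, used by
#' xp-EHH) is returned alongside.
#'
#' @inheritParams ehh
#' @return `ehh_curve` whose `points` also carry `ehh_unnorm`.
#' @export
ehhs <- function(haps, core, config = sweep_config()) {
  l <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, 0L, TRUE,
                     config$ehh_cutoff, -1L)
  r <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, 0L, TRUE,
                     config$ehh_cutoff, 1L)
  n <- nrow(haps$haps)
  f <- mean(haps$haps[, core])
  h0 <- (f^2 + (1 - f)^2) * n / (n - 1) - 1 / (n - 1)  # core homozygosity
  pts <- data.frame(
    pos = c(rev(haps$snps$pos[l$snp + 1L]), haps$snps$pos[core],
            haps$snps$pos[r$snp + 1L]),
    ehh = c(rev(l$ehh), 1, r$ehh),
    ehh_unnorm = c(rev(l$ehh_unnorm), h0, r$ehh_unnorm))
  structure(list(core_index = core, side = "both", allele_partition = "site",
                 points = pts), class = "ehh_curve")
}

#' Integrated haplotype homozygosity at one core
#'
#' Trapezoidal integral of the two-sided EHH curve over physical distance
#' (bp), from the core to the linearly interpolated point where the curve
#' crosses the cutoff. Under `edge_policy = "discard"` a side that never
#' reaches the cutoff marks the core `edge_truncated`.
#'
#' @inheritParams ehh
#' @return list: `area` (bp), `edge_truncated` (logical).
#' @export
ihh <- function(haps, core, allele, config = sweep_config()) {
  l <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, allele, FALSE,
                     config$ehh_cutoff, -1L)
  r <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, allele, FALSE,
                     config$ehh_cutoff, 1L)
  list(area = l$area + r$area, edge_truncated = !(l$reached && r$reached))
}

#' Integrated EHHS (iES / inES) at one core
#' @inheritParams ehh
#' @return list: `ies` (Tang-normalized integral), `ines` (Sabeti
#'   unnormalized integral), `edge_truncated`.
#' @export
ies <- function(haps, core, config = sweep_config()) {
  l <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, 0L, TRUE,
                     config$ehh_cutoff, -1L)
  r <- .cpp_ehh_side(haps$haps, haps$snps$pos, core - 1L, 0L, TRUE,
                     config$ehh_cutoff, 1L)
  list(ies = l$area + r$area, ines = l$area_unnorm + r$area_unnorm,
       edge_truncated = !(l$reached && r$reached))
}

# Full genome scan; chromosome-aware (extension never crosses a chromosome
# boundary because each chromosome is scanned separately).
scan_hh <- function(haps, config = sweep_config()) {
  res <- vector("list", length(unique(haps$snps$chrom)))
  for (k in seq_along(unique(haps$snps$chrom))) {
    ch <- unique(haps$snps$chrom)[k]
    idx <- which(haps$snps$chrom == ch)
    df <- .cpp_scan_hh(haps$haps[, idx, drop = FALSE], haps$snps$pos[idx],
                       config$ehh_cutoff, config$core_maf_min)
    res[[k]] <- df
  }
  do.call(rbind, res)
}

# Merge small frequency bins with their nearest neighbor until every
# remaining bin holds >= min_n valid scores (or one bin remains).
merge_bins <- function(bin, valid, min_n = 10) {
  bin <- as.integer(bin)
  repeat {
    tab <- table(bin[valid])
    if (!length(tab) || min(tab) >= min_n || length(tab) == 1) break
    small <- as.integer(names(tab)[which.min(tab)])
    lv <- as.integer(names(tab))
    neighbors <- lv[lv != small]
    target <- neighbors[which.min(abs(neighbors - small))]
    bin[bin == small] <- target
  }
  bin
}

#' iHS scan
#'
#' Per SNP with MAF >= `core_maf_min`, `raw = ln(iHH_ancestral /
#' iHH_derived)`; standardized within derived-allele-frequency bins
#' (`freq_bins` equal-width bins over (0,1), small bins merged) as
#' `z = (raw - mean_bin) / sd_bin`. Cores failing the MAF filter, with a
#' zero/undefined integral, or truncated at a chromosome edge (under
#' `edge_policy = "discard"`) are flagged and excluded from
#' standardization.
#'
#' @param haps polarized [haplotype_matrix()] (0 = ancestral).
#' @param config [sweep_config()]
#' @return a [score_table()] with `stat = "ihs"`.
#' @export
ihs <- function(haps, config = sweep_config()) {
  sc <- scan_hh(haps, config)
  raw <- log(sc$ihh_anc / sc$ihh_der)
  flag <- rep("ok", nrow(sc))
  flag[sc$maf_fail] <- "maf_fail"
  flag[!sc$maf_fail & (is.na(raw) | !is.finite(raw))] <- "undefined"
  if (config$edge_policy == "discard")
    flag[flag == "ok" & sc$edge_allele] <- "edge_truncated"
  valid <- flag == "ok"

  std <- rep(NA_real_, nrow(sc))
  if (any(valid)) {
    bin0 <- pmin(config$freq_bins,
                 floor(sc$freq_der * config$freq_bins) + 1L)
    bin <- merge_bins(bin0, valid)
    for (b in unique(bin[valid])) {
      in_b <- valid & bin == b
      if (sum(in_b) < 10) {
        flag[in_b] <- "undefined"         # can't standardize a tiny bin
        next
      }
      mu <- mean(raw[in_b]); sdv <- stats::sd(raw[in_b])
      std[in_b] <- if (sdv > 0) (raw[in_b] - mu) / sdv else 0
    }
  }
  std[flag != "ok"] <- NA_real_
  score_table(haps$snps, "ihs", raw, std, freq_der = sc$freq_der,
              flag = flag)
}

# shared ln-ratio machinery for the two cross-population statistics
xp_ratio <- function(haps_a, haps_b, config, column, stat_name,
                     standardize) {
  check_same_panel(haps_a, haps_b)
  sa <- scan_hh(haps_a, config)
  sb <- scan_hh(haps_b, config)
  raw <- log(sa[[column]] / sb[[column]])
  flag <- rep("ok", nrow(sa))
  flag[is.na(raw) | !is.finite(raw)] <- "undefined"
  if (config$edge_policy == "discard")
    flag[flag == "ok" & (sa$edge_site | sb$edge_site)] <- "edge_truncated"
  valid <- flag == "ok"
  std <- rep(NA_real_, nrow(sa))
  if (sum(valid) >= 2) {
    if (standardize == "zscore") {
      std[valid] <- (raw[valid] - mean(raw[valid])) / stats::sd(raw[valid])
    } else {                              # median-centered variant
      std[valid] <- (raw[valid] - stats::median(raw[valid])) /
        stats::sd(raw[valid])
    }
  }
  freq_pooled <- (sa$freq_der * nrow(haps_a$haps) +
                  sb$freq_der * nrow(haps_b$haps)) /
    (nrow(haps_a$haps) + nrow(haps_b$haps))
  score_table(haps_a$snps, stat_name, raw, std, freq_der = freq_pooled,
              flag = flag)
}

#' xp-EHH scan
#'
#' Cross-population EHH: per SNP, `raw = ln(inES_A / inES_B)` where inES is
#' the allele-pooled integral of the unnormalized site haplotype
#' homozygosity in each population; standardized genome-wide by z-score.
#' Positive extremes indicate longer haplotype homozygosity (a sweep) in
#' population A, negative in B; swapping populations negates every score.
#'
#' @param haps_a,haps_b [haplotype_matrix()] for the two populations, same
#'   SNP panel.
#' @param config [sweep_config()]
#' @return a [score_table()] with `stat = "xpehh"`.
#' @export
xpehh <- function(haps_a, haps_b, config = sweep_config()) {
  xp_ratio(haps_a, haps_b, config, "ines", "xpehh", "zscore")
}

#' Rsb scan
#'
#' Per SNP, `raw = ln(iES_A / iES_B)` where iES integrates the
#' core-normalized EHHS; unlike iHS this needs no allele polarization.
#' Standardization is a genome-wide z-score by default; `"median"` centers
#' on the median instead (Tang-style robust centering).
#'
#' @inheritParams xpehh
#' @param standardize `"zscore"` (default) or `"median"`.
#' @return a [score_table()] with `stat = "rsb"`.
#' @export
rsb <- function(haps_a, haps_b, config = sweep_config(),
                standardize = c("zscore", "median")) {
  xp_ratio(haps_a, haps_b, config, "ies", "rsb", match.arg(standardize))
}

#' Per-SNP Weir-Cockerham FST
#'
#' Variance-component estimator for two populations: per SNP the components
#' a (between populations), b (between individuals within populations) and
#' c (within individuals) are formed from sample sizes, allele frequencies
#' and observed heterozygosity, and `theta = a / (a + b + c)`. SNPs where
#' `a + b + c = 0` or with fewer than 2 genotyped samples in either
#' population are flagged `undefined`. The `std` column is the genome-wide
#' z-score of theta. `attr(result, "mean_fst")` holds the ratio-of-sums
#' average `sum(a) / sum(a+b+c)` over valid SNPs.
#'
#' @param g [genotype_matrix()]
#' @param pop_a,pop_b population labels (each may name several pooled
#'   populations) or sample index vectors.
#' @return a [score_table()] with `stat = "fst"` and attributes `mean_fst`,
#'   `components` (data.frame a, b, c).
#' @export
wc_fst <- function(g, pop_a, pop_b) {
  pick <- function(p) {
    if (is.character(p)) which(g$pops %in% p) else as.integer(p)
  }
  ia <- pick(pop_a); ib <- pick(pop_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each population needs at least 2 samples")

  comp <- function(idx) {
    m <- g$calls[idx, , drop = FALSE]
    n <- colSums(!is.na(m))
    p <- ifelse(n > 0, colSums(m, na.rm = TRUE) / (2 * n), NA)
    h <- ifelse(n > 0, colSums(m == 1, na.rm = TRUE) / n, NA)
    list(n = n, p = p, h = h)
  }
  A <- comp(ia); B <- comp(ib)
  r <- 2
  nbar <- (A$n + B$n) / r
  ok <- A$n >= 2 & B$n >= 2 & nbar > 1
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(ok & tot != 0, a / tot, NA)
  flag <- ifelse(ok & tot != 0, "ok", "undefined")

  valid <- flag == "ok"
  std <- rep(NA_real_, length(theta))
  if (sum(valid) >= 2)
    std[valid] <- (theta[valid] - mean(theta[valid])) /
      stats::sd(theta[valid])
  res <- score_table(g$snps, "fst", theta, std, flag = flag)
  attr(res, "mean_fst") <- sum(a[valid & !is.na(tot)]) /
    sum(tot[valid & !is.na(tot)])
  attr(res, "components") <- data.frame(a = a, b = b, c = cc)
  res
}

#' Average FST across SNPs
#'
#' Ratio-of-sums Weir-Cockerham average over valid SNPs.
#' @inheritParams wc_fst
#' @return scalar mean FST.
#' @export
mean_fst <- function(g, pop_a, pop_b) {
  attr(wc_fst(g, pop_a, pop_b), "mean_fst")
}
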