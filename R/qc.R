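# Marker-level quality control: call rate, minor allele frequency and the
# Hardy-Weinberg exact test, with strict "less than" removal semantics.

#' QC thresholds
#'
#' A SNP is removed when call rate < `min_call_rate`, MAF < `min_maf` or the
#' Hardy-Weinberg exact p-value < `min_hwe_p` (strict inequalities). The
#' defaults are the common chip-QC settings: 90% call rate, 5% MAF, HWE
#' p 1e-6.
#'
#' @param min_call_rate,min_maf,min_hwe_p thresholds, each in (0, 1].
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.05,
                          min_hwe_p = 1e-6) {
  v <- c(min_call_rate, min_maf, min_hwe_p)
  if (any(v <= 0) || any(v > 1)) stop("thresholds must lie in (0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p), class = "qc_thresholds")
}

#' Per-SNP call rate
#' @param g [genotype_matrix()]
#' @param snp_index SNP column index (default: all SNPs).
#' @return fraction of non-missing calls per SNP.
#' @export
call_rate <- function(g, snp_index = seq_len(ncol(g$calls))) {
  if (nrow(g$calls) < 1) stop("call_rate requires at least one sample")
  colMeans(!is.na(g$calls[, snp_index, drop = FALSE]))
}

#' Per-SNP minor allele frequency
#'
#' `min(p, 1-p)` of the alternate-allele frequency among non-missing calls.
#' Errors if a requested SNP has no non-missing call (such a SNP must
#' already fail the call-rate filter).
#'
#' @inheritParams call_rate
#' @return MAF per SNP.
#' @export
maf <- function(g, snp_index = seq_len(ncol(g$calls))) {
  m <- g$calls[, snp_index, drop = FALSE]
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0))
    stop("MAF undefined: SNP(s) with all calls missing: ",
         paste(g$snps$id[snp_index][n_obs == 0], collapse = ", "))
  p <- colSums(m, na.rm = TRUE) / (2 * n_obs)
  pmin(p, 1 - p)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts (same parity,
#' same allele totals) whose conditional probability does not exceed that of
#' the observed configuration. Probabilities follow the recurrence
#' `P(nAa+2)/P(nAa) = (nA - nAa)(na - nAa) / ((nAa + 2)(nAa + 1))` where
#' nA/na are the minor/major allele counts, anchored at the distribution
#' mode -- the numerically stable form used by PLINK-style implementations.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return exact p-value in `[0, 1]`.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("HWE test undefined with zero samples")
  n_a1 <- 2 * n_AA + n_Aa                 # allele A count
  rare <- min(n_a1, 2 * n - n_a1)         # minor allele count
  obs_het <- n_Aa
  hets <- seq(rare %% 2, rare, by = 2)    # feasible het counts, same parity
  if (length(hets) == 1) return(1.0)

  # unnormalized probabilities via the two-step recurrence from the mode
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[mid_i] <- 1.0
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      h <- hets[i]
      probs[i + 1] <- probs[i] *
        (rare - h) * (2 * n - rare - h) / ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- hets[i]
      probs[i - 1] <- probs[i] *
        h * (h - 1) / ((rare - h + 2) * (2 * n - rare - h + 2))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(obs_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

hwe_p_all <- function(g, snp_index = seq_len(ncol(g$calls))) {
  vapply(snp_index, function(j) {
    c_j <- g$calls[, j]
    c_j <- c_j[!is.na(c_j)]
    if (!length(c_j)) return(NA_real_)
    hwe_exact_p(sum(c_j == 0), sum(c_j == 1), sum(c_j == 2))
  }, numeric(1))
}

#' Apply marker-level QC filters
#'
#' Evaluates the three filters on the full (pooled) sample set and removes
#' SNPs failing any of them; strict "less than" semantics per
#' [qc_thresholds()]. Idempotent: re-running on the result removes nothing.
#'
#' @param g [genotype_matrix()]
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered matrix) and `report` (class
#'   `qc_report`: totals and per-SNP fail reasons).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  n_snp <- ncol(g$calls)
  cr <- call_rate(g)
  fail_cr <- cr < thresholds$min_call_rate
  has_obs <- colSums(!is.na(g$calls)) > 0
  mafs <- rep(NA_real_, n_snp)
  mafs[has_obs] <- maf(g, which(has_obs))
  fail_maf <- !is.na(mafs) & mafs < thresholds$min_maf
  fail_maf[!has_obs] <- FALSE             # uncallable: call-rate fail covers it
  hwe <- hwe_p_all(g)
  fail_hwe <- !is.na(hwe) & hwe < thresholds$min_hwe_p

  fail_any <- fail_cr | fail_maf | fail_hwe
  keep <- which(!fail_any)
  reasons <- data.frame(id = g$snps$id, call_rate = cr, maf = mafs,
                        hwe_p = hwe, fail_callrate = fail_cr,
                        fail_maf = fail_maf, fail_hwe = fail_hwe,
                        stringsAsFactors = FALSE)
  report <- structure(list(
    n_input = n_snp, n_fail_callrate = sum(fail_cr),
    n_fail_maf = sum(fail_maf), n_fail_hwe = sum(fail_hwe),
    n_retained = length(keep), thresholds = thresholds,
    snp_report = reasons), class = "qc_report")

  g2 <- genotype_matrix(g$snps[keep, , drop = FALSE], g$samples, g$pops,
                        g$calls[, keep, drop = FALSE],
                        a1 = if (!is.null(g$a1)) g$a1[, keep, drop = FALSE],
                        a2 = if (!is.null(g$a2)) g$a2[, keep, drop = FALSE],
                        phased = if (!is.null(g$phased))
                          g$phased[, keep, drop = FALSE])
  list(genotypes = g2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<qc_report> %d SNPs in; removed %d call-rate, %d MAF, %d HWE ",
    "(overlaps possible); %d retained\n"),
    x$n_input, x$n_fail_callrate, x$n_fail_maf, x$n_fail_hwe, x$n_retained))
  invisible(x)
}
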