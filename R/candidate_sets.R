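# Candidate regions and gene sets: top-percentile selection on score
# tables, SNP-to-gene annotation, UpSet-style intersections and the
# candidate gene set (CGS).

#' Select the most extreme fraction of a score table
#'
#' Returns the `ceiling(fraction * n_valid)` SNPs most extreme in the
#' stated tail of the standardized score (`abs(std)` for `two_sided`),
#' including all ties at the boundary.
#'
#' @param scores a [score_table()].
#' @param fraction fraction in (0, 1), e.g. 0.01.
#' @param tail `"upper"`, `"lower"` or `"two_sided"`.
#' @return integer vector of row indices into `scores`.
#' @export
select_top <- function(scores, fraction,
                       tail = c("two_sided", "upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(fraction > 0, fraction < 1)
  valid <- which(scores$flag == "ok" & !is.na(scores$std))
  if (!length(valid)) stop("no valid standardized scores to select from")
  v <- switch(tail, upper = scores$std[valid], lower = -scores$std[valid],
              two_sided = abs(scores$std[valid]))
  k <- ceiling(fraction * length(valid) - 1e-9)  # guard 0.07*100 = 7.0000..01
  thr <- sort(v, decreasing = TRUE)[k]
  valid[v >= thr]
}

#' Flag per-SNP significance at the 1% and 5% thresholds
#' @param scores a [score_table()].
#' @param tail passed to [select_top()].
#' @return the table with `sig_1pct`/`sig_5pct` filled.
#' @export
flag_significance <- function(scores, tail = "two_sided") {
  scores$sig_1pct <- seq_len(nrow(scores)) %in%
    select_top(scores, 0.01, tail)
  scores$sig_5pct <- seq_len(nrow(scores)) %in%
    select_top(scores, 0.05, tail)
  scores
}

#' Annotate selected SNPs with overlapping genes
#'
#' Returns the genes whose `[start - flank, end + flank]` interval
#' (1-based, inclusive at both boundaries) contains at least one selected
#' SNP position. The overlap search uses an interval tree
#' ([IRanges][IRanges::findOverlaps]), not an all-pairs scan. Chromosome
#' names present in the SNPs but absent from the annotation (or vice versa)
#' trigger a warning with counts.
#'
#' @param snp_set data.frame with `chrom` and `pos` columns (e.g. rows of a
#'   score table selected by [select_top()]).
#' @param annotation a [gene_annotation()].
#' @param flank_bp symmetric flank in bp (default 50000).
#' @param name,statistic,comparison,threshold provenance for the result.
#' @return a [gene_set()].
#' @export
annotate_genes <- function(snp_set, annotation, flank_bp = 50000,
                           name = "candidates", statistic = NA_character_,
                           comparison = NA_character_,
                           threshold = NA_real_) {
  only_snp <- setdiff(unique(snp_set$chrom), unique(annotation$chrom))
  if (length(only_snp))
    warning(sum(snp_set$chrom %in% only_snp), " SNP(s) on ",
            length(only_snp),
            " chromosome(s) absent from the annotation: ",
            paste(only_snp, collapse = ", "))
  lv <- union(unique(snp_set$chrom), unique(annotation$chrom))
  snp_gr <- GenomicRanges::GRanges(
    factor(snp_set$chrom, lv), IRanges::IRanges(snp_set$pos, snp_set$pos))
  gene_gr <- GenomicRanges::GRanges(
    factor(annotation$chrom, lv),
    IRanges::IRanges(pmax(1, annotation$start - flank_bp),
                     annotation$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(gene_gr, snp_gr)
  ids <- annotation$gene_id[unique(S4Vectors::queryHits(hits))]
  gene_set(name, ids, statistic = statistic, comparison = comparison,
           threshold = threshold)
}

#' UpSet-style intersection matrix of gene sets
#'
#' Computes the size of every *exclusive* membership combination (each gene
#' counted once, in the combination of exactly the sets containing it), so
#' the sizes sum to the size of the union.
#'
#' @param sets list of [gene_set()] objects.
#' @return data.frame of class `upset_matrix`: one logical column per set
#'   plus `size`; `attr(,"set_names")` and `attr(,"union_size")`.
#' @export
intersect_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("gene set names must be unique")
  univ <- sort(unique(unlist(lapply(sets, function(s) s$gene_ids))))
  member <- vapply(sets, function(s) univ %in% s$gene_ids,
                   logical(length(univ)))
  member <- matrix(member, nrow = length(univ),
                   dimnames = list(univ, nm))
  key <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  combos <- unique(key)
  rows <- lapply(combos, function(k) {
    flags <- as.logical(as.integer(strsplit(k, "")[[1]]))
    c(as.list(flags), list(size = sum(key == k)))
  })
  out <- do.call(rbind.data.frame, rows)
  names(out) <- c(nm, "size")
  attr(out, "set_names") <- nm
  attr(out, "union_size") <- length(univ)
  class(out) <- c("upset_matrix", "data.frame")
  out
}

#' Build the candidate gene set (CGS)
#'
#' Combines per-test gene sets by set algebra: `"union"` (default; the
#' pooled candidate list across tests at one threshold) or
#' `"intersection"` (the genes every test agrees on -- the construction
#' behind an N-way overlap at a relaxed threshold).
#'
#' @param sets list of [gene_set()].
#' @param rule `"union"` or `"intersection"`.
#' @param name name for the result.
#' @return a [gene_set()].
#' @export
cgs <- function(sets, rule = c("union", "intersection"), name = "CGS") {
  rule <- match.arg(rule)
  stopifnot(length(sets) >= 1)
  ids <- lapply(sets, function(s) s$gene_ids)
  out <- if (rule == "union") Reduce(union, ids) else Reduce(intersect, ids)
  thr <- unique(vapply(sets, function(s) s$provenance$threshold, numeric(1)))
  gene_set(name, out,
           statistic = paste(vapply(sets, function(s)
             s$provenance$statistic, character(1)), collapse = "+"),
           comparison = rule,
           threshold = if (length(thr) == 1) thr else NA_real_)
}
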