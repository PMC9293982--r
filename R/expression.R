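# Expression arm: FPKM, the least-squares stage t-statistic, top-7%
# stage-specific expression gene sets (SEGS), the CGS-SEGS association and
# delta-delta-Ct arithmetic.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = 1e6 * C / (N * L / 1e3)`: `C` fragments uniquely assigned to the
#' gene, `N` total uniquely mapped fragments in the sample, `L` coding
#' length in bp. Vectorized over its arguments.
#'
#' @param C fragment count(s), >= 0.
#' @param N total mapped fragments, > 0.
#' @param L gene length in bp, > 0.
#' @return FPKM value(s).
#' @export
fpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("total fragment count N must be positive")
  if (any(L <= 0)) stop("gene length L must be positive")
  if (any(C < 0)) stop("fragment count C must be non-negative")
  1e6 * C / (N * L / 1e3)
}

#' FPKM matrix from counts and gene lengths
#'
#' @param counts integer matrix genes x samples.
#' @param lengths gene lengths in bp (one per row of `counts`).
#' @param totals per-sample totals `N`; defaults to `colSums(counts)`.
#' @param stage_of_sample optional stage labels to attach.
#' @return [expression_matrix()] if stages given, else a plain matrix.
#' @export
fpkm_matrix <- function(counts, lengths, totals = colSums(counts),
                        stage_of_sample = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts),
            length(totals) == ncol(counts))
  vals <- fpkm(counts, matrix(rep(totals, each = nrow(counts)),
                              nrow = nrow(counts)),
               matrix(lengths, nrow(counts), ncol(counts)))
  if (is.null(stage_of_sample)) return(vals)
  expression_matrix(vals, rownames(counts), colnames(counts),
                    stage_of_sample)
}

# t for one response vector given the focal-group indicator; implements the
# design X = [indicator, intercept] with MSE = RSS/N (biased, by contract).
tstat_core <- function(y, ind) {
  n <- length(y)
  n1 <- sum(ind)
  if (n1 == 0 || n1 == n) stop("focal group must be a strict, non-empty subset")
  m1 <- mean(y[ind == 1])
  m0 <- mean(y[ind == 0])
  beta <- m1 - m0                          # coefficient [0]
  fit <- ifelse(ind == 1, m1, m0)
  rss <- sum((y - fit)^2)
  mse <- rss / n
  xx_inv_00 <- 1 / n1 + 1 / (n - n1)       # [(X'X)^-1][0,0]
  if (rss == 0) {
    if (beta == 0) return(list(t = 0, flag = "degenerate"))
    return(list(t = sign(beta) * Inf, flag = "zero_residual"))
  }
  list(t = beta / sqrt(mse * xx_inv_00), flag = "ok")
}

#' Least-squares t-statistic for stage-specific expression
#'
#' Fits `Y = X beta` with `X = [focal-stage indicator, intercept]` by least
#' squares and returns `t = beta[0] / sqrt(MSE * [(X'X)^-1][0,0])` with
#' `MSE = RSS / N` -- note the biased divisor `N`, not `N - 2`, which
#' shrinks the MSE, so on a two-group design this equals the classic pooled
#' two-sample t inflated by `sqrt(N/(N-2))`. Degenerate fits (zero residual
#' variance) return 0
#' with flag `"degenerate"` when the group means also coincide, otherwise a
#' signed infinity with flag `"zero_residual"`.
#'
#' @param expr [expression_matrix()]
#' @param gene gene id or row index.
#' @param stage focal stage label.
#' @return list with `t` and `flag`.
#' @export
stage_tstat <- function(expr, gene, stage) {
  ind <- as.integer(expr$stage_of_sample == stage)
  y <- expr$values[gene, ]
  tstat_core(as.numeric(y), ind)
}

# vectorized across genes
stage_tstats <- function(expr, stage) {
  ind <- expr$stage_of_sample == stage
  n <- ncol(expr$values)
  n1 <- sum(ind)
  if (n1 == 0 || n1 == n) stop("focal group must be a strict, non-empty subset")
  m1 <- rowMeans(expr$values[, ind, drop = FALSE])
  m0 <- rowMeans(expr$values[, !ind, drop = FALSE])
  rss <- rowSums((expr$values[, ind, drop = FALSE] - m1)^2) +
    rowSums((expr$values[, !ind, drop = FALSE] - m0)^2)
  beta <- m1 - m0
  denom <- sqrt((rss / n) * (1 / n1 + 1 / (n - n1)))
  t <- ifelse(rss > 0, beta / denom,
              ifelse(beta == 0, 0, sign(beta) * Inf))
  stats::setNames(t, expr$gene_ids)
}

#' Build stage-specific expression gene sets (SEGS)
#'
#' For each stage (or, with `by = "sample"`, each single sample treated as
#' its own focal group), genes are ranked by descending t-statistic
#' (up-regulation in the focal group first) and the top
#' `ceiling(segs_fraction * n_genes)` form that stage's SEGS; boundary ties
#' are all included.
#'
#' @param expr [expression_matrix()]
#' @param segs_fraction fraction of genes per set (default 0.07).
#' @param by `"stage"` (default; replicate groups) or `"sample"`
#'   (leave-one-in per-sample mode).
#' @return list of class `segs_result`: `t` (genes x groups), `rank`,
#'   `membership` (logical), `segs` (list of gene-id vectors),
#'   `segs_fraction`.
#' @export
build_segs <- function(expr, segs_fraction = 0.07,
                       by = c("stage", "sample")) {
  by <- match.arg(by)
  groups <- if (by == "stage") unique(expr$stage_of_sample) else
    expr$sample_ids
  if (length(groups) < 2)
    stop("need at least two groups to contrast")
  tmat <- vapply(groups, function(gp) {
    ind_lab <- if (by == "stage") expr$stage_of_sample else expr$sample_ids
    e2 <- expr
    e2$stage_of_sample <- ind_lab
    stage_tstats(e2, gp)
  }, numeric(length(expr$gene_ids)))
  n_genes <- length(expr$gene_ids)
  k <- ceiling(segs_fraction * n_genes - 1e-9)
  membership <- matrix(FALSE, n_genes, length(groups),
                       dimnames = list(expr$gene_ids, groups))
  ranks <- membership
  storage.mode(ranks) <- "integer"
  segs <- list()
  for (gp in groups) {
    tv <- tmat[, gp]
    ranks[, gp] <- rank(-tv, ties.method = "min")
    thr <- sort(tv, decreasing = TRUE)[k]
    membership[, gp] <- tv >= thr
    segs[[gp]] <- expr$gene_ids[membership[, gp]]
  }
  structure(list(t = tmat, rank = ranks, membership = membership,
                 segs = segs, segs_fraction = segs_fraction),
            class = "segs_result")
}

#' Associate sweep candidates with stage-specific expression
#'
#' Intersects the candidate gene set with each stage's SEGS and reports the
#' per-stage contribution `|CGS intersect SEGS_stage| / |union over stages
#' of the intersections|` (0 everywhere when that union is empty).
#'
#' @param cgs_set a [gene_set()] (the CGS); must be non-empty.
#' @param segs a [build_segs()] result.
#' @return list of class `association_result`: `intersections` (per-stage
#'   gene-id lists), `contribution` (named fractions), `union_size`.
#' @export
associate <- function(cgs_set, segs) {
  if (!length(cgs_set$gene_ids)) stop("candidate gene set is empty")
  inter <- lapply(segs$segs, function(ids)
    sort(intersect(cgs_set$gene_ids, ids)))
  u <- sort(unique(unlist(inter)))
  contribution <- vapply(inter, function(x)
    if (length(u)) length(x) / length(u) else 0, numeric(1))
  structure(list(intersections = inter, contribution = contribution,
                 union_size = length(u)), class = "association_result")
}

#' Relative expression by the 2^-ddCt method
#'
#' `2 ^ -((ct_target - ct_reference) -
#'        (ct_target_calibrator - ct_reference_calibrator))`.
#'
#' @param ct_target,ct_reference Ct of target and reference gene in the
#'   sample of interest.
#' @param ct_target_calibrator,ct_reference_calibrator same pair in the
#'   calibrator sample.
#' @return fold change.
#' @export
ddct <- function(ct_target, ct_reference, ct_target_calibrator,
                 ct_reference_calibrator) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference),
            is.finite(ct_target_calibrator),
            is.finite(ct_reference_calibrator))
  2^-((ct_target - ct_reference) -
        (ct_target_calibrator - ct_reference_calibrator))
}
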