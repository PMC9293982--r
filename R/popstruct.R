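# Population structure: Patterson-scaled PCA, p-distance matrices,
# Saitou-Nei neighbor joining, LD (haplotype and composite r2), sliding
# window LD pruning and LD decay curves.

#' Principal component analysis of genotypes
#'
#' Missing calls are mean-imputed per SNP; each SNP column is centered by
#' `2*p` and scaled by `sqrt(2*p*(1-p))` (Patterson convention) with `p` the
#' alternate-allele frequency; scores are the projections of samples onto
#' the top eigenvectors of the sample covariance matrix. Monomorphic SNPs
#' carry no information and are dropped with a message.
#'
#' @param g [genotype_matrix()]
#' @param n_components number of components (<= min(samples - 1, SNPs)).
#' @return list of class `pca_result`: `coords` (samples x components),
#'   `eigenvalues`, `varexp`.
#' @export
pca <- function(g, n_components = 2) {
  m <- g$calls
  p <- colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    message("pca: dropping ", sum(!poly), " monomorphic SNP(s)")
    m <- m[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (n_components > min(nrow(m) - 1, ncol(m)))
    stop("n_components exceeds min(samples - 1, snps)")
  x <- sweep(m, 2, 2 * p)
  x[is.na(x)] <- 0                         # mean imputation == centered zero
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(x, nu = n_components, nv = 0)
  eig <- sv$d^2 / (nrow(m) - 1)
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(coords) <- list(g$samples, paste0("PC", seq_len(n_components)))
  structure(list(coords = coords,
                 eigenvalues = eig[seq_len(n_components)],
                 varexp = (eig / sum(eig))[seq_len(n_components)]),
            class = "pca_result")
}

#' Pairwise p-distance
#'
#' Mean over co-observed SNPs of `|calls_i - calls_j| / 2`: the average
#' allele difference between two individuals, in `[0, 1]`. Pairs use
#' pairwise deletion of missing data.
#'
#' @param g [genotype_matrix()]
#' @param i,j sample indices or names.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(g, i, j) {
  ci <- g$calls[i, ]
  cj <- g$calls[j, ]
  ok <- !is.na(ci) & !is.na(cj)
  if (!any(ok))
    stop("no co-observed SNP between samples ", i, " and ", j)
  mean(abs(ci[ok] - cj[ok])) / 2
}

#' Full p-distance matrix
#' @param g [genotype_matrix()]
#' @return list of class `distance_matrix`: `labels`, `d` (symmetric,
#'   zero diagonal).
#' @export
p_distance_matrix <- function(g) {
  n <- length(g$samples)
  d <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- p_distance(g, i, j)
  structure(list(labels = g$samples, d = d), class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: iteratively joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` with `R_i = sum_k d(i,k)`, assigning
#' branch lengths `l_i = d(i,j)/2 + (R_i - R_j)/(2(n-2))`. Negative branch
#' lengths are clamped to 0 with the deficit moved to the sibling branch, so
#' `l_i + l_j = d(i,j)` is preserved. The result is the unrooted NJ tree as
#' an ape-compatible `phylo` object (the final three lineages attach to one
#' internal node).
#'
#' @param dm a [p_distance_matrix()] result, or a plain symmetric matrix
#'   with dimnames.
#' @return an object of class `phylo`.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  labels <- if (inherits(dm, "distance_matrix")) dm$labels else rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) stop("neighbor joining requires at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")

  n_tip <- n
  next_node <- n_tip + 2L                 # n_tip+1 reserved for the root
  nodes <- seq_len(n_tip)                 # active node ids
  edges <- matrix(0L, 0, 2)
  elen <- numeric(0)

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (length(nodes) > 3) {
    m <- length(nodes)
    R <- rowSums(d)
    q <- (m - 2) * d - outer(R, R, "+")
    diag(q) <- Inf
    ij <- arrayInd(which.min(q), dim(q))
    i <- min(ij); j <- max(ij)
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    l <- clamp_pair(li, lj)
    new_id <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, nodes[i]), c(new_id, nodes[j]))
    elen <- c(elen, l)
    d_new <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    nodes <- c(nodes[keep], new_id)
  }

  # resolve the last three lineages around the root via the three-point rule
  root <- n_tip + 1L
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  for (k in 1:3) {
    edges <- rbind(edges, c(root, nodes[k]))
    elen <- c(elen, max(c(la, lb, lc)[k], 0))
  }

  # renumber internal nodes so the root is n_tip+1 and children follow
  internal <- sort(unique(edges[edges > n_tip]))
  remap <- stats::setNames(seq_along(internal) + n_tip,
                           as.character(internal))
  remap[as.character(root)] <- n_tip + 1L
  others <- setdiff(internal, root)
  if (length(others))
    remap[as.character(others)] <- n_tip + 1L + seq_along(others)
  big <- edges > n_tip
  edges[big] <- remap[as.character(edges[big])]

  tree <- list(edge = edges, edge.length = elen, tip.label = labels,
               Nnode = length(internal))
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  tree
}

hap_freqs <- function(col) colMeans(col)

#' Pairwise linkage disequilibrium r-squared
#'
#' Haplotype mode computes `r2 = D^2 / (pA pa pB pb)` from phased haplotype
#' frequencies; composite mode is the squared Pearson correlation of the
#' genotype dosages (the unphased fallback used by chip pipelines).
#'
#' @param x a [haplotype_matrix()] (haplotype mode) or [genotype_matrix()]
#'   (composite mode).
#' @param snp_a,snp_b SNP column indices.
#' @param mode `"haplotype"` or `"composite"`; defaults to whatever `x`
#'   supports.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(x, snp_a, snp_b,
                  mode = if (inherits(x, "haplotype_matrix")) "haplotype"
                         else "composite") {
  mode <- match.arg(mode, c("haplotype", "composite"))
  if (mode == "haplotype") {
    stopifnot(inherits(x, "haplotype_matrix"))
    a <- x$haps[, snp_a]; b <- x$haps[, snp_b]
    pa <- mean(a); pb <- mean(b)
    if (pa %in% c(0, 1) || pb %in% c(0, 1))
      stop("r2 undefined for a monomorphic SNP")
    D <- mean(a * b) - pa * pb
    (D * D) / (pa * (1 - pa) * pb * (1 - pb))
  } else {
    m <- if (inherits(x, "genotype_matrix")) x$calls else x$haps
    a <- m[, snp_a]; b <- m[, snp_b]
    ok <- !is.na(a) & !is.na(b)
    if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0)
      stop("r2 undefined for a monomorphic SNP")
    stats::cor(a[ok], b[ok])^2
  }
}

# Vectorized composite r2 matrix among a set of SNP columns (mean-imputed
# missing); monomorphic columns yield NA rows/cols.
r2_matrix <- function(calls) {
  m <- calls
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  r * r
}

#' Sliding-window LD pruning
#'
#' PLINK `--indep-pairwise`-style pruning: within each window of
#' `window_snps` consecutive SNPs (advancing by `step_snps`), while any
#' retained pair has `r2 > r2_max`, one SNP of the currently worst pair is
#' removed -- the SNP with the *lower* MAF (equal MAFs: the later-positioned
#' SNP). Composite (genotype dosage) r-squared is used, matching PLINK.
#'
#' @param g [genotype_matrix()]
#' @param window_snps,step_snps window size and step in SNPs.
#' @param r2_max threshold above which a pair is considered in LD.
#' @return integer vector of retained SNP column indices.
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 10, r2_max = 0.1) {
  n_snp <- ncol(g$calls)
  n_obs <- colSums(!is.na(g$calls))
  p <- ifelse(n_obs > 0, colSums(g$calls, na.rm = TRUE) / (2 * n_obs), 0)
  mafs <- pmin(p, 1 - p)
  removed <- rep(FALSE, n_snp)
  for (ch in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == ch)
    starts <- seq(1, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      if (length(win) < 2) next
      repeat {
        act <- win[!removed[win]]
        if (length(act) < 2) break
        r2 <- r2_matrix(g$calls[, act, drop = FALSE])
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        if (max(r2) <= r2_max) break
        worst <- arrayInd(which.max(r2), dim(r2))
        a <- act[worst[1]]; b <- act[worst[2]]
        drop_snp <- if (mafs[a] < mafs[b]) a
                    else if (mafs[b] < mafs[a]) b
                    else max(a, b)         # equal MAF: later position goes
        removed[drop_snp] <- TRUE
      }
    }
  }
  which(!removed)
}

#' LD decay curve
#'
#' Mean r-squared of all intra-chromosome SNP pairs, binned by physical
#' distance, computed separately per population. Haplotype input uses
#' haplotype r2; genotype input uses composite r2.
#'
#' @param x [haplotype_matrix()] or [genotype_matrix()].
#' @param max_dist_bp maximum pair distance (default 500 kb).
#' @param bin_width_bp bin width (default 1 kb).
#' @return data.frame of class `ld_decay_curve`: `pop`, `bin_lo`, `bin_hi`,
#'   `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(x, max_dist_bp = 5e5, bin_width_bp = 1e3) {
  is_h <- inherits(x, "haplotype_matrix")
  m_all <- if (is_h) x$haps else x$calls
  pops_of_rows <- x$pops
  snps <- x$snps
  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  out <- list()
  for (pop in unique(pops_of_rows)) {
    m <- m_all[pops_of_rows == pop, , drop = FALSE]
    sums <- numeric(n_bins); cnts <- integer(n_bins)
    cnts_ok <- integer(n_bins)
    for (ch in unique(snps$chrom)) {
      idx <- which(snps$chrom == ch)
      if (length(idx) < 2) next
      pos <- snps$pos[idx]
      mm <- m[, idx, drop = FALSE]
      if (anyNA(mm)) {
        mu <- colMeans(mm, na.rm = TRUE)
        nai <- which(is.na(mm), arr.ind = TRUE)
        mm[nai] <- mu[nai[, 2]]
      }
      mu <- colMeans(mm)
      sd_ <- sqrt(colMeans(mm^2) - mu^2)
      nr <- nrow(mm)
      for (k in seq_len(length(idx) - 1)) {
        dist <- pos[(1 + k):length(idx)] - pos[seq_len(length(idx) - k)]
        keep <- which(dist <= max_dist_bp)
        if (!length(keep)) {
          if (min(dist) > max_dist_bp) break else next
        }
        i1 <- keep; i2 <- keep + k
        cross <- colMeans(mm[, i1, drop = FALSE] * mm[, i2, drop = FALSE])
        denom <- sd_[i1] * sd_[i2]
        r <- ifelse(denom > 0, (cross - mu[i1] * mu[i2]) / denom, NA)
        r2 <- r * r
        ok <- !is.na(r2)
        b_all <- pmin(n_bins, floor(dist[keep] / bin_width_bp) + 1L)
        tab_all <- table(b_all)
        cnts[as.integer(names(tab_all))] <-
          cnts[as.integer(names(tab_all))] + as.integer(tab_all)
        if (!any(ok)) next
        b <- b_all[ok]
        agg <- tapply(r2[ok], b, sum)
        nb <- as.integer(names(agg))
        sums[nb] <- sums[nb] + agg
        cnts_ok[nb] <- cnts_ok[nb] + as.integer(table(b))
      }
    }
    out[[pop]] <- data.frame(
      pop = pop, bin_lo = (seq_len(n_bins) - 1) * bin_width_bp,
      bin_hi = seq_len(n_bins) * bin_width_bp,
      mean_r2 = ifelse(cnts_ok > 0, sums / cnts_ok, NA),
      n_pairs = cnts, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ld_decay_curve", "data.frame")
  res
}
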