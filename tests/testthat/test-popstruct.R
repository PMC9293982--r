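test_that("pca separates degenerate clusters and honours the eigen identity", {
  v1 <- c(0L, 2L, 0L, 2L, 1L, 0L)
  v2 <- c(2L, 0L, 2L, 0L, 1L, 2L)
  calls <- rbind(v1, v1, v1, v2, v2, v2)
  g <- make_g(calls)
  p <- pca(g, 2)
  expect_equal(stats::sd(p$coords[1:3, 1]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(p$coords[4:6, 1]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(p$coords[1:3, 1]) - mean(p$coords[4:6, 1])), 1)

  set.seed(3)
  calls <- matrix(sample(0:2, 15 * 60, replace = TRUE), 15)
  g2 <- make_g(calls)
  p2 <- pca(g2, 5)
  expect_equal(unname(stats::cov(p2$coords)),
               diag(p2$eigenvalues), tolerance = 1e-9)
  expect_true(all(diff(p2$varexp) <= 1e-12) && all(p2$varexp >= 0))
  expect_error(pca(g2, 15), "n_components")
})

test_that("pca recovers simulated population labels (silhouette > 0.5)", {
  cfg <- sim_config(seed = 21, n_pops = 3, n_samples_per_pop = 15,
                    n_snps = 1500)
  g <- haps_to_genotypes(simulate_haplotypes(cfg)$haplotypes)
  p <- suppressMessages(pca(g, 2))
  expect_gt(mean_silhouette(p$coords, g$pops), 0.5)
})

test_that("p_distance matches hand arithmetic and stays in [0,1]", {
  g <- make_g(rbind(c(0L, 2L), c(2L, 2L)))
  expect_equal(p_distance(g, 1, 2), 0.5)   # (|0-2|/2 + |2-2|/2) / 2
  expect_equal(p_distance(g, 1, 1), 0)
  set.seed(4)
  calls <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10)
  ok <- colSums(!is.na(calls)) > 0
  g2 <- make_g(calls[, ok, drop = FALSE])
  dm <- p_distance_matrix(g2)
  expect_true(all(dm$d >= 0 & dm$d <= 1))
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
})

test_that("neighbor_joining solves 3 taxa exactly and rejects asymmetry", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  # three-point equations: la = (3+4-5)/2 = 1, lb = 2, lc = 3
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
  d2 <- d; d2[1, 2] <- 99
  expect_error(neighbor_joining(d2), "symmetric")
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("neighbor_joining recovers additive matrices exactly", {
  skip_if_not_installed("ape")
  set.seed(5)
  for (rep in 1:20) {
    n_taxa <- sample(4:8, 1)
    ref <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
    dd <- stats::cophenetic(ref)
    tr <- neighbor_joining(dd)
    dd2 <- stats::cophenetic(tr)[rownames(dd), colnames(dd)]
    expect_equal(dd2, dd, tolerance = 1e-9)
  }
})

test_that("NJ on an ultrametric matrix matches single linkage topology", {
  skip_if_not_installed("ape")
  skip_if_not_installed("phangorn")
  set.seed(6)
  for (rep in 1:5) {
    ref <- ape::rcoal(6)
    dd <- stats::cophenetic(ref)
    nj_tr <- neighbor_joining(dd)
    sl <- ape::as.phylo(stats::hclust(stats::as.dist(dd), "single"))
    expect_equal(phangorn::RF.dist(ape::unroot(nj_tr), ape::unroot(sl)), 0)
  }
})

test_that("ld_r2 matches haplotype-frequency arithmetic", {
  # AB=4, ab=4: D = 0.5 - 0.25 = 0.25; r2 = 1
  h <- make_h(cbind(rep(c(1L, 0L), each = 4), rep(c(1L, 0L), each = 4)))
  expect_equal(ld_r2(h, 1, 2), 1.0)
  g <- make_g(rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(1L, 1L)))
  expect_equal(ld_r2(g, 1, 2, mode = "composite"), 1.0)
  expect_error(ld_r2(make_h(cbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 0L, 1L))),
                     1, 2), "monomorphic")
  # independent uniform haplotypes: r2 small at large n
  set.seed(7)
  hb <- make_h(matrix(rbinom(2 * 3000 * 2, 1, 0.5), 6000))
  expect_lt(ld_r2(hb, 1, 2), 0.01)
})

test_that("ld_prune keeps the higher-MAF SNP of a duplicated pair", {
  set.seed(8)
  base <- rbinom(40, 1, 0.3) + rbinom(40, 1, 0.3)
  # SNP2 duplicates SNP1 but with a few genotypes pushed toward fixation
  # (lower MAF); SNP3 independent
  snp2 <- base; snp2[base == 1][1:4] <- 0
  calls <- cbind(base, snp2, sample(0:2, 40, replace = TRUE))
  g <- make_g(matrix(as.integer(calls), 40))
  kept <- ld_prune(g)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)

  # equal-MAF exact duplicate: later position removed
  g2 <- make_g(matrix(as.integer(cbind(base, base)), 40))
  expect_equal(ld_prune(g2), 1L)

  # orthogonal SNPs: nothing removed
  g3 <- make_g(rbind(c(0L, 0L), c(0L, 2L), c(2L, 0L), c(2L, 2L)))
  expect_equal(ld_prune(g3), c(1L, 2L))
})

test_that("pruning contract holds on simulated chromosomes", {
  cfg <- sim_config(seed = 22, n_snps = 400, n_samples_per_pop = 20)
  g <- haps_to_genotypes(simulate_haplotypes(cfg)$haplotypes)
  kept <- ld_prune(g)
  expect_lt(length(kept), 400)
  expect_equal(prune_violations(g, kept), 0L)
  # duplicating every sample does not change the pruned set
  gd <- genotype_matrix(g$snps, c(g$samples, paste0(g$samples, "b")),
                        c(g$pops, g$pops), rbind(g$calls, g$calls))
  expect_equal(ld_prune(gd), kept)
})

test_that("ld_decay bins conserve pairs and decay with distance", {
  h <- make_h(matrix(c(1L, 0L), 4, 1), pos = 500)   # single SNP: no pairs
  expect_equal(sum(ld_decay(h, 1e4, 1e3)$n_pairs), 0)

  cfg <- sim_config(seed = 23, n_snps = 800, n_samples_per_pop = 25,
                    mosaic_segment_len_bp = 3e4)
  h2 <- simulate_haplotypes(cfg)$haplotypes
  dec <- ld_decay(h2, max_dist_bp = 2e5, bin_width_bp = 2e4)
  one <- dec[dec$pop == "POP1", ]
  expect_true(all(one$mean_r2 >= 0 & one$mean_r2 <= 1, na.rm = TRUE))
  pos <- h2$snps$pos
  n_elig <- sum(vapply(seq_along(pos), function(i)
    sum(pos > pos[i] & pos <= pos[i] + 2e5), numeric(1)))
  expect_equal(sum(one$n_pairs), n_elig)
  ok <- !is.na(one$mean_r2)
  expect_lt(stats::cor(seq_len(nrow(one))[ok], one$mean_r2[ok],
                       method = "spearman"), 0)
})
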