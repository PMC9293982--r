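test_that("ehh matches hand enumeration at and beyond the core", {
  # 4 derived carriers split 2/2 at the first right-flanking SNP
  haps <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(1L, 1L, 0L), c(1L, 1L, 1L),
                c(0L, 0L, 0L), c(0L, 1L, 1L))
  h <- make_h(haps)
  cv <- ehh(h, 1, 1)
  expect_equal(cv$points$ehh[cv$points$pos == h$snps$pos[1]], 1)
  expect_equal(cv$points$ehh[cv$points$pos == h$snps$pos[2]],
               (2 * 1 + 2 * 1) / (4 * 3))
  # identical carriers: EHH stays 1 to the chromosome edge
  hid <- make_h(rbind(matrix(1L, 3, 5), matrix(0L, 3, 5)))
  cvid <- ehh(hid, 3, 1)
  expect_true(all(cvid$points$ehh == 1))
  expect_error(ehh(make_h(rbind(c(1L, 1L), c(0L, 0L), c(0L, 1L), c(0L, 0L))),
                   1, 1), "2 carrier")
})

test_that("ehh and ehhs agree with the brute-force enumerator (<=8 haps)", {
  set.seed(31)
  for (rep in 1:40) {
    n_h <- 2 * sample(2:4, 1)
    n_s <- sample(4:10, 1)
    haps <- matrix(rbinom(n_h * n_s, 1, runif(1, 0.3, 0.7)), n_h)
    core <- sample(n_s, 1)
    h <- make_h(haps)
    for (allele in 0:1) {
      if (sum(haps[, core] == allele) < 2) next
      cv <- ehh(h, core, allele, sweep_config(ehh_cutoff = 1e-9))
      for (k in seq_len(nrow(cv$points))) {
        s <- match(cv$points$pos[k], h$snps$pos)
        expect_equal(cv$points$ehh[k], ehh_brute(haps, core, allele, s),
                     tolerance = 1e-12)
      }
    }
    f <- mean(haps[, core])
    if (f > 0 && f < 1) {
      cs <- ehhs(h, core, sweep_config(ehh_cutoff = 1e-9))
      expect_equal(cs$points$ehh[cs$points$pos == h$snps$pos[core]], 1)
      for (k in seq_len(nrow(cs$points))) {
        s <- match(cs$points$pos[k], h$snps$pos)
        expect_equal(cs$points$ehh[k], ehhs_brute(haps, core, s),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("EHH curves decay monotonically outward on simulated panels", {
  cfg <- sim_config(seed = 32, n_snps = 300, n_samples_per_pop = 12)
  h <- simulate_haplotypes(cfg)$haplotypes
  set.seed(32)
  for (core in sample(20:280, 15)) {
    for (allele in 0:1) {
      if (sum(h$haps[, core] == allele) < 2) next
      pts <- ehh(h, core, allele)$points
      ci <- which(pts$pos == h$snps$pos[core])
      expect_true(all(diff(pts$ehh[ci:nrow(pts)]) <= 1e-12))
      expect_true(all(diff(rev(pts$ehh[1:ci])) <= 1e-12))
    }
  }
})

test_that("ihh integrates the trapezoid with cutoff interpolation", {
  # right side: EHH == 1 for 1000 bp (carriers identical over snps 1..2),
  # then 0 at the next SNP 100 bp away; left side empty (core at edge).
  haps <- rbind(c(1L, 1L, 0L), c(1L, 1L, 1L), c(0L, 0L, 0L), c(0L, 1L, 1L))
  h <- make_h(haps, pos = c(1000, 2000, 2100))
  r <- ihh(h, 1, 1)
  # area = 1000 * 1 + 95 * (1 + 0.05) / 2 = 1049.875
  expect_equal(r$area, 1049.875)
  # doubling distances doubles the integral
  h2 <- make_h(haps, pos = c(2000, 4000, 4200))
  expect_equal(ihh(h2, 1, 1)$area, 2 * r$area)
})

test_that("ihh equals a fine-grid trapezoid oracle on piecewise-linear curves", {
  cfg <- sim_config(seed = 33, n_snps = 200, n_samples_per_pop = 10)
  h <- simulate_haplotypes(cfg)$haplotypes
  cut <- 0.05
  set.seed(33)
  cores <- sample(50:150, 5)
  for (core in cores) {
    for (allele in 0:1) {
      if (sum(h$haps[, core] == allele) < 2) next
      r <- ihh(h, core, allele)
      pts <- ehh(h, core, allele)$points
      ci <- which(pts$pos == h$snps$pos[core])
      side_area <- function(px, py) {
        if (length(px) < 2) return(0)
        area <- 0
        for (k in 2:length(px)) {
          if (py[k] >= cut) {
            area <- area + abs(px[k] - px[k - 1]) * (py[k] + py[k - 1]) / 2
          } else {
            frac <- (py[k - 1] - cut) / (py[k - 1] - py[k])
            dx <- abs(px[k] - px[k - 1]) * frac
            area <- area + dx * (py[k - 1] + cut) / 2
            break
          }
        }
        area
      }
      oracle <- side_area(pts$pos[ci:1], pts$ehh[ci:1]) +
        side_area(pts$pos[ci:nrow(pts)], pts$ehh[ci:nrow(pts)])
      expect_equal(r$area, oracle, tolerance = 1e-9)
    }
  }
})

test_that("ihs is zero under mirror symmetry and standardizes per bin", {
  # derived carriers mirror ancestral carriers: iHH_anc == iHH_der
  block <- rbind(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L),
                 c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  haps <- cbind(block[, 1:2], rep(c(0L, 1L), each = 2), block[, 3:4])
  h <- make_h(haps)
  r <- ihh(h, 3, 0)$area
  d <- ihh(h, 3, 1)$area
  expect_equal(r, d)

  cfg <- sim_config(seed = 34, n_snps = 2000, n_samples_per_pop = 30)
  hs <- simulate_haplotypes(cfg)$haplotypes
  st <- ihs(hap_subset(hs, "POP1"))
  ok <- st$flag == "ok"
  expect_gt(sum(ok), 200)
  expect_equal(mean(st$std[ok]), 0, tolerance = 0.15)
  expect_equal(stats::sd(st$std[ok]), 1, tolerance = 0.1)
  # relabeling haplotypes within the population leaves raw scores unchanged
  hp <- hap_subset(hs, "POP1")
  set.seed(1)
  perm <- sample(nrow(hp$haps))
  hp2 <- haplotype_matrix(hp$snps, hp$haps[perm, ],
                          hp$sample_of_haplotype[perm], hp$pops[perm],
                          hp$anc_policy)
  expect_equal(ihs(hp2)$raw, st$raw)
})

test_that("xpehh and rsb obey the identity and antisymmetry contracts", {
  cfg <- sim_config(seed = 35, n_snps = 500, n_samples_per_pop = 15)
  h <- simulate_haplotypes(cfg)$haplotypes
  h1 <- hap_subset(h, "POP1"); h2 <- hap_subset(h, "POP2")
  same <- xpehh(h1, h1)
  expect_true(all(same$raw[same$flag == "ok"] == 0))
  same_rsb <- rsb(h1, h1)
  expect_true(all(same_rsb$raw[same_rsb$flag == "ok"] == 0))

  ab <- xpehh(h1, h2); ba <- xpehh(h2, h1)
  expect_equal(ab$raw, -ba$raw)
  abr <- rsb(h1, h2); bar <- rsb(h2, h1)
  expect_equal(abr$raw, -bar$raw)

  h2_trunc <- hap_subset(h, "POP2")
  h2_trunc$snps <- h2_trunc$snps[1:100, ]
  h2_trunc$haps <- h2_trunc$haps[, 1:100]
  expect_error(xpehh(h1, h2_trunc), "same SNP panel")
})

test_that("ehhs core normalization and rsb median option behave", {
  cfg <- sim_config(seed = 36, n_snps = 300, n_samples_per_pop = 10)
  h <- simulate_haplotypes(cfg)$haplotypes
  for (core in c(50, 150, 250)) {
    pts <- ehhs(h, core)$points
    expect_equal(pts$ehh[pts$pos == h$snps$pos[core]], 1)
  }
  h1 <- hap_subset(h, "POP1"); h2 <- hap_subset(h, "POP2")
  rz <- rsb(h1, h2); rm <- rsb(h1, h2, standardize = "median")
  ok <- rz$flag == "ok"
  expect_equal(stats::median(rm$std[ok]), 0, tolerance = 1e-9)
  expect_equal(rz$raw, rm$raw)
})

test_that("wc_fst hits the fixed-difference and identity limits", {
  calls <- rbind(matrix(0L, 5, 4), matrix(2L, 5, 4))
  g <- make_g(calls, pops = rep(c("A", "B"), each = 5))
  st <- wc_fst(g, "A", "B")
  expect_true(all(st$raw == 1))
  expect_equal(attr(st, "mean_fst"), 1)

  # zero between-population component: all-heterozygote tables give a = 0
  # exactly (theta = 0); generic identical tables give the estimator's
  # small-sample negative bias, which must match the textbook oracle
  ghet <- make_g(matrix(1L, 8, 1), pops = rep(c("A", "B"), each = 4))
  expect_equal(unname(wc_fst(ghet, "A", "B")$raw), 0, tolerance = 1e-12)
  block <- c(0L, 0L, 1L, 1L, 2L)
  g2 <- make_g(matrix(c(block, block), 10, 1),
               pops = rep(c("A", "B"), each = 5))
  expect_equal(unname(wc_fst(g2, "A", "B")$raw),
               wc_oracle(block, block)$theta, tolerance = 1e-12)
  expect_lt(unname(wc_fst(g2, "A", "B")$raw), 0)
  expect_error(wc_fst(g, "A", "missing"), "2 samples")
})

test_that("wc_fst equals the textbook oracle on random small tables", {
  set.seed(37)
  for (rep in 1:100) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    ca <- sample(0:2, na, replace = TRUE)
    cb <- sample(0:2, nb, replace = TRUE)
    g <- make_g(matrix(as.integer(c(ca, cb)), na + nb, 1),
                pops = rep(c("A", "B"), c(na, nb)))
    o <- wc_oracle(ca, cb)
    st <- wc_fst(g, "A", "B")
    if (is.na(o$theta)) {
      expect_equal(st$flag, "undefined")
    } else {
      expect_equal(unname(st$raw), o$theta, tolerance = 1e-12)
    }
  }
})
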