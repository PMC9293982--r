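small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_snps = 300, n_samples_per_pop = 12, ...)
}

test_that("generators are pure functions of the seed", {
  a <- simulate_haplotypes(small_cfg(99))
  b <- simulate_haplotypes(small_cfg(99))
  expect_identical(a$haplotypes$haps, b$haplotypes$haps)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_haplotypes(small_cfg(100))
  expect_false(identical(a$haplotypes$haps, c_$haplotypes$haps))

  qa <- simulate_genotypes_for_qc(small_cfg(7))
  qb <- simulate_genotypes_for_qc(small_cfg(7))
  expect_identical(qa$genotypes$calls, qb$genotypes$calls)

  ea <- simulate_expression(small_cfg(7))
  eb <- simulate_expression(small_cfg(7))
  expect_identical(ea$counts, eb$counts)
})

test_that("carrier_fraction 1 fixes the sweep SNP in the focal population", {
  cfg <- small_cfg(2)
  cfg$sweep_specs <- list(list(pop = 1, pos_bp = 5e6, carrier_fraction = 1))
  sim <- simulate_haplotypes(cfg)
  idx <- sim$truth$sweeps$snp_index
  col <- sim$haplotypes$haps[sim$haplotypes$pops == "POP1", idx]
  expect_equal(length(unique(col)), 1)
  expect_error(sim_config(sweep_specs = list(list(
    pop = 1, pos_bp = 9e99, carrier_fraction = 0.5))), "outside")
})

test_that("neutral FST calibration lands within 0.05 of the target", {
  vals <- vapply(1:3, function(s) {
    cfg <- sim_config(seed = 100 + s, n_snps = 2000, n_samples_per_pop = 30)
    g <- haps_to_genotypes(simulate_haplotypes(cfg)$haplotypes)
    mean_fst(g, "POP1", "POP2")
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.10), 0.05)
})

test_that("QC generator honours its planted-violation contract", {
  sim <- simulate_genotypes_for_qc(small_cfg(3))
  res <- apply_qc(sim$genotypes)
  removed <- setdiff(seq_len(200), match(res$genotypes$snps$id,
                                         sim$genotypes$snps$id))
  expect_setequal(removed, unlist(sim$truth[c("fail_callrate", "fail_maf",
                                              "fail_hwe")]))
  cfg0 <- small_cfg(3)
  cfg0$qc <- list(n_snps = 100, n_callrate = 0, n_maf = 0, n_hwe = 0)
  res0 <- apply_qc(simulate_genotypes_for_qc(cfg0)$genotypes)
  expect_equal(res0$report$n_retained, 100)

  # a planted monomorphic SNP always fails MAF
  cfgm <- small_cfg(4)
  simm <- simulate_genotypes_for_qc(cfgm)
  mono <- which(apply(simm$genotypes$calls, 2,
                      function(x) length(unique(x[!is.na(x)])) == 1))
  expect_true(all(mono %in% simm$truth$fail_maf))
})

test_that("expression counts reproduce the FPKM matrix exactly", {
  sim <- simulate_expression(small_cfg(5))
  again <- fpkm_matrix(sim$counts, unname(sim$lengths))
  expect_equal(unname(again), unname(sim$expression$values))
  # zero noise: within-stage replicates identical
  cfg0 <- small_cfg(5)
  cfg0$expression$noise_cv <- 0
  sim0 <- simulate_expression(cfg0)
  v <- sim0$expression$values
  st <- sim0$expression$stage_of_sample
  for (s in unique(st)) {
    cols <- which(st == s)
    expect_true(all(v[, cols] == v[, cols[1]]))
  }
})

test_that("effect_fold 1 yields chance-level SEGS recovery", {
  cfg <- small_cfg(6)
  cfg$expression$effect_fold <- 1
  sim <- simulate_expression(cfg)
  segs <- build_segs(sim$expression)
  hits <- vapply(unique(sim$truth$de_genes$stage), function(s) {
    planted <- sim$truth$de_genes$gene_id[sim$truth$de_genes$stage == s]
    mean(planted %in% segs$segs[[s]])
  }, numeric(1))
  expect_lt(mean(hits), 0.3)              # ~7% expected at chance
})

test_that("emit_fixture_bundle is byte-stable and round-trips", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_cfg(8)
  cfg$sweep_specs <- list(list(pop = 1, pos_bp = 5e6, carrier_fraction = 0.8))
  f1 <- emit_fixture_bundle(cfg, d1)
  f2 <- emit_fixture_bundle(cfg, d2)
  for (k in names(f1))
    expect_identical(unname(tools::md5sum(f1[[k]])),
                     unname(tools::md5sum(f2[[k]])), info = k)

  sim <- simulate_haplotypes(cfg)
  g <- read_vcf(f1[["vcf"]], utils::read.table(f1[["pop_map"]],
                                               header = TRUE, sep = "\t"))
  expect_identical(g$calls, haps_to_genotypes(sim$haplotypes)$calls)
  h <- to_haplotypes(g, "alt_is_derived")
  expect_identical(unname(h$haps), unname(sim$haplotypes$haps))

  qc_sim <- simulate_genotypes_for_qc(cfg)
  gq <- read_plink(f1[["ped"]], f1[["map"]])
  expect_identical(gq$calls, qc_sim$genotypes$calls)

  ann <- read_gff(f1[["gff"]])
  expect_equal(nrow(ann), ceiling(cfg$n_snps / 10))
})
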