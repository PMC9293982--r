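vcf_lines <- function(body, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body)
}

test_that("read_vcf decodes GT, skips non-SNP records, validates pop_map", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1",
    "chr1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/1\t1|1",
    "chr1\t250\tv3\tCTT\tC\t.\tPASS\t.\tGT\t0/1\t0/0",   # indel: skipped
    "chr1\t300\tv4\tG\tA\t.\tPASS\t.\tGT\t1/1\t./.",
    "chr1\t400\tv5\tT\tA\t.\tPASS\t.\tGT\t0/0\t0/1")), f)
  pm <- data.frame(sample = c("S1", "S2"), pop = c("P1", "P2"))
  expect_message(g <- read_vcf(f, pm), "skipped 1")
  expect_equal(nrow(g$snps), 4)
  expect_equal(g$snps$id, c("v1", "v2", "v4", "v5"))
  expect_equal(unname(g$calls[1, ]), c(0L, 1L, 2L, 0L))
  expect_equal(unname(g$calls[2, ]), c(1L, 2L, NA, 1L))
  expect_equal(g$pops, c("P1", "P2"))
  expect_true(g$phased[2, 1] && !g$phased[1, 1])

  expect_error(read_vcf(f, data.frame(sample = "S1", pop = "P1")),
               "absent from pop_map.*S2")
  expect_error(read_vcf(file.path(tempdir(), "nope.vcf"), pm),
               "cannot read")
})

test_that("VCF round-trips a synthetic panel to an identical object", {
  cfg <- sim_config(seed = 42, n_snps = 500, n_samples_per_pop = 10,
                    n_pops = 2)
  g <- haps_to_genotypes(simulate_haplotypes(cfg)$haplotypes)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f)
  g2 <- read_vcf(f, data.frame(sample = g$samples, pop = g$pops))
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$samples, g$samples)
  expect_identical(g2$snps$pos, g$snps$pos)
  expect_identical(g2$snps$anc, g$snps$anc)
  expect_identical(g2$a1, unname(g$a1) * 1L)
  expect_true(all(g2$phased))
})

test_that("read_plink counts alleles against the first-seen reference", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("FAM1 S1 0 0 0 -9 A A G T", ped)
  writeLines(c("chr1\tm1\t0\t100", "chr1\tm2\t0\t200"), map)
  g <- read_plink(ped, map)
  expect_equal(unname(g$calls[1, ]), c(0L, 1L))
  expect_equal(g$pops, "FAM1")

  writeLines(c("chr1\tm1\t0\t100", "chr1\tm2\t0\t200",
               "chr1\tm3\t0\t300"), map)
  expect_error(read_plink(ped, map), "mismatch")
})

test_that("PLINK round-trip through write/read is a fixed point", {
  cfg <- sim_config(seed = 7, n_samples_per_pop = 15)
  g <- simulate_genotypes_for_qc(cfg)$genotypes
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_plink(g, ped, map)
  g1 <- read_plink(ped, map)
  write_plink(g1, ped, map)
  g2 <- read_plink(ped, map)
  expect_identical(g2$calls, g1$calls)
  expect_identical(g1$samples, g$samples)
  expect_identical(g1$pops, g$pops)
  expect_identical(g1$snps$pos, g$snps$pos)
})

test_that("to_haplotypes polarizes by policy with ref-ward tie-break", {
  # one SNP; genotypes 0|1 and 1|1 -> alleles (0,1,1,1); alt is major
  g <- make_g(rbind(1L, 2L))
  g$a1 <- rbind(0L, 1L); g$a2 <- rbind(1L, 1L)
  g$phased <- matrix(TRUE, 2, 1)
  h <- to_haplotypes(g, "major_allele")
  expect_equal(as.vector(h$haps), c(1L, 0L, 0L, 0L))
  h2 <- to_haplotypes(g, "alt_is_derived")
  expect_equal(as.vector(h2$haps), c(0L, 1L, 1L, 1L))

  # 50/50 tie: ref stays ancestral (no flip)
  gt <- make_g(rbind(1L, 1L))
  gt$a1 <- rbind(0L, 1L); gt$a2 <- rbind(1L, 0L)
  gt$phased <- matrix(TRUE, 2, 1)
  expect_equal(as.vector(to_haplotypes(gt, "major_allele")$haps),
               c(0L, 1L, 1L, 0L))

  gu <- make_g(rbind(1L, 2L))
  expect_error(to_haplotypes(gu), "no phase")
  g$phased[2, 1] <- FALSE
  expect_error(to_haplotypes(g, "major_allele"), "S2")
})

test_that("haplotype expansion preserves allele frequencies and row count", {
  cfg <- sim_config(seed = 5, n_snps = 200, n_samples_per_pop = 8)
  g <- haps_to_genotypes(simulate_haplotypes(cfg)$haplotypes)
  h <- to_haplotypes(g, "major_allele")
  expect_equal(nrow(h$haps), 2 * length(g$samples))
  f_hap <- colMeans(h$haps)
  f_alt <- colMeans(g$calls) / 2
  expect_true(all(abs(f_hap - f_alt) < 1e-12 | abs(f_hap - (1 - f_alt)) < 1e-12))
})

test_that("read_gff keeps gene features only and flags malformed lines", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1",
               "chr1\tsrc\texon\t250\t500\t.\t+\t.\tParent=g1",
               "chr2\tsrc\tgene\t10\t90\t.\t-\t.\tID=g2",
               "chr2\tsrc\texon\t10\t50\t.\t-\t.\tParent=g2",
               "chr2\tsrc\texon\t60\t90\t.\t-\t.\tParent=g2",
               "chr2\tsrc\texon\t60\t90\t.\t-\t.\tParent=g2"), f)
  ann <- read_gff(f)
  expect_equal(ann$gene_id, c("g1", "g2"))
  expect_equal(ann$start, c(100, 10))

  writeLines(c("##gff-version 3", "chr1\tbroken line"), f)
  expect_error(read_gff(f), "line 2")
})

test_that("write_newick handles degenerate and real trees", {
  expect_equal(write_newick("A"), "A;")
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  txt <- write_newick(tr)
  skip_if_not_installed("ape")
  parsed <- ape::read.tree(text = txt)
  expect_setequal(parsed$tip.label, c("a", "b", "c"))
  expect_equal(sum(parsed$edge.length), sum(tr$edge.length), tolerance = 1e-6)
})

test_that("score tables round-trip through TSV", {
  snps <- make_snps(5)
  st <- score_table(snps, "ihs", raw = c(0.1, -0.2, NA, 1.5, 0),
                    std = c(0.5, -1, NA, 2.5, 0.1),
                    freq_der = runif(5), flag = c("ok", "ok", "maf_fail",
                                                  "ok", "ok"))
  st$sig_1pct <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  st$sig_5pct <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(st, f)
  back <- read_score_table(f)
  for (cl in c("chrom", "pos", "id", "stat", "raw", "std", "sig_1pct",
               "sig_5pct"))
    expect_equal(back[[cl]], st[[cl]], info = cl)
})
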