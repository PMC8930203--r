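test_that("read counting respects flags and the strict mapq cutoff", {
  dir <- withr::local_tempdir()
  cfg <- test_genome_config()
  bam <- make_toy_bam(dir)
  cnt <- count_mapped_reads(bam, cfg)
  expect_identical(cnt$per_contig[["chr1"]], 30L)
  expect_identical(cnt$per_contig[["X"]], 8L)
  expect_identical(cnt$per_contig[["Y"]], 2L)
  expect_identical(cnt$total_hq, 40L)
  expect_identical(cnt$total_hq, sum(cnt$per_contig))

  # reads at exactly mapq 30 are excluded (strict inequality)
  boundary <- rbind(toy_reads(),
                    data.frame(contig = "X",
                               start = 5000000L + (1:5) * 1000L,
                               mapq = 30L, length = 100L))
  bam2 <- make_toy_bam(dir, "S2", boundary)
  cnt2 <- count_mapped_reads(bam2, cfg)
  expect_identical(cnt2$per_contig, cnt$per_contig)

  # unmapped reads never count
  reads <- data.frame(contig = c(rep("chr1", 6), rep(NA, 4)),
                      start = c((1:6) * 1000L, rep(NA, 4)),
                      mapq = c(rep(60L, 6), rep(0L, 4)), length = 100L)
  bam3 <- make_toy_bam(dir, "S3", reads)
  expect_identical(count_mapped_reads(bam3, cfg)$total_hq, 6L)
})

test_that("read counting requires an index and keeps counts conserved", {
  dir <- withr::local_tempdir()
  bam <- make_toy_bam(dir)
  unlink(paste0(bam, ".bai"))
  expect_error(count_mapped_reads(bam, test_genome_config()), "index")
})

test_that("Xmap and Ymap are exact read-count fractions", {
  dir <- withr::local_tempdir()
  cfg <- test_genome_config()
  cnt <- count_mapped_reads(make_toy_bam(dir), cfg)
  expect_identical(compute_xmap(cnt, cfg), 8 / 40)
  expect_identical(compute_ymap(cnt, cfg), 2 / 40)

  # zero numerator is a valid 0, absent contig is an error
  no_x <- data.frame(contig = rep("chr1", 5), start = (1:5) * 1000L,
                     mapq = 60L, length = 100L)
  bam <- write_fixture_alignments(list(S9 = no_x), c(chr1 = 100000L),
                                  withr::local_tempdir())[["S9"]]
  cnt2 <- count_mapped_reads(bam, cfg)
  expect_error(compute_xmap(cnt2, cfg), "contig mismatch.*X")
  cnt2$per_contig <- c(cnt2$per_contig, X = 0L)
  expect_identical(compute_xmap(cnt2, cfg), 0)
})

test_that("doubling every read leaves the fraction features unchanged", {
  dir <- withr::local_tempdir()
  cfg <- test_genome_config()
  reads <- toy_reads()
  doubled <- rbind(reads, transform(reads, start = start + 7L))
  b1 <- make_toy_bam(dir, "A", reads)
  b2 <- make_toy_bam(dir, "B", doubled)
  c1 <- count_mapped_reads(b1, cfg)
  c2 <- count_mapped_reads(b2, cfg)
  expect_identical(compute_xmap(c1, cfg), compute_xmap(c2, cfg))
  expect_identical(compute_ymap(c1, cfg), compute_ymap(c2, cfg))
  r1 <- compute_xyratio(compute_xmap(c1, cfg), compute_ymap(c1, cfg), c1$total_hq)
  r2 <- compute_xyratio(compute_xmap(c2, cfg), compute_ymap(c2, cfg), c2$total_hq)
  expect_identical(as.numeric(r1), as.numeric(r2))
})

test_that("XY ratio divides the fractions and censors a zero Ymap", {
  r <- compute_xyratio(0.2, 0.05, 40L)
  expect_identical(as.numeric(r), 4)
  expect_false(attr(r, "censored"))

  r0 <- compute_xyratio(0.2, 0, 40L)
  expect_identical(as.numeric(r0), 0.2 / (1 / 40))
  expect_true(attr(r0, "censored"))

  expect_error(compute_xyratio(0, 0, 40L), "undefined ratio")
  expect_equal(compute_xyratio(0.035, 1.61e-05, 1e6)[[1]], 2173.913,
               tolerance = 1e-4)
})

test_that("X heterozygosity counts het calls among non-missing diploid X genotypes", {
  dir <- withr::local_tempdir()
  vcf <- make_xh_vcf(file.path(dir, "xh.vcf"))
  expect_identical(compute_xh(vcf, "S1"), 3 / 8)

  all_missing <- make_xh_vcf(file.path(dir, "m.vcf"), gt = rep("./.", 6))
  expect_true(is.na(compute_xh(all_missing, "S1")))

  hom_male <- make_xh_vcf(file.path(dir, "h.vcf"), gt = rep("0/0", 6))
  expect_identical(compute_xh(hom_male, "S1"), 0)

  expect_error(compute_xh(vcf, "nope"), "unknown sample")

  no_x <- make_xh_vcf(file.path(dir, "nx.vcf"), gt = rep("0/1", 4),
                      sites = xh_sites(4, chrom = "chr1"))
  expect_warning(xh <- compute_xh(no_x, "S1"), "no X")
  expect_true(is.na(xh))
})

test_that("XH skips PAR sites, haploid calls, and counts 1/2 as het", {
  dir <- withr::local_tempdir()
  # 2 PAR1 sites (het) + 4 informative: het 1/2, haploid (skipped), hom, miss
  sites <- rbind(xh_sites(2, pos0 = 100000L), xh_sites(4))
  gt <- c("0/1", "0/1", "1/2", "1", "0/0", "./.")
  vcf <- make_xh_vcf(file.path(dir, "par.vcf"), gt = gt, sites = sites)
  expect_identical(compute_xh(vcf, "S1"), 1 / 2)

  # with PAR masking off the two PAR hets enter the denominator
  cfg_nopar <- genome_config(par_regions = list())
  expect_identical(compute_xh(vcf, "S1", cfg_nopar), 3 / 4)
})

test_that("XH is invariant to record order and to non-X sites", {
  dir <- withr::local_tempdir()
  sites <- rbind(xh_sites(10), xh_sites(5, chrom = "chr1"))
  gt <- c(xh_gt, rep("0/1", 5))
  set.seed(42)
  for (i in 1:3) {
    ord <- sample(nrow(sites))
    vcf <- make_xh_vcf(file.path(dir, paste0("p", i, ".vcf")),
                       gt = gt[ord], sites = sites[ord, ])
    expect_identical(compute_xh(vcf, "S1"), 3 / 8)
  }
})

test_that("SRY depth averages filtered coverage over the region", {
  dir <- withr::local_tempdir()
  cfg <- test_genome_config()  # 100 bp region at the SRY locus

  tile3 <- data.frame(contig = "Y", start = rep(sry_start, 3), mapq = 60L,
                      length = 100L)
  bam <- make_toy_bam(dir, "T3", tile3)
  expect_identical(compute_sry_depth(bam, cfg), 3)

  half <- data.frame(contig = "Y", start = sry_start, mapq = 60L, length = 50L)
  bam2 <- make_toy_bam(dir, "T1", half)
  expect_identical(compute_sry_depth(bam2, cfg), 0.5)

  # mapq at the cutoff contributes nothing
  low <- data.frame(contig = "Y", start = sry_start, mapq = 30L, length = 100L)
  bam3 <- make_toy_bam(dir, "T0", low)
  expect_identical(compute_sry_depth(bam3, cfg), 0)

  female <- data.frame(contig = "chr1", start = (1:5) * 1000L, mapq = 60L,
                       length = 100L)
  bam4 <- make_toy_bam(dir, "F1", female)
  expect_identical(compute_sry_depth(bam4, cfg), 0)
})

test_that("variant filtering applies the four rules and is idempotent", {
  dir <- withr::local_tempdir()
  vcf <- make_filter_vcf(file.path(dir, "filt.vcf"))
  out <- file.path(dir, "filt_pass.vcf")
  kept <- filter_variants(vcf, out_path = out)
  expect_identical(nrow(kept), 4L)
  # QUAL 30 retained, 29.9 removed; the 3/4-missing site removed
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(kept))
  expect_identical(sort(pos), c(100L, 400L, 500L, 600L))

  twice <- filter_variants(out)
  expect_identical(nrow(twice), 4L)
  expect_identical(sort(GenomicRanges::start(SummarizedExperiment::rowRanges(twice))),
                   sort(pos))
})

test_that("genotype depth masking precedes the missingness test", {
  dir <- withr::local_tempdir()
  # 10 samples; site 1: 4 missing + 2 low-depth -> 6/10 missing -> removed;
  # site 2: depth >= 5 everywhere, MAC 4 -> retained
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A",
                      alt = "G", qual = 50)
  gt <- rbind(c(rep("./.", 4), rep("0/1", 6)),
              c(rep("0/1", 4), rep("0/0", 6)))
  colnames(gt) <- paste0("P", 1:10)
  dp <- rbind(c(rep(NA, 4), 4L, 4L, rep(10L, 4)), rep(10L, 10))
  write_fixture_vcf(sites, gt, file.path(dir, "dp.vcf"), dp = dp)
  kept <- filter_variants(file.path(dir, "dp.vcf"))
  expect_identical(nrow(kept), 1L)
  expect_identical(GenomicRanges::start(SummarizedExperiment::rowRanges(kept)), 200L)

  # depth 5 itself passes (strict "< 5" masks)
  dp2 <- rbind(c(rep(NA, 4), 5L, 5L, rep(10L, 4)), rep(10L, 10))
  write_fixture_vcf(sites, gt, file.path(dir, "dp2.vcf"), dp = dp2)
  expect_identical(nrow(filter_variants(file.path(dir, "dp2.vcf"))), 2L)

  # without a DP field the depth filter is skipped with a warning
  write_fixture_vcf(sites, gt, file.path(dir, "nodp.vcf"))
  expect_warning(kept3 <- filter_variants(file.path(dir, "nodp.vcf")), "DP")
  expect_identical(nrow(kept3), 2L)
})

test_that("minor allele count uses the second most common allele", {
  dir <- withr::local_tempdir()
  # site 1: alleles 6x0, 2x1 -> MAC 2 -> removed; site 2: 5x0, 3x1 -> kept
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A",
                      alt = "G", qual = 50)
  gt <- rbind(c("0/0", "0/0", "0/1", "0/1"),
              c("0/1", "0/1", "0/1", "0/0"))
  colnames(gt) <- paste0("P", 1:4)
  write_fixture_vcf(sites, gt, file.path(dir, "mac.vcf"),
                    dp = matrix(10L, 2, 4))
  kept <- filter_variants(file.path(dir, "mac.vcf"))
  expect_identical(nrow(kept), 1L)
  expect_identical(GenomicRanges::start(SummarizedExperiment::rowRanges(kept)), 200L)
})

test_that("feature extraction composes the per-operation values", {
  dir <- withr::local_tempdir()
  cfg <- test_genome_config()
  reads <- list(
    M1 = toy_reads(),
    F1 = data.frame(contig = c(rep("chr1", 30), rep("X", 10)),
                    start = c(seq(1L, by = 200L, length.out = 30),
                              seq(3000000L, by = 300L, length.out = 10)),
                    mapq = 60L, length = 100L)
  )
  bams <- write_fixture_alignments(reads, tiny_reference, dir)
  sites <- xh_sites(10)
  gt <- cbind(M1 = rep(c("0/0", "./."), 5),
              F1 = c("0/1", "0/1", "0/1", "0/0", "0/0",
                     "1/1", "0/0", "1/1", "./.", "./."))
  vcf <- file.path(dir, "cohort.vcf")
  write_fixture_vcf(sites, gt, vcf)

  tbl <- extract_feature_table(bams, vcf = vcf, config = cfg,
                               features = c("XH", "Xmap"))
  expect_s3_class(tbl, "feature_table")
  expect_identical(selected_features(tbl), c("XH", "Xmap"))
  m <- as.data.frame(tbl)[tbl$sample_id == "M1", ]
  f <- as.data.frame(tbl)[tbl$sample_id == "F1", ]
  expect_identical(m$Xmap, 8 / 40)
  expect_identical(f$Xmap, 10 / 40)
  expect_identical(m$XH, 0)
  expect_identical(f$XH, 3 / 8)
  # non-selected features are still carried when computable
  expect_identical(m$Ymap, 2 / 40)
  expect_identical(f$Ymap, 0)

  # selecting a feature whose contig is absent is a configuration error
  xonly <- write_fixture_alignments(
    list(P1 = data.frame(contig = "X", start = 3000000L, mapq = 60L,
                         length = 100L)),
    c(chr1 = 100000L, X = 160000000L), file.path(dir, "xonly"))
  expect_error(
    extract_feature_table(xonly, config = cfg, features = c("Xmap", "Ymap")),
    "configuration error.*Ymap.*P1")

  # XH without a VCF is a configuration error
  expect_error(extract_feature_table(bams, config = cfg, features = "XH"),
               "XH.*VCF")
})

test_that("feature tables round-trip through TSV bit-stably", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(n_male = 5, n_female = 5, seed = 3))
  path <- file.path(dir, "feat.tsv")
  write_feature_table(sim$features, path)
  back <- read_feature_table(path)
  expect_identical(back$Xmap, sim$features$Xmap)
  expect_identical(back$Ymap, sim$features$Ymap)
  expect_identical(back$XYratio, sim$features$XYratio)
  expect_identical(selected_features(back),
                   selected_features(sim$features))
  header <- readLines(path, n = 1L)
  expect_identical(header, "sample_id\tXH\tXmap\tYmap\tXYratio\tSRY_dep")
})

test_that("feature tables enforce range and selection invariants", {
  df <- data.frame(sample_id = c("a", "b"), Xmap = c(0.6, 0.5),
                   Ymap = c(0.5, 0.1))
  expect_error(feature_table(df, "Xmap"), "exceed 1")
  df2 <- data.frame(sample_id = c("a", "a"), Xmap = c(0.1, 0.2))
  expect_error(feature_table(df2, "Xmap"), "unique")
  df3 <- data.frame(sample_id = c("a", "b"), Xmap = c(0.1, NA))
  expect_error(feature_table(df3, "Xmap"), "missing")
  expect_error(feature_table(data.frame(sample_id = "a", XH = 0.2),
                             character(0)), "non-empty")
})
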