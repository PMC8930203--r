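# Fixtures are built in code: a tiny three-contig reference, hand-countable
# BAM read layouts, and small VCFs. SRY is placed at Y:2,654,896-2,655,740
# (its GRCh37 locus) so the default genome_config() works unchanged.

tiny_reference <- c(chr1 = 100000L, X = 160000000L, Y = 2700000L)

sry_start <- 2654896L
sry_end <- 2655740L

test_genome_config <- function(...) {
  genome_config(sry_region = list(contig = "Y", start = sry_start,
                                  end = sry_start + 99L), ...)
}

# 40 high-quality reads: 30 on chr1, 8 on X, 2 on Y (the Y pair tiles the
# 100 bp SRY test region back to back, each read 50 bp)
toy_reads <- function() {
  data.frame(
    contig = c(rep("chr1", 30), rep("X", 8), rep("Y", 2)),
    start = c(seq(1L, by = 200L, length.out = 30),
              seq(3000000L, by = 300L, length.out = 8),
              c(sry_start, sry_start + 50L)),
    mapq = 60L,
    length = c(rep(100L, 38), 50L, 50L)
  )
}

make_toy_bam <- function(dir = withr::local_tempdir(), sample_id = "S1",
                         reads = toy_reads()) {
  paths <- write_fixture_alignments(stats::setNames(list(reads), sample_id),
                                    tiny_reference, dir)
  paths[[sample_id]]
}

# one sample, 10 X genotypes outside PAR: 3 het, 5 hom, 2 missing -> XH 0.375
xh_sites <- function(n = 10L, chrom = "X", pos0 = 3000000L) {
  data.frame(chrom = chrom, pos = pos0 + seq_len(n) * 100L,
             ref = "A", alt = "G", qual = 50)
}

xh_gt <- c("0/1", "0/1", "0/1", "0/0", "0/0", "1/1", "0/0", "1/1", "./.", "./.")

make_xh_vcf <- function(path, gt = xh_gt, sample_id = "S1", sites = NULL) {
  if (is.null(sites)) sites <- xh_sites(length(gt))
  m <- matrix(gt, ncol = 1L, dimnames = list(NULL, sample_id))
  write_fixture_vcf(sites, m, path)
  path
}

# 6 sites over 4 samples; exactly 2 violate one filter rule each:
# site 2 fails QUAL (29.9 < 30), site 3 fails missingness (3/4 > 0.5).
# Sites 1, 4, 5, 6 pass all four rules -> 4 retained.
make_filter_vcf <- function(path) {
  sites <- data.frame(chrom = "chr1", pos = seq_len(6L) * 100L,
                      ref = "A", alt = "G",
                      qual = c(50, 29.9, 50, 50, 30, 50))
  gt <- rbind(
    c("0/1", "0/1", "0/1", "0/0"),
    c("0/1", "0/1", "0/1", "0/0"),
    c("./.", "./.", "./.", "0/1"),
    c("0/1", "0/1", "1/1", "0/0"),
    c("0/1", "1/1", "0/1", "0/0"),
    c("0/1", "0/1", "0/1", "1/1")
  )
  colnames(gt) <- paste0("P", 1:4)
  dp <- matrix(10L, nrow = 6L, ncol = 4L)
  write_fixture_vcf(sites, gt, path, dp = dp)
  path
}

# per-sex Xmap/Ymap statistics of the large reference exome cohort
printed_stats <- function() {
  sex_stats(
    mean_xmap_m = 0.018, sd_xmap_m = 0.0011,
    mean_ymap_m = 0.00067, sd_ymap_m = 0.00014,
    mean_xmap_f = 0.035, sd_xmap_f = 0.0020,
    mean_ymap_f = 1.61e-05, sd_ymap_f = 3.36e-05
  )
}

# Independent posterior oracle: Bayes rule with densities evaluated through
# solve()/determinant(), a different numerical path from the fit's Cholesky.
oracle_posteriors <- function(x, fit) {
  k <- length(fit$weights)
  dens <- vapply(seq_len(k), function(j) {
    sigma <- fit$covariances[[j]]
    inv <- solve(sigma)
    logdet <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
    centered <- sweep(x, 2L, fit$means[j, ])
    q <- rowSums((centered %*% inv) * centered)
    exp(-0.5 * q - 0.5 * logdet - 0.5 * ncol(x) * log(2 * pi)) * fit$weights[[j]]
  }, numeric(nrow(x)))
  dens / rowSums(dens)
}
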