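#' Configuration for synthetic cohort simulation
#'
#' Defines per-sex feature distributions and aneuploidy injection for
#' simulated cohorts. Defaults reproduce the per-sex Xmap/Ymap statistics of
#' a large clinical exome cohort (males 0.018 +/- 0.0011 and 0.00067 +/-
#' 0.00014; females 0.035 +/- 0.0020 and 1.61e-05 +/- 3.36e-05) at its
#' sample sizes (1,257 males, 1,136 females). XH and SRY depth magnitudes are
#' plumbing for the qualitative male/female contrast: male XH is near-zero
#' half-normal noise (sd 0.002), female XH is 0.25 +/- 0.05; male SRY depth
#' is 30 +/- 5, female SRY depth is half-normal noise (sd 0.1).
#'
#' Aneuploid samples get Xmap/Ymap scaled by copy-number multipliers: XYY
#' (1, 2) and XXY (2, 1) relative to the male means, XXX (1.5, 1) and X
#' monosomy (0.5, 1) relative to the female means. With
#' `match_paper_gates = TRUE`, aneuploid points are instead drawn truncated
#' inside the corresponding printed gate region (computed from the configured
#' per-sex distributions) with a safety margin — e.g. XYY Ymap at fold-change
#' 2.2-2.7 of the male mean, the range observed for real XYY exomes — so that
#' injected counts are exactly recoverable by the gates.
#'
#' @param n_male,n_female Numbers of karyotypically normal samples.
#' @param aneuploidy_spec Named integer vector over `XYY`, `XXY`, `XXX`, `X`
#'   giving counts of injected aneuploid samples.
#' @param male,female Per-sex feature distributions: lists with `Xmap`,
#'   `Ymap`, `XH`, `SRY_dep`, each `c(mean, sd)`.
#' @param copy_multipliers Named list karyotype -> `c(x, y)` multipliers.
#' @param match_paper_gates Draw aneuploid points truncated inside the gate
#'   regions instead of at their copy-number expectations.
#' @param seed Integer seed.
#'
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_male = 1257L,
                              n_female = 1136L,
                              aneuploidy_spec = integer(0),
                              male = list(Xmap = c(0.018, 0.0011),
                                          Ymap = c(0.00067, 0.00014),
                                          XH = c(0, 0.002),
                                          SRY_dep = c(30, 5)),
                              female = list(Xmap = c(0.035, 0.0020),
                                            Ymap = c(1.61e-05, 3.36e-05),
                                            XH = c(0.25, 0.05),
                                            SRY_dep = c(0, 0.1)),
                              copy_multipliers = list(XYY = c(1, 2),
                                                      XXY = c(2, 1),
                                                      XXX = c(1.5, 1),
                                                      X = c(0.5, 1)),
                              match_paper_gates = FALSE,
                              seed = 1L) {
  if (n_male < 0 || n_female < 0 || any(aneuploidy_spec < 0))
    stop("sample counts must be non-negative", call. = FALSE)
  if (length(aneuploidy_spec)) {
    bad <- setdiff(names(aneuploidy_spec), c("XYY", "XXY", "XXX", "X"))
    if (length(bad))
      stop("unknown aneuploidy karyotype(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  for (dist in list(male, female))
    for (f in FEATURE_NAMES[-4L])  # XYratio is derived, not drawn
      if (is.null(dist[[f]]) || length(dist[[f]]) != 2L || dist[[f]][[2L]] < 0)
        stop("each feature distribution must be c(mean, sd) with sd >= 0",
             call. = FALSE)
  structure(
    list(n_male = as.integer(n_male), n_female = as.integer(n_female),
         aneuploidy_spec = aneuploidy_spec, male = male, female = female,
         copy_multipliers = copy_multipliers,
         match_paper_gates = isTRUE(match_paper_gates),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Truncated normal draws by inverse-CDF; errors when the truncation removes
# more than half the mass (an infeasible configuration rather than a
# realistic one).
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("infeasible simulation: point mass outside truncation bounds",
           call. = FALSE)
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 0.5)
    stop("infeasible simulation: truncation removes more than 50% of the ",
         "distribution mass (mean ", mean, ", sd ", sd, ", bounds [",
         lower, ", ", upper, "])", call. = FALSE)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

half_normal <- function(n, sd) abs(stats::rnorm(n, 0, sd))

draw_feature <- function(n, spec, lower = 0, upper = Inf) {
  if (spec[[1L]] == 0) pmin(half_normal(n, spec[[2L]]), upper)
  else rtrunc_norm(n, spec[[1L]], spec[[2L]], lower, upper)
}

draw_normal_sex <- function(n, dist) {
  data.frame(
    XH = draw_feature(n, dist$XH, upper = 1),
    Xmap = draw_feature(n, dist$Xmap, upper = 1),
    Ymap = draw_feature(n, dist$Ymap, upper = 1),
    SRY_dep = draw_feature(n, dist$SRY_dep)
  )
}

# (x, y) draws for one aneuploid karyotype
draw_aneuploid_xy <- function(n, kar, cfg) {
  m <- cfg$male; f <- cfg$female
  if (cfg$match_paper_gates) {
    gc <- gate_config()
    # band draws are truncated at 2.5 sd, inside the 3 sd gate, leaving a
    # margin for the shift between the configured distribution and the
    # empirical cohort statistics the gates are actually evaluated on
    band <- function(mu, sd) c(max(0, mu - 2.5 * sd), mu + 2.5 * sd)
    switch(kar,
      XYY = {
        bx <- band(m$Xmap[1], m$Xmap[2])
        x <- rtrunc_norm(n, m$Xmap[1], m$Xmap[2], bx[1], bx[2])
        y <- rtrunc_norm(n, 2.4 * m$Ymap[1], m$Ymap[2],
                         lower = 2.2 * m$Ymap[1])
        cbind(x, y)
      },
      XXY = {
        by <- band(m$Ymap[1], m$Ymap[2])
        x <- rtrunc_norm(n, 2.5 * f$Xmap[1], f$Xmap[2],
                         lower = gc$xxy_x_mult * f$Xmap[1])
        y <- rtrunc_norm(n, m$Ymap[1], m$Ymap[2], by[1], by[2])
        cbind(x, y)
      },
      XXX = {
        by <- band(f$Ymap[1], f$Ymap[2])
        x <- rtrunc_norm(n, 3.5 * f$Xmap[1], f$Xmap[2],
                         lower = gc$xxx_x_mult * f$Xmap[1])
        y <- rtrunc_norm(n, f$Ymap[1], f$Ymap[2], by[1], by[2])
        cbind(x, y)
      },
      X = {
        by <- band(f$Ymap[1], f$Ymap[2])
        x <- rtrunc_norm(n, 0.4 * f$Xmap[1], f$Xmap[2],
                         lower = 0, upper = gc$x_monosomy_mult * f$Xmap[1])
        y <- rtrunc_norm(n, f$Ymap[1], f$Ymap[2], by[1], by[2])
        cbind(x, y)
      }
    )
  } else {
    mult <- cfg$copy_multipliers[[kar]]
    base <- if (kar %in% c("XYY", "XXY")) m else f
    x <- rtrunc_norm(n, mult[[1L]] * base$Xmap[1], mult[[1L]] * base$Xmap[2],
                     0, 1)
    y <- if (base$Ymap[1] == 0 || mult[[2L]] * base$Ymap[1] == 0)
      half_normal(n, base$Ymap[2])
    else rtrunc_norm(n, mult[[2L]] * base$Ymap[1], mult[[2L]] * base$Ymap[2],
                     0, 1)
    cbind(x, y)
  }
}

draw_aneuploids <- function(kar, n, cfg) {
  m <- cfg$male; f <- cfg$female
  xy <- draw_aneuploid_xy(n, kar, cfg)
  sex <- switch(kar, XYY = "male", XXY = "male", XXX = "female", X = "female")
  # XH tracks the number of X copies, SRY depth the number of Y copies
  xh <- switch(kar,
    XYY = draw_feature(n, m$XH, upper = 1),
    XXY = draw_feature(n, f$XH, upper = 1),
    XXX = draw_feature(n, f$XH, upper = 1),
    X = draw_feature(n, m$XH, upper = 1))
  sry <- switch(kar,
    XYY = rtrunc_norm(n, 2 * m$SRY_dep[1], 2 * m$SRY_dep[2]),
    XXY = draw_feature(n, m$SRY_dep),
    XXX = draw_feature(n, f$SRY_dep),
    X = draw_feature(n, f$SRY_dep))
  data.frame(XH = xh, Xmap = xy[, 1L], Ymap = xy[, 2L], SRY_dep = sry,
             sex = sex, karyotype = kar, stringsAsFactors = FALSE)
}

#' Simulate a cohort with known sex and karyotype truth
#'
#' Draws per-sample features from truncated Gaussian distributions per sex
#' and injected karyotype, and derives `XYratio = Xmap / Ymap`. Deterministic
#' given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `features` (a [feature_table()] over all five
#'   features) and `truth` (data.frame: `sample_id`, `sex`, `karyotype`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  total <- config$n_male + config$n_female + sum(config$aneuploidy_spec)
  if (total < 4L)
    stop("simulation needs at least 4 samples in total", call. = FALSE)
  set.seed(config$seed)
  parts <- list()
  if (config$n_male > 0L) {
    d <- draw_normal_sex(config$n_male, config$male)
    d$sex <- "male"; d$karyotype <- "XY"
    parts[[length(parts) + 1L]] <- d
  }
  if (config$n_female > 0L) {
    d <- draw_normal_sex(config$n_female, config$female)
    d$sex <- "female"; d$karyotype <- "XX"
    parts[[length(parts) + 1L]] <- d
  }
  for (kar in names(config$aneuploidy_spec)) {
    n <- config$aneuploidy_spec[[kar]]
    if (n > 0L)
      parts[[length(parts) + 1L]] <- draw_aneuploids(kar, n, config)
  }
  df <- do.call(rbind, parts)
  df$sample_id <- sprintf("S%05d", seq_len(nrow(df)))
  df$XYratio <- df$Xmap / df$Ymap
  features <- feature_table(
    df[, c("sample_id", FEATURE_NAMES)],
    selected_features = FEATURE_NAMES
  )
  truth <- df[, c("sample_id", "sex", "karyotype")]
  rownames(truth) <- NULL
  list(features = features, truth = truth)
}

#' Write miniature sorted, indexed BAM fixtures
#'
#' Emits one valid coordinate-sorted, indexed BAM per sample from an explicit
#' read layout over a tiny reference, so feature extractors can be checked
#' against hand-counted values exactly.
#'
#' @param sample_reads Named list (one element per sample id). Each element
#'   is a data.frame with columns `contig`, `start`, `mapq`, and optionally
#'   `length` (read length, default `read_length`); one row per read. Rows
#'   with `contig = NA` become unmapped records.
#' @param reference Named integer vector: contig name -> contig length.
#' @param out_dir Output directory (created if needed).
#' @param read_length Default read length in bp.
#'
#' @return Named character vector of BAM paths.
#' @export
write_fixture_alignments <- function(sample_reads, reference, out_dir,
                                     read_length = 100L) {
  stopifnot(is.list(sample_reads), length(names(reference)) > 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- names(reference)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contigs, as.integer(reference))
  )
  out <- character(0)
  for (sid in names(sample_reads)) {
    reads <- sample_reads[[sid]]
    stopifnot(all(c("contig", "start", "mapq") %in% names(reads)))
    if (is.null(reads$length)) reads$length <- read_length
    mapped <- !is.na(reads$contig)
    bad <- setdiff(unique(reads$contig[mapped]), contigs)
    if (length(bad))
      stop("fixture config error: contig(s) not in the tiny reference: ",
           paste(bad, collapse = ", "), call. = FALSE)
    over <- mapped & (reads$start + reads$length - 1L > reference[reads$contig])
    if (any(over, na.rm = TRUE))
      stop("fixture config error: read extends past its contig end",
           call. = FALSE)
    ord <- order(match(reads$contig, contigs), reads$start, na.last = TRUE)
    reads <- reads[ord, , drop = FALSE]
    mapped <- !is.na(reads$contig)
    lines <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
      sprintf("%s_r%04d", sid, seq_len(nrow(reads))),
      ifelse(mapped, 0L, 4L),
      ifelse(mapped, reads$contig, "*"),
      ifelse(mapped, as.integer(reads$start), 0L),
      ifelse(mapped, as.integer(reads$mapq), 0L),
      ifelse(mapped, paste0(reads$length, "M"), "*"),
      vapply(reads$length, function(l) strrep("A", l), character(1L)),
      vapply(reads$length, function(l) strrep("I", l), character(1L))
    )
    sam <- file.path(out_dir, paste0(sid, ".sam"))
    writeLines(c(header, lines), sam)
    bam <- Rsamtools::asBam(sam, file.path(out_dir, sid),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    out[[sid]] <- bam
  }
  out
}

#' Write a miniature multi-sample VCF fixture
#'
#' Produces a valid plain-text VCF from an explicit site/genotype layout so
#' that heterozygosity and variant filtering can be checked against hand
#' counts.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`
#'   (use `NA` for a missing QUAL).
#' @param gt Character matrix (sites x samples) of genotype strings such as
#'   `"0/1"`, `"1|1"`, `"./."`, `"0"` (haploid).
#' @param out_path Output `.vcf` path.
#' @param sample_ids Sample names; default taken from `colnames(gt)`.
#' @param dp Optional integer matrix (sites x samples) of genotype depths;
#'   `NA` becomes `.`.
#' @param reference Optional named vector contig -> length for the header;
#'   defaults to `max(pos) + 1000` per chromosome.
#'
#' @return `out_path`, invisibly.
#' @export
write_fixture_vcf <- function(sites, gt, out_path, sample_ids = colnames(gt),
                              dp = NULL, reference = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)))
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites))
    stop("fixture config error: gt rows must match sites", call. = FALSE)
  if (is.null(sample_ids))
    stop("fixture config error: sample ids are required", call. = FALSE)
  if (!is.character(gt) || any(is.na(gt)))
    stop("fixture config error: genotypes must be strings like '0/1' ",
         "('./.' for missing)", call. = FALSE)
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    stopifnot(all(dim(dp) == dim(gt)))
  }
  if (is.null(reference)) {
    reference <- tapply(sites$pos, sites$chrom, function(p) max(p) + 1000L)
    reference <- reference[unique(sites$chrom)]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            as.integer(reference)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(dp))
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  body <- vapply(seq_len(nrow(sites)), function(i) {
    cells <- if (is.null(dp)) gt[i, ] else
      paste0(gt[i, ], ":", ifelse(is.na(dp[i, ]), ".", dp[i, ]))
    paste(c(sites$chrom[[i]], sites$pos[[i]], ".", sites$ref[[i]],
            sites$alt[[i]],
            ifelse(is.na(sites$qual[[i]]), ".", sites$qual[[i]]),
            ".", ".", fmt, cells), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), out_path)
  invisible(out_path)
}
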