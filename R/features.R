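#' @importFrom Rsamtools ScanBamParam scanBamFlag scanBam scanBamHeader BamFile
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importFrom GenomicAlignments readGAlignments coverage
#' @importFrom GenomicRanges seqnames start
#' @importFrom methods is
NULL

FEATURE_NAMES <- c("XH", "Xmap", "Ymap", "XYratio", "SRY_dep")
BAM_FEATURES <- c("Xmap", "Ymap", "XYratio", "SRY_dep")

#' Per-sample feature table
#'
#' Assembles per-sample sex-feature rows into the table consumed by the
#' mixture model and the karyotype gates. The five features are XH
#' (X-chromosome heterozygosity), Xmap and Ymap (fractions of high-quality
#' reads mapping to X and Y), XYratio (Xmap/Ymap), and SRY_dep (mean depth
#' over the SRY gene). A feature may be selected for modeling only when it is
#' present (non-missing) for every sample.
#'
#' @param df A data.frame with a `sample_id` column and any of the feature
#'   columns `XH`, `Xmap`, `Ymap`, `XYratio`, `SRY_dep`. Absent columns are
#'   filled with `NA`.
#' @param selected_features Ordered character vector naming the features used
#'   for modeling.
#'
#' @return A `feature_table`: a data.frame with all five feature columns and
#'   a `selected_features` attribute.
#' @export
feature_table <- function(df, selected_features) {
  stopifnot(is.data.frame(df), "sample_id" %in% names(df))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("sample_ids must be unique", call. = FALSE)
  selected_features <- as.character(selected_features)
  if (length(selected_features) == 0L)
    stop("selected_features must be non-empty", call. = FALSE)
  bad <- setdiff(selected_features, FEATURE_NAMES)
  if (length(bad))
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (f in FEATURE_NAMES) if (is.null(df[[f]])) df[[f]] <- NA_real_
  df <- df[, c("sample_id", FEATURE_NAMES), drop = FALSE]
  for (f in selected_features) {
    if (anyNA(df[[f]]))
      stop("selected feature '", f, "' is missing for sample(s): ",
           paste(df$sample_id[is.na(df[[f]])], collapse = ", "), call. = FALSE)
  }
  validate_feature_ranges(df)
  structure(df, selected_features = selected_features,
            class = c("feature_table", "data.frame"))
}

validate_feature_ranges <- function(df) {
  in01 <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  if (!in01(df$XH)) stop("XH must lie in [0, 1]", call. = FALSE)
  if (!in01(df$Xmap)) stop("Xmap must lie in [0, 1]", call. = FALSE)
  if (!in01(df$Ymap)) stop("Ymap must lie in [0, 1]", call. = FALSE)
  both <- !is.na(df$Xmap) & !is.na(df$Ymap)
  if (any(df$Xmap[both] + df$Ymap[both] > 1 + 1e-12))
    stop("Xmap + Ymap cannot exceed 1", call. = FALSE)
  if (!all(is.na(df$XYratio) | df$XYratio >= 0) ||
      !all(is.na(df$SRY_dep) | df$SRY_dep >= 0))
    stop("XYratio and SRY_dep must be non-negative", call. = FALSE)
  invisible(df)
}

#' @export
selected_features <- function(x) attr(x, "selected_features")

check_bam_index <- function(bam_path) {
  if (!file.exists(bam_path))
    stop("BAM file not found: ", bam_path, call. = FALSE)
  idx <- c(paste0(bam_path, ".bai"),
           paste0(tools::file_path_sans_ext(bam_path), ".bai"))
  if (!any(file.exists(idx)))
    stop("missing BAM index for ", bam_path,
         " (expected ", idx[[1L]], ")", call. = FALSE)
  invisible(TRUE)
}

hq_flags <- function() {
  scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
              isSupplementaryAlignment = FALSE)
}

#' Count high-quality mapped reads per chromosome
#'
#' Counts primary mapped reads with mapping quality strictly greater than the
#' configured cutoff, per contig. Unmapped, secondary, and supplementary
#' records are excluded, as are reads with unavailable mapping quality.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM file.
#' @param config A [genome_config()].
#' @param sample_id Sample identifier; defaults to the BAM basename.
#'
#' @return A `read_counts` object: `sample_id`, `per_contig` (named integer
#'   vector over all header contigs), and `total_hq` (their sum).
#' @export
count_mapped_reads <- function(bam_path, config = genome_config(),
                               sample_id = NULL) {
  check_bam_index(bam_path)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(bam_path))
  targets <- names(scanBamHeader(bam_path)[[1L]]$targets)
  param <- ScanBamParam(flag = hq_flags(), what = c("rname", "mapq"))
  rec <- scanBam(bam_path, param = param)[[1L]]
  keep <- !is.na(rec$mapq) & rec$mapq > config$mapq_min
  per_contig <- table(factor(as.character(rec$rname[keep]), levels = targets))
  per_contig <- stats::setNames(as.integer(per_contig), targets)
  structure(
    list(sample_id = sample_id, per_contig = per_contig,
         total_hq = sum(per_contig)),
    class = "read_counts"
  )
}

contig_fraction <- function(counts, contig_name, label) {
  if (counts$total_hq == 0L)
    stop("empty alignment: no high-quality mapped reads for sample ",
         counts$sample_id, call. = FALSE)
  contig <- resolve_contig(contig_name, names(counts$per_contig))
  if (is.na(contig))
    stop("contig mismatch: '", contig_name, "' (needed for ", label,
         ") is absent from the BAM header", call. = FALSE)
  unname(counts$per_contig[[contig]] / counts$total_hq)
}

#' Fraction of high-quality reads mapped to the X chromosome
#'
#' @param counts A `read_counts` object from [count_mapped_reads()].
#' @param config A [genome_config()].
#' @return Xmap, the X read count divided by the genome-wide total of
#'   high-quality mapped reads.
#' @export
compute_xmap <- function(counts, config = genome_config()) {
  contig_fraction(counts, config$x_name, "Xmap")
}

#' Fraction of high-quality reads mapped to the Y chromosome
#'
#' @inheritParams compute_xmap
#' @return Ymap, the Y read count divided by the genome-wide total.
#' @export
compute_ymap <- function(counts, config = genome_config()) {
  contig_fraction(counts, config$y_name, "Ymap")
}

#' Ratio of X to Y read-mapping fractions
#'
#' Returns Xmap/Ymap. Female samples on small panels routinely have zero Y
#' reads; in that case the denominator is replaced by a one-read pseudocount
#' (1/total reads) and the result is flagged via a `censored` attribute, so
#' the feature stays finite while preserving the ordering of samples.
#'
#' @param xmap,ymap Read-mapping fractions for X and Y.
#' @param total_hq Total high-quality mapped reads (used only for the
#'   pseudocount when `ymap == 0`).
#' @return The ratio, with logical attribute `censored`.
#' @export
compute_xyratio <- function(xmap, ymap, total_hq) {
  if (xmap == 0 && ymap == 0)
    stop("undefined ratio: both Xmap and Ymap are zero", call. = FALSE)
  if (ymap > 0) return(structure(xmap / ymap, censored = FALSE))
  structure(xmap / (1 / total_hq), censored = TRUE)
}

read_vcf_input <- function(vcf) {
  if (methods::is(vcf, "VCF")) return(vcf)
  if (!file.exists(vcf)) stop("VCF file not found: ", vcf, call. = FALSE)
  suppressWarnings(VariantAnnotation::readVcf(vcf, genome = "cohort"))
}

# Split "0/1"-style genotype strings into per-call summaries.
# Returns, per genotype: n_alleles, missing (any "."), het (two called
# alleles with different indices).
parse_genotypes <- function(gt) {
  parts <- strsplit(as.character(gt), "[/|]")
  n <- lengths(parts)
  missing <- vapply(parts, function(p) any(p == "." | p == ""), logical(1L))
  het <- !missing & n == 2L &
    vapply(parts, function(p) length(p) == 2L && p[[1L]] != p[[2L]], logical(1L))
  list(n_alleles = n, missing = missing, het = het)
}

#' X-chromosome heterozygosity for one sample
#'
#' Among diploid genotype calls at X-chromosome sites outside the
#' pseudoautosomal regions, returns the fraction with two different allele
#' calls, excluding missing genotypes from the denominator. Haploid and other
#' non-diploid calls are skipped. Heterozygosity is defined purely by the two
#' allele indices differing, so multi-allelic genotypes such as `1/2` count
#' as heterozygous.
#'
#' @param vcf Path to a VCF (optionally gzipped) or a `VCF` object already
#'   read with `VariantAnnotation::readVcf()`.
#' @param sample_id Sample to evaluate; must be present in the VCF.
#' @param config A [genome_config()].
#' @return Heterozygosity in `[0, 1]`, or `NA` when no non-missing diploid X
#'   genotype exists (a warning is emitted when the VCF has no X sites
#'   at all).
#' @export
compute_xh <- function(vcf, sample_id, config = genome_config()) {
  vcf <- read_vcf_input(vcf)
  if (!sample_id %in% colnames(vcf))
    stop("unknown sample '", sample_id, "' not present in the VCF",
         call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(vcf)))
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
  on_x <- chrom %in% contig_aliases(config$x_name)
  if (!any(on_x)) {
    warning("no X-chromosome sites in VCF; XH is missing", call. = FALSE)
    return(NA_real_)
  }
  in_par <- rep(FALSE, length(pos))
  for (iv in config$par_regions)
    in_par <- in_par | (on_x & pos >= iv$start & pos <= iv$end)
  rows <- which(on_x & !in_par)
  if (length(rows) == 0L) {
    warning("all X-chromosome sites fall in PAR; XH is missing", call. = FALSE)
    return(NA_real_)
  }
  gt <- VariantAnnotation::geno(vcf)$GT[rows, sample_id]
  g <- parse_genotypes(gt)
  informative <- !g$missing & g$n_alleles == 2L
  if (!any(informative)) return(NA_real_)
  sum(g$het[informative]) / sum(informative)
}

#' Mean read depth over the SRY region
#'
#' Mean per-base depth across the configured SRY interval, using the same
#' read filters as [count_mapped_reads()] (primary mapped reads with mapping
#' quality strictly above the cutoff). Uncovered bases count as depth 0; a
#' region with no coverage yields 0.
#'
#' @inheritParams count_mapped_reads
#' @return Mean depth (non-negative real).
#' @export
compute_sry_depth <- function(bam_path, config = genome_config()) {
  check_bam_index(bam_path)
  targets <- names(scanBamHeader(bam_path)[[1L]]$targets)
  contig <- resolve_contig(config$sry_region$contig, targets)
  if (is.na(contig))
    stop("contig mismatch: SRY contig '", config$sry_region$contig,
         "' is absent from the BAM header", call. = FALSE)
  s <- config$sry_region$start
  e <- config$sry_region$end
  which <- GRanges(contig, IRanges(s, e))
  param <- ScanBamParam(flag = hq_flags(), what = "mapq", which = which)
  gal <- readGAlignments(bam_path, param = param)
  gal <- gal[!is.na(mcols(gal)$mapq) & mcols(gal)$mapq > config$mapq_min]
  if (length(gal) == 0L) return(0)
  cvg <- coverage(gal)[[contig]]
  width <- e - s + 1L
  upper <- min(e, length(cvg))
  total <- if (upper >= s) sum(as.numeric(S4Vectors::window(cvg, s, upper))) else 0
  total / width
}

#' Filter a multi-sample VCF
#'
#' Applies genotype- and site-level quality filters: genotypes with depth
#' below the threshold are set missing first, then sites are retained only
#' when the missing-genotype fraction does not exceed the maximum, the minor
#' allele count meets the minimum, and QUAL meets the minimum. Sites with a
#' missing QUAL (`.`) pass the QUAL filter. The minor allele count is the
#' second-largest per-allele count over non-missing called alleles (after the
#' depth mask), which reduces to `min(ref, alt)` at biallelic sites.
#'
#' @param vcf Path to a multi-sample VCF or a `VCF` object.
#' @param filter_config A [variant_filter_config()].
#' @param out_path Optional path to write the filtered VCF.
#' @return Invisibly, the filtered `VCF` object (depth-masked genotypes
#'   included).
#' @export
filter_variants <- function(vcf, filter_config = variant_filter_config(),
                            out_path = NULL) {
  vcf <- read_vcf_input(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  if (is.null(dp)) {
    warning("VCF has no per-genotype DP field; depth filter skipped",
            call. = FALSE)
  } else {
    mask <- !is.na(dp) & dp < filter_config$min_depth
    gt[mask] <- "./."
    VariantAnnotation::geno(vcf)$GT <- gt
  }
  parsed <- apply(gt, 2L, function(col) parse_genotypes(col)$missing)
  miss_mat <- matrix(parsed, nrow = nrow(gt))
  miss_frac <- rowMeans(miss_mat)

  mac <- vapply(seq_len(nrow(gt)), function(i) {
    calls <- gt[i, !miss_mat[i, ]]
    if (length(calls) == 0L) return(0L)
    alleles <- unlist(strsplit(calls, "[/|]"))
    alleles <- alleles[alleles != "." & alleles != ""]
    if (length(alleles) == 0L) return(0L)
    counts <- sort(tabulate(factor(alleles)), decreasing = TRUE)
    if (length(counts) < 2L) 0L else as.integer(counts[[2L]])
  }, integer(1L))

  qual <- VariantAnnotation::qual(vcf)
  keep <- miss_frac <= filter_config$max_missing_fraction &
    mac >= filter_config$min_minor_allele_count &
    (is.na(qual) | qual >= filter_config$min_qual)

  out <- vcf[keep, ]
  if (!is.null(out_path))
    VariantAnnotation::writeVcf(out, out_path)
  invisible(out)
}

compute_bam_features <- function(bam_path, config, sample_id) {
  counts <- count_mapped_reads(bam_path, config, sample_id = sample_id)
  res <- list(Xmap = NA_real_, Ymap = NA_real_, XYratio = NA_real_,
              SRY_dep = NA_real_, errors = list())
  grab <- function(name, expr) {
    val <- tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NA_real_
    })
    res[[name]] <<- as.numeric(val)
  }
  grab("Xmap", compute_xmap(counts, config))
  grab("Ymap", compute_ymap(counts, config))
  if (!is.na(res$Xmap) && !is.na(res$Ymap))
    grab("XYratio", compute_xyratio(res$Xmap, res$Ymap, counts$total_hq))
  grab("SRY_dep", compute_sry_depth(bam_path, config))
  res
}

#' Extract the per-sample feature table from BAM and VCF inputs
#'
#' Runs all feature extractors over a cohort and assembles a
#' [feature_table()]. All features computable from the supplied inputs are
#' stored; features outside `features` are kept in the table but excluded
#' from modeling. A selected feature that cannot be computed for some sample
#' raises a configuration error naming the sample and feature.
#'
#' @param bam_paths Character vector of indexed BAM paths, optionally named
#'   by sample id (defaults to basenames).
#' @param vcf Path to a multi-sample VCF or a `VCF` object; required when
#'   `XH` is selected. Sample names in the VCF must match the BAM sample ids.
#' @param config A [genome_config()].
#' @param features Ordered features to select for modeling.
#' @param workers Number of parallel workers for per-sample extraction; the
#'   output is identical for any worker count.
#'
#' @return A `feature_table`.
#' @export
extract_feature_table <- function(bam_paths,
                                  vcf = NULL,
                                  config = genome_config(),
                                  features = c("XH", FEATURE_NAMES[-1L]),
                                  workers = 1L) {
  features <- match.arg(features, FEATURE_NAMES, several.ok = TRUE)
  sample_ids <- names(bam_paths)
  if (is.null(sample_ids))
    sample_ids <- tools::file_path_sans_ext(basename(bam_paths))
  if ("XH" %in% features && is.null(vcf))
    stop("configuration error: feature 'XH' requires a VCF input",
         call. = FALSE)
  if (!is.null(vcf)) vcf <- read_vcf_input(vcf)

  one_sample <- function(i) {
    sid <- sample_ids[[i]]
    row <- list(sample_id = sid, XH = NA_real_, Xmap = NA_real_,
                Ymap = NA_real_, XYratio = NA_real_, SRY_dep = NA_real_)
    errors <- list()
    bf <- compute_bam_features(bam_paths[[i]], config, sid)
    row[BAM_FEATURES] <- bf[BAM_FEATURES]
    errors <- bf$errors
    if (!is.null(vcf)) {
      xh <- tryCatch(compute_xh(vcf, sid, config), error = function(e) {
        errors[["XH"]] <<- conditionMessage(e)
        NA_real_
      })
      row$XH <- xh
    }
    for (f in features) {
      if (is.na(row[[f]])) {
        why <- if (!is.null(errors[[f]])) errors[[f]] else "value is missing"
        stop("configuration error: selected feature '", f,
             "' unavailable for sample '", sid, "': ", why, call. = FALSE)
      }
    }
    row
  }

  rows <- if (workers > 1L) {
    parallel::mclapply(seq_along(bam_paths), one_sample,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_along(bam_paths), one_sample)
  }
  failed <- vapply(rows, inherits, logical(1L), what = "try-error")
  if (any(failed)) {
    cond <- attr(rows[[which(failed)[1L]]], "condition")
    stop(conditionMessage(cond), call. = FALSE)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[c("sample_id", FEATURE_NAMES)], stringsAsFactors = FALSE)))
  feature_table(df, features)
}

#' Write a feature table to TSV
#'
#' Columns `sample_id XH Xmap Ymap XYratio SRY_dep`, missing values encoded
#' as `NA`, numerics at full (17 significant digit) precision so tables
#' round-trip bit-stably.
#'
#' @param tbl A [feature_table()].
#' @param path Output TSV path.
#' @export
write_feature_table <- function(tbl, path) {
  out <- as.data.frame(tbl)
  for (f in FEATURE_NAMES)
    out[[f]] <- ifelse(is.na(out[[f]]), "NA",
                       formatC(out[[f]], digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' @param path TSV written by [write_feature_table()] (or any TSV with a
#'   `sample_id` column and feature columns).
#' @param features Features to select for modeling; by default, every feature
#'   column with no missing values.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, features = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  if (is.null(features)) {
    present <- FEATURE_NAMES[vapply(FEATURE_NAMES, function(f)
      !is.null(df[[f]]) && !anyNA(df[[f]]), logical(1L))]
    if (length(present) == 0L)
      stop("no fully observed feature column in ", path, call. = FALSE)
    features <- present
  }
  feature_table(df, features)
}
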