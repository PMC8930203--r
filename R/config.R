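#' Genome configuration for feature extraction
#'
#' Describes how sex-chromosome features are located on the reference the
#' BAM/VCF inputs were aligned to: the X and Y contig names, the SRY interval
#' on Y whose mean depth is used as a male indicator, the pseudoautosomal
#' regions (PAR) excluded from X heterozygosity, and the mapping-quality
#' cutoff defining a "high-quality" read.
#'
#' Defaults target a GRCh37-style reference: SRY at Y:2,654,896-2,655,740 and
#' the two X PARs (PAR1 X:60,001-2,699,520; PAR2 X:154,931,044-155,260,560).
#' PAR sites are diploid in males and would inflate male X heterozygosity,
#' hence the exclusion. Both "X"/"Y" and "chrX"/"chrY" naming dialects are
#' resolved automatically against each file's header.
#'
#' @param x_name,y_name Chromosome labels for X and Y.
#' @param sry_region Named list with `contig`, `start`, `end` (1-based,
#'   closed) locating the SRY gene on the Y chromosome.
#' @param par_regions List of intervals (each a list with `contig`, `start`,
#'   `end`, 1-based closed) on X excluded from heterozygosity; set to
#'   `list()` to disable PAR masking.
#' @param mapq_min Reads must have mapping quality strictly greater than this
#'   to count as high-quality (default 30).
#'
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(x_name = "X",
                          y_name = "Y",
                          sry_region = list(contig = "Y", start = 2654896L, end = 2655740L),
                          par_regions = list(
                            list(contig = "X", start = 60001L, end = 2699520L),
                            list(contig = "X", start = 154931044L, end = 155260560L)
                          ),
                          mapq_min = 30L) {
  stopifnot(is.character(x_name), length(x_name) == 1L,
            is.character(y_name), length(y_name) == 1L)
  mapq_min <- as.integer(mapq_min)
  if (is.na(mapq_min) || mapq_min < 0L)
    stop("mapq_min must be a non-negative integer", call. = FALSE)
  check_interval <- function(iv, what) {
    if (!all(c("contig", "start", "end") %in% names(iv)))
      stop(what, " must have fields contig, start, end", call. = FALSE)
    if (iv$start > iv$end)
      stop(what, " has start > end", call. = FALSE)
    iv$start <- as.integer(iv$start); iv$end <- as.integer(iv$end)
    iv
  }
  sry_region <- check_interval(sry_region, "sry_region")
  if (!contig_matches(sry_region$contig, y_name))
    stop("sry_region must lie on the Y chromosome (", y_name, ")", call. = FALSE)
  par_regions <- lapply(par_regions, check_interval, what = "par_regions entry")
  for (iv in par_regions)
    if (!contig_matches(iv$contig, x_name))
      stop("par_regions must lie on the X chromosome (", x_name, ")", call. = FALSE)
  structure(
    list(x_name = x_name, y_name = y_name, sry_region = sry_region,
         par_regions = par_regions, mapq_min = mapq_min),
    class = "genome_config"
  )
}

#' Variant filtering thresholds
#'
#' Site- and genotype-level thresholds applied before X heterozygosity is
#' computed: genotypes below `min_depth` are set missing, then sites are
#' dropped when more than `max_missing_fraction` of genotypes are missing,
#' the minor allele count falls below `min_minor_allele_count`, or QUAL falls
#' below `min_qual`.
#'
#' @param max_missing_fraction Sites with a missing-genotype fraction
#'   strictly greater than this are removed (default 0.5).
#' @param min_minor_allele_count Sites with minor allele count strictly below
#'   this are removed (default 3).
#' @param min_qual Sites with QUAL strictly below this are removed
#'   (default 30).
#' @param min_depth Genotypes with depth strictly below this are set missing
#'   (default 5).
#'
#' @return An object of class `variant_filter_config`.
#' @export
variant_filter_config <- function(max_missing_fraction = 0.5,
                                  min_minor_allele_count = 3L,
                                  min_qual = 30,
                                  min_depth = 5L) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must lie in [0, 1]", call. = FALSE)
  if (min_minor_allele_count < 0 || min_qual < 0 || min_depth < 0)
    stop("filter thresholds must be non-negative", call. = FALSE)
  structure(
    list(max_missing_fraction = max_missing_fraction,
         min_minor_allele_count = as.integer(min_minor_allele_count),
         min_qual = min_qual,
         min_depth = as.integer(min_depth)),
    class = "variant_filter_config"
  )
}

#' Karyotype gate configuration
#'
#' Multipliers defining the six karyotype gates on the (Xmap, Ymap) plane.
#' Normal bands are mean +/- `sd_multiplier` * sd per sex; aneuploidy gates
#' are fold-changes of cohort means: XYY requires Ymap > `xyy_y_mult` times
#' the male mean, XXY requires Xmap > `xxy_x_mult` times the female mean,
#' XXX requires Xmap > `xxx_x_mult` times the female mean, and X monosomy
#' requires Xmap < `x_monosomy_mult` times the female mean. Gates are
#' evaluated in the fixed precedence order XX, XY, XYY, XXY, XXX, X.
#'
#' @param sd_multiplier Width of the normal bands in standard deviations
#'   (default 3, the empirical three-sigma rule).
#' @param xyy_y_mult,xxy_x_mult,xxx_x_mult,x_monosomy_mult Fold-change
#'   thresholds (defaults 2, 2, 3, 0.5).
#'
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(sd_multiplier = 3,
                        xyy_y_mult = 2,
                        xxy_x_mult = 2,
                        xxx_x_mult = 3,
                        x_monosomy_mult = 0.5) {
  vals <- c(sd_multiplier, xyy_y_mult, xxy_x_mult, xxx_x_mult, x_monosomy_mult)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all gate multipliers must be positive", call. = FALSE)
  structure(
    list(sd_multiplier = sd_multiplier, xyy_y_mult = xyy_y_mult,
         xxy_x_mult = xxy_x_mult, xxx_x_mult = xxx_x_mult,
         x_monosomy_mult = x_monosomy_mult),
    class = "gate_config"
  )
}

# "X" and "chrX" refer to the same contig in mixed-reference inputs
contig_aliases <- function(name) {
  if (startsWith(name, "chr")) unique(c(name, sub("^chr", "", name)))
  else unique(c(name, paste0("chr", name)))
}

contig_matches <- function(a, b) a %in% contig_aliases(b)

# Resolve a configured contig name against the names present in a file
# header; returns NA_character_ when no dialect matches.
resolve_contig <- function(name, available) {
  hits <- intersect(contig_aliases(name), available)
  if (length(hits) == 0L) NA_character_ else hits[[1L]]
}

#' @export
print.genome_config <- function(x, ...) {
  cat("Genome configuration\n")
  cat("  X contig: ", x$x_name, "   Y contig: ", x$y_name, "\n", sep = "")
  cat("  SRY region: ", x$sry_region$contig, ":", x$sry_region$start, "-",
      x$sry_region$end, "\n", sep = "")
  cat("  PAR regions excluded from XH: ", length(x$par_regions), "\n", sep = "")
  cat("  high-quality reads: mapq > ", x$mapq_min, "\n", sep = "")
  invisible(x)
}
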