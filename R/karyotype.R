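KARYOTYPES <- c("XX", "XY", "XYY", "XXY", "XXX", "X")

#' Per-sex cohort statistics of Xmap and Ymap
#'
#' Sample means and standard deviations of the X and Y read-mapping fractions
#' in the genetically determined male and female samples; suffixes `m` and
#' `f` denote males and females. These statistics anchor the karyotype gates.
#' Mixture-model outliers are excluded by default so that ambiguous samples
#' do not inflate the per-sex standard deviations.
#'
#' @param tbl A [feature_table()] with non-missing `Xmap` and `Ymap`.
#' @param calls `sex_calls` from [assign_sexes()] aligned with `tbl`.
#' @param exclude_outliers Drop uncertainty-flagged samples before computing
#'   the statistics (default TRUE).
#'
#' @return A `sex_stats` object with fields `mean_xmap_m`, `sd_xmap_m`,
#'   `mean_ymap_m`, `sd_ymap_m`, `mean_xmap_f`, `sd_xmap_f`, `mean_ymap_f`,
#'   `sd_ymap_f`, `n_m`, `n_f`.
#' @export
cohort_stats <- function(tbl, calls, exclude_outliers = TRUE) {
  stopifnot(inherits(tbl, "feature_table"))
  df <- merge(as.data.frame(tbl), as.data.frame(calls), by = "sample_id")
  if (anyNA(df$Xmap) || anyNA(df$Ymap))
    stop("Xmap and Ymap must be present for every sample", call. = FALSE)
  if (exclude_outliers) df <- df[!df$outlier, , drop = FALSE]
  m <- df[df$sex == "male", , drop = FALSE]
  f <- df[df$sex == "female", , drop = FALSE]
  if (nrow(m) < 2L || nrow(f) < 2L)
    stop("insufficient cohort: need at least 2 non-outlier samples per sex ",
         "(males: ", nrow(m), ", females: ", nrow(f), ")", call. = FALSE)
  sex_stats(
    mean_xmap_m = mean(m$Xmap), sd_xmap_m = stats::sd(m$Xmap),
    mean_ymap_m = mean(m$Ymap), sd_ymap_m = stats::sd(m$Ymap),
    mean_xmap_f = mean(f$Xmap), sd_xmap_f = stats::sd(f$Xmap),
    mean_ymap_f = mean(f$Ymap), sd_ymap_f = stats::sd(f$Ymap),
    n_m = nrow(m), n_f = nrow(f)
  )
}

#' Construct per-sex Xmap/Ymap statistics directly
#'
#' Useful for applying the karyotype gates with externally supplied cohort
#' statistics (e.g. from a previous run or a published cohort) instead of
#' recomputing them.
#'
#' @param mean_xmap_m,sd_xmap_m,mean_ymap_m,sd_ymap_m Male statistics.
#' @param mean_xmap_f,sd_xmap_f,mean_ymap_f,sd_ymap_f Female statistics.
#' @param n_m,n_f Sample counts behind the statistics (optional).
#' @return A `sex_stats` object.
#' @export
sex_stats <- function(mean_xmap_m, sd_xmap_m, mean_ymap_m, sd_ymap_m,
                      mean_xmap_f, sd_xmap_f, mean_ymap_f, sd_ymap_f,
                      n_m = NA_integer_, n_f = NA_integer_) {
  vals <- c(mean_xmap_m, sd_xmap_m, mean_ymap_m, sd_ymap_m,
            mean_xmap_f, sd_xmap_f, mean_ymap_f, sd_ymap_f)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("sex statistics must be finite and non-negative", call. = FALSE)
  structure(
    list(mean_xmap_m = mean_xmap_m, sd_xmap_m = sd_xmap_m,
         mean_ymap_m = mean_ymap_m, sd_ymap_m = sd_ymap_m,
         mean_xmap_f = mean_xmap_f, sd_xmap_f = sd_xmap_f,
         mean_ymap_f = mean_ymap_f, sd_ymap_f = sd_ymap_f,
         n_m = n_m, n_f = n_f),
    class = "sex_stats"
  )
}

#' Read/write sex statistics as TSV
#'
#' @param path TSV with one header row and one value row over the
#'   `sex_stats` fields.
#' @return A `sex_stats` object.
#' @export
read_sex_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  do.call(sex_stats, as.list(df[1L, , drop = FALSE]))
}

#' @rdname read_sex_stats
#' @param stats A `sex_stats` object to write.
#' @export
write_sex_stats <- function(stats, path) {
  df <- as.data.frame(unclass(stats))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

in_band <- function(v, center, sd, mult) {
  v > center - mult * sd & v < center + mult * sd
}

# All six gates for one (x, y) point; returns the named logical vector in
# precedence order XX, XY, XYY, XXY, XXX, X. All inequalities are strict.
evaluate_gates <- function(x, y, stats, cfg) {
  s <- cfg$sd_multiplier
  male_x <- in_band(x, stats$mean_xmap_m, stats$sd_xmap_m, s)
  male_y <- in_band(y, stats$mean_ymap_m, stats$sd_ymap_m, s)
  female_x <- in_band(x, stats$mean_xmap_f, stats$sd_xmap_f, s)
  female_y <- in_band(y, stats$mean_ymap_f, stats$sd_ymap_f, s)
  c(
    XX = female_x && female_y,
    XY = male_x && male_y,
    XYY = male_x && y > cfg$xyy_y_mult * stats$mean_ymap_m,
    XXY = x > cfg$xxy_x_mult * stats$mean_xmap_f && male_y,
    XXX = x > cfg$xxx_x_mult * stats$mean_xmap_f && female_y,
    X = x < cfg$x_monosomy_mult * stats$mean_xmap_f && female_y
  )
}

#' Classify the sex-chromosome karyotype of one sample
#'
#' Evaluates the six gates on the raw (unscaled) Xmap/Ymap point: the XX and
#' XY gates are the per-sex mean +/- 3 sd bands in both coordinates; XYY is
#' the male X band with Ymap above twice the male mean; XXY is Xmap above
#' twice the female mean with a male-band Ymap; XXX is Xmap above three times
#' the female mean with a female-band Ymap; X monosomy is Xmap below half the
#' female mean with a female-band Ymap. The first matching gate in the
#' precedence order XX, XY, XYY, XXY, XXX, X is reported; a sample matching
#' no gate is `UNCLASSIFIED` and should be confirmed by karyotyping.
#'
#' @param x,y Xmap and Ymap of the sample (raw fractions).
#' @param stats A `sex_stats` object.
#' @param config A [gate_config()].
#' @param sample_id Optional identifier carried into the result.
#'
#' @return A `karyotype_call` list: `sample_id`, `karyotype`,
#'   `gates_matched` (character vector in precedence order), `xmap`, `ymap`.
#' @export
classify_karyotype <- function(x, y, stats, config = gate_config(),
                               sample_id = NA_character_) {
  if (!is.finite(x) || !is.finite(y))
    stop("Xmap and Ymap must be finite to classify a karyotype",
         call. = FALSE)
  gates <- evaluate_gates(x, y, stats, config)
  matched <- names(gates)[gates]
  structure(
    list(sample_id = sample_id,
         karyotype = if (length(matched)) matched[[1L]] else "UNCLASSIFIED",
         gates_matched = matched, xmap = x, ymap = y),
    class = "karyotype_call"
  )
}

#' Karyotype report for a cohort
#'
#' Computes a karyotype call for every sample and summarizes the cohort:
#' counts per karyotype and the list of abnormal (non-XX/XY) samples with the
#' Xmap/Ymap values and gate that triggered them.
#'
#' @param tbl A [feature_table()] with `Xmap` and `Ymap` present.
#' @param stats A `sex_stats` object (e.g. from [cohort_stats()]).
#' @param config A [gate_config()].
#'
#' @return A list of class `karyotype_report` with `calls` (data.frame:
#'   `sample_id`, `karyotype`, `gates_matched`, `xmap`, `ymap`), `summary`
#'   (data.frame: `karyotype`, `n`), and `abnormal` (subset of `calls`).
#' @export
karyotype_report <- function(tbl, stats, config = gate_config()) {
  stopifnot(inherits(tbl, "feature_table"))
  if (anyNA(tbl$Xmap) || anyNA(tbl$Ymap))
    stop("Xmap and Ymap must be present for every sample", call. = FALSE)
  calls <- lapply(seq_len(nrow(tbl)), function(i)
    classify_karyotype(tbl$Xmap[[i]], tbl$Ymap[[i]], stats, config,
                       sample_id = tbl$sample_id[[i]]))
  df <- data.frame(
    sample_id = vapply(calls, `[[`, character(1L), "sample_id"),
    karyotype = vapply(calls, `[[`, character(1L), "karyotype"),
    gates_matched = vapply(calls, function(k)
      paste(k$gates_matched, collapse = ","), character(1L)),
    xmap = vapply(calls, `[[`, numeric(1L), "xmap"),
    ymap = vapply(calls, `[[`, numeric(1L), "ymap"),
    stringsAsFactors = FALSE
  )
  lev <- c(KARYOTYPES, "UNCLASSIFIED")
  counts <- table(factor(df$karyotype, levels = lev))
  summary <- data.frame(karyotype = lev, n = as.integer(counts),
                        stringsAsFactors = FALSE)
  summary <- summary[summary$n > 0L, , drop = FALSE]
  rownames(summary) <- NULL
  abnormal <- df[!df$karyotype %in% c("XX", "XY"), , drop = FALSE]
  structure(list(calls = df, summary = summary, abnormal = abnormal),
            class = "karyotype_report")
}

#' @export
print.karyotype_report <- function(x, ...) {
  cat("Karyotype report:", nrow(x$calls), "samples\n")
  print(x$summary, row.names = FALSE)
  if (nrow(x$abnormal)) {
    cat("abnormal samples:\n")
    print(x$abnormal, row.names = FALSE)
  } else {
    cat("no abnormal samples\n")
  }
  invisible(x)
}

#' Write the per-sample karyotype calls and cohort summary as TSV
#'
#' @param report A `karyotype_report`.
#' @param calls_path,summary_path Output TSV paths (`NULL` to skip either).
#' @export
write_karyotype_report <- function(report, calls_path, summary_path = NULL) {
  if (!is.null(calls_path))
    utils::write.table(report$calls, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.table(report$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(report)
}
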