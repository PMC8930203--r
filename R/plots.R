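#' Scatter plot of samples in the discriminant subspace
#'
#' Projects the scaled features onto the direction best separating the two
#' fitted components (the Fisher-style discriminant of the pooled-covariance
#' fit) and an orthogonal residual axis, colored by inferred sex with
#' outliers marked.
#'
#' @param fit A `mixture_fit` from [fit_gmm()].
#' @param scaled A `scaled_features` object (the input to the fit).
#' @param calls `sex_calls` from [assign_sexes()].
#' @return A ggplot object.
#' @export
plot_sex_clusters <- function(fit, scaled, calls) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  x <- scaled$x
  pooled <- Reduce(`+`, Map(`*`, fit$covariances, fit$weights))
  dir1 <- solve(pooled, fit$means[2L, ] - fit$means[1L, ])
  dir1 <- dir1 / sqrt(sum(dir1^2))
  d1 <- as.numeric(x %*% dir1)
  resid <- x - outer(d1, dir1)
  d2 <- if (ncol(x) > 1L) stats::prcomp(resid, center = FALSE)$x[, 1L]
        else rep(0, nrow(x))
  df <- data.frame(dir1 = d1, dir2 = as.numeric(d2), sex = calls$sex,
                   outlier = calls$outlier)
  ggplot2::ggplot(df, ggplot2::aes(x = dir1, y = dir2,
                                   color = sex,
                                   shape = outlier)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Dir1 (discriminant)", y = "Dir2", color = "sex",
                  shape = "outlier") +
    ggplot2::theme_minimal()
}

#' Xmap-vs-Ymap scatter with karyotype gate boundaries
#'
#' Shows every sample on the raw (Xmap, Ymap) plane, with the per-sex normal
#' bands drawn as rectangles and the XYY fold-change threshold as a line,
#' colored by called karyotype.
#'
#' @param report A `karyotype_report`.
#' @param stats The `sex_stats` used for the gates.
#' @param config The [gate_config()] used.
#' @return A ggplot object.
#' @export
plot_karyotype_gates <- function(report, stats, config = gate_config()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  s <- config$sd_multiplier
  bands <- data.frame(
    sex = c("XY band", "XX band"),
    xmin = c(stats$mean_xmap_m - s * stats$sd_xmap_m,
             stats$mean_xmap_f - s * stats$sd_xmap_f),
    xmax = c(stats$mean_xmap_m + s * stats$sd_xmap_m,
             stats$mean_xmap_f + s * stats$sd_xmap_f),
    ymin = c(stats$mean_ymap_m - s * stats$sd_ymap_m,
             stats$mean_ymap_f - s * stats$sd_ymap_f),
    ymax = c(stats$mean_ymap_m + s * stats$sd_ymap_m,
             stats$mean_ymap_f + s * stats$sd_ymap_f)
  )
  ggplot2::ggplot(report$calls) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = xmin, xmax = xmax,
                                    ymin = ymin, ymax = ymax),
                       fill = NA, color = "grey40", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = config$xyy_y_mult * stats$mean_ymap_m,
                        color = "firebrick", linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(x = xmap, y = ymap,
                                     color = karyotype), alpha = 0.8) +
    ggplot2::labs(x = "Xmap", y = "Ymap", color = "karyotype") +
    ggplot2::theme_minimal()
}
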