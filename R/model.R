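#' Scale selected features to zero mean and unit variance
#'
#' Centers each selected feature column to mean 0 and scales it to sample
#' standard deviation 1, so that features on very different scales (e.g.
#' SRY depth in the tens vs Ymap near 1e-4) contribute comparably to the
#' mixture model.
#'
#' @param tbl A [feature_table()] with at least two samples and no missing
#'   values among the selected features.
#' @return A list with `x` (scaled matrix, rownames = sample ids), `center`
#'   and `scale` (per-feature parameters), of class `scaled_features`.
#' @export
scale_features <- function(tbl) {
  feats <- selected_features(tbl)
  if (nrow(tbl) < 2L)
    stop("scaling requires at least 2 samples", call. = FALSE)
  x <- as.matrix(as.data.frame(tbl)[, feats, drop = FALSE])
  rownames(x) <- tbl$sample_id
  if (anyNA(x))
    stop("selected features contain missing values", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate feature(s) with zero variance: ",
         paste(feats[sds == 0], collapse = ", "), call. = FALSE)
  scaled <- scale(x)
  structure(
    list(x = scaled[, , drop = FALSE],
         center = attr(scaled, "scaled:center"),
         scale = attr(scaled, "scaled:scale")),
    class = "scaled_features"
  )
}

# log N(x | mu, sigma) for all rows of x, via Cholesky
mvn_logdensity <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  centered <- sweep(x, 2L, mu)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Posterior responsibilities and log-likelihood given current parameters
gmm_e_step <- function(x, weights, means, covariances) {
  k <- length(weights)
  logd <- vapply(seq_len(k), function(j)
    mvn_logdensity(x, means[j, ], covariances[[j]]) + log(weights[[j]]),
    numeric(nrow(x)))
  ll_rows <- logsumexp_rows(logd)
  resp <- exp(logd - ll_rows)
  list(resp = resp, loglik = sum(ll_rows))
}

gmm_m_step <- function(x, resp, ridge) {
  n <- nrow(x); d <- ncol(x); k <- ncol(resp)
  nk <- colSums(resp)
  weights <- nk / n
  means <- (t(resp) %*% x) / nk
  covariances <- lapply(seq_len(k), function(j) {
    centered <- sweep(x, 2L, means[j, ])
    sig <- crossprod(centered * resp[, j], centered) / nk[[j]]
    sig + diag(ridge, d)
  })
  list(weights = weights, means = means, covariances = covariances)
}

run_em_once <- function(x, k, seed, max_iter, tol, ridge) {
  set.seed(seed)
  n <- nrow(x)
  km <- tryCatch(stats::kmeans(x, centers = k, nstart = 1L),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  # guard against an (almost) empty component at initialization
  resp <- (resp + 1e-6) / rowSums(resp + 1e-6)
  params <- gmm_m_step(x, resp, ridge)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    e <- tryCatch(gmm_e_step(x, params$weights, params$means, params$covariances),
                  error = function(err) NULL)
    if (is.null(e) || !is.finite(e$loglik)) return(NULL)
    trace <- c(trace, e$loglik)
    if (iter > 1L && abs(e$loglik - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- e$loglik
    params <- gmm_m_step(x, e$resp, ridge)
  }
  list(weights = params$weights, means = params$means,
       covariances = params$covariances, responsibilities = e$resp,
       loglik_trace = trace, converged = converged)
}

#' Fit a two-component Gaussian mixture by expectation-maximization
#'
#' Full per-component covariances with a small diagonal ridge keep the fit
#' well-posed even when one cluster is nearly degenerate in a feature (male
#' X heterozygosity is exactly 0 for most males on panels). Multiple random
#' restarts with k-means initialization are run and the fit with the best
#' final log-likelihood is kept; results are deterministic given `seed`.
#'
#' @param x Scaled feature matrix (samples x features), e.g.
#'   `scale_features(tbl)$x`.
#' @param k Number of components (default 2: one per sex).
#' @param seed Integer seed; fans out deterministically to restart seeds.
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-8).
#' @param ridge Diagonal ridge added to each covariance (default 1e-6).
#' @param n_restarts Number of random restarts (default 10).
#'
#' @return A `mixture_fit`: `weights`, `means` (k x d), `covariances` (list
#'   of k matrices), `responsibilities` (n x k posterior matrix, rownames =
#'   sample ids), `loglik_trace`, `seed`, `converged`.
#' @export
fit_gmm <- function(x, k = 2L, seed = 1L, max_iter = 500L, tol = 1e-8,
                    ridge = 1e-6, n_restarts = 10L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L * k)
    stop("need at least ", 2L * k, " samples to fit ", k, " components",
         call. = FALSE)
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, n_restarts)
  best <- NULL
  traces <- list()
  for (rs in restart_seeds) {
    fit <- run_em_once(x, k, rs, max_iter, tol, ridge)
    if (is.null(fit)) next
    traces[[length(traces) + 1L]] <- fit$loglik_trace
    ll <- fit$loglik_trace[[length(fit$loglik_trace)]]
    if (is.null(best) || ll > best$loglik_trace[[length(best$loglik_trace)]])
      best <- fit
  }
  if (is.null(best)) {
    cond <- structure(
      class = c("gmm_convergence_error", "error", "condition"),
      list(message = "EM failed to converge in every restart",
           call = sys.call(), traces = traces))
    stop(cond)
  }
  rownames(best$responsibilities) <- rownames(x)
  structure(
    c(best, list(seed = seed, k = k, ridge = ridge)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit:", x$k, "components,",
      nrow(x$responsibilities), "samples\n")
  cat("  weights:", signif(x$weights, 4), "\n")
  cat("  log-likelihood:", x$loglik_trace[[length(x$loglik_trace)]],
      "after", length(x$loglik_trace), "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

# Decide which mixture component is male from the unscaled per-cluster
# feature means, trying the most biologically decisive feature first:
# higher Ymap -> male; higher SRY_dep -> male; higher XYratio -> female;
# lower XH -> male; lower Xmap -> male.
label_clusters <- function(fit, tbl) {
  cluster <- max.col(fit$responsibilities)
  feats <- selected_features(tbl)
  df <- as.data.frame(tbl)
  cluster_mean <- function(f, cl) mean(df[[f]][cluster == cl])
  rules <- list(
    list(feature = "Ymap", male_is = "higher"),
    list(feature = "SRY_dep", male_is = "higher"),
    list(feature = "XYratio", male_is = "lower"),
    list(feature = "XH", male_is = "lower"),
    list(feature = "Xmap", male_is = "lower")
  )
  for (r in rules) {
    f <- r$feature
    if (!f %in% feats) next
    if (!all(1:2 %in% cluster)) break  # one empty cluster: no means to compare
    m1 <- cluster_mean(f, 1L)
    m2 <- cluster_mean(f, 2L)
    if (is.na(m1) || is.na(m2) || m1 == m2) next
    male_cluster <- if (r$male_is == "higher") {
      if (m1 > m2) 1L else 2L
    } else {
      if (m1 < m2) 1L else 2L
    }
    return(male_cluster)
  }
  stop("labeling error: no selected feature separates the cluster means",
       call. = FALSE)
}

#' Assign sexes from a fitted mixture
#'
#' Each sample is assigned to its higher-posterior component; components are
#' mapped to sexes from the unscaled per-cluster feature means (higher Ymap
#' means male, falling back through SRY depth, XY ratio, XH, and Xmap for
#' panels lacking Y content). Uncertainty is 1 minus the maximum posterior;
#' samples whose uncertainty exceeds the threshold are flagged as outliers.
#'
#' @param fit A `mixture_fit` from [fit_gmm()].
#' @param tbl The [feature_table()] the fit was computed from (same row
#'   order).
#' @param threshold Uncertainty threshold for the outlier flag (default 0.1).
#'
#' @return A `sex_calls` data.frame: `sample_id`, `sex` ("male"/"female"),
#'   `uncertainty`, `outlier`.
#' @export
assign_sexes <- function(fit, tbl, threshold = 0.1) {
  stopifnot(inherits(fit, "mixture_fit"), inherits(tbl, "feature_table"))
  if (nrow(fit$responsibilities) != nrow(tbl))
    stop("fit and feature table are not aligned", call. = FALSE)
  male_cluster <- label_clusters(fit, tbl)
  cluster <- max.col(fit$responsibilities)
  maxpost <- fit$responsibilities[cbind(seq_len(nrow(tbl)), cluster)]
  uncertainty <- 1 - maxpost
  calls <- data.frame(
    sample_id = tbl$sample_id,
    sex = ifelse(cluster == male_cluster, "male", "female"),
    uncertainty = uncertainty,
    outlier = uncertainty > threshold,
    stringsAsFactors = FALSE
  )
  structure(calls, class = c("sex_calls", "data.frame"))
}

#' Infer the sex of a single sample against a reference cohort
#'
#' Small batches (or single samples) cannot support unsupervised clustering,
#' so the sample is appended to a reference feature table analyzed with the
#' same features, the combined table is rescaled and refit, and the sample's
#' call is returned. By construction this is exactly the cohort-mode result
#' on reference + sample.
#'
#' @param sample A one-row data.frame (or list) with `sample_id` and the
#'   reference's selected features.
#' @param reference A [feature_table()] of reference samples.
#' @param seed Seed passed to [fit_gmm()].
#' @param threshold Uncertainty threshold for the outlier flag.
#' @param ... Further arguments to [fit_gmm()].
#'
#' @return A one-row `sex_calls` data.frame for the submitted sample.
#' @export
infer_single_sample <- function(sample, reference, seed = 1L,
                                threshold = 0.1, ...) {
  stopifnot(inherits(reference, "feature_table"))
  feats <- selected_features(reference)
  sample <- as.data.frame(as.list(sample), stringsAsFactors = FALSE)
  missing_in_sample <- feats[!vapply(feats, function(f)
    !is.null(sample[[f]]) && !is.na(sample[[f]]), logical(1L))]
  if (length(missing_in_sample))
    stop("configuration error: sample lacks reference feature(s): ",
         paste(missing_in_sample, collapse = ", "), call. = FALSE)
  for (f in FEATURE_NAMES) if (is.null(sample[[f]])) sample[[f]] <- NA_real_
  combined <- rbind(as.data.frame(reference),
                    sample[, c("sample_id", FEATURE_NAMES)])
  tbl <- feature_table(combined, feats)
  sc <- scale_features(tbl)
  fit <- fit_gmm(sc$x, seed = seed, ...)
  calls <- assign_sexes(fit, tbl, threshold = threshold)
  calls[calls$sample_id == sample$sample_id, , drop = FALSE]
}
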