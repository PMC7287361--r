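#' Reduce the four CRQA metrics to one synchrony component
#'
#' Standardises the four recurrence metrics across all dyad-blocks,
#' eigendecomposes their correlation matrix and scores the first principal
#' component. The component sign is fixed so the loading sum is positive
#' (higher score = more synchrony) and scores are standardised.
#'
#' @param metrics Data frame from [crqa_dataset()] (or any table with the
#'   four metric columns).
#' @param metric_cols Names of the metric columns entering the PCA. The
#'   entropy enters as the raw Shannon entropy of the diagonal line-length
#'   histogram (`entr`): the normalised variant (`rentr`) divides by the
#'   log of the number of distinct line lengths, a denominator that itself
#'   grows under strong coupling and in synthetic data inverts the
#'   metric's relation to it; both are reported by [crqa_dataset()].
#' @return List of class `synchrony_pca`: `scores` (the input table plus a
#'   standardised `pc1` column), `loadings` (unit-norm, per component),
#'   `variance_explained` (proportions, all components), `metric_cols`.
#' @export
pca_synchrony <- function(metrics,
                          metric_cols = c("det", "lam", "maxl", "entr")) {
  stopifnot(is.data.frame(metrics), all(metric_cols %in% names(metrics)))
  if (nrow(metrics) < 5L) {
    stop("need at least 5 dyad-block rows for a stable PCA, got ",
         nrow(metrics))
  }
  X <- as.matrix(metrics[, metric_cols])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant metric column(s): ",
         paste(metric_cols[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  ve <- eig$values / sum(eig$values)
  loadings <- eig$vectors
  rownames(loadings) <- metric_cols
  ## sign convention: PC1 points toward "more synchrony on all metrics"
  for (k in seq_len(ncol(loadings))) {
    if (sum(loadings[, k]) < 0) loadings[, k] <- -loadings[, k]
  }
  pc1 <- as.numeric(Z %*% loadings[, 1L])
  scores <- metrics
  scores$pc1 <- as.numeric(scale(pc1))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, metric_cols = metric_cols),
            class = "synchrony_pca")
}

#' @export
print.synchrony_pca <- function(x, ...) {
  cat("Synchrony PCA over", paste(x$metric_cols, collapse = ", "), "\n")
  cat(sprintf("  PC1 variance explained: %.1f%%\n",
              100 * x$variance_explained[1]))
  cat("  PC1 loadings:",
      paste(sprintf("%s %.2f", x$metric_cols, x$loadings[, 1]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Best time-lagged correlation between demonstrator and observer
#'
#' Pearson correlation of the two preprocessed learning-phase series with
#' the observer shifted later by 0..`max_lag_s` seconds (integer samples,
#' overlap-restricted, no wraparound); returns the maximum and its lag.
#' Positive lags only: the observer reacts after the demonstrator.
#'
#' @param demo_trace,obs_trace Preprocessed [eda_trace()]s, equal rate.
#' @param max_lag_s Largest observer delay considered, seconds.
#' @return List with `r` (maximum correlation) and `lag_s` (its lag).
#' @export
lagged_correlation <- function(demo_trace, obs_trace, max_lag_s = 10) {
  stopifnot(inherits(demo_trace, "eda_trace"),
            inherits(obs_trace, "eda_trace"),
            demo_trace$sample_rate == obs_trace$sample_rate)
  fs <- demo_trace$sample_rate
  x <- demo_trace$values
  y <- obs_trace$values
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  max_lag <- as.integer(floor(max_lag_s * fs))
  if (n - max_lag < 8L) {
    stop("overlap at the maximum lag would be under 8 samples (n = ", n,
         ", max lag = ", max_lag, " samples)")
  }
  best_r <- -Inf; best_lag <- 0L
  for (lag in 0:max_lag) {
    ## observer shifted later: y[t + lag] aligned with x[t]
    r <- stats::cor(x[seq_len(n - lag)], y[seq_len(n - lag) + lag])
    if (r > best_r) { best_r <- r; best_lag <- lag }
  }
  list(r = best_r, lag_s = best_lag / fs)
}

#' Learning-phase CS differentiation
#'
#' Mean transformed observer response to CS+ minus CS- during the
#' learning phase — the "early differentiation" alternative predictor.
#'
#' @param trials A learning-phase trial table from [score_phase()].
#' @return Amplitude difference (transformed units).
#' @export
learning_csdiff <- function(trials) {
  plus <- trials$amplitude_tx[trials$cs == "plus"]
  minus <- trials$amplitude_tx[trials$cs == "minus"]
  if (!length(plus) || !length(minus)) {
    stop("trial table must contain both CS+ and CS- presentations")
  }
  mean(plus) - mean(minus)
}

#' Synchrony component and alternative predictors for a whole dataset
#'
#' Runs the PCA over the CRQA metrics table and, per dyad-block, computes
#' the three non-synchrony predictors from the learning phase: mean UCS
#' response, learning-phase CS differentiation, and the best time-lagged
#' demonstrator-observer correlation.
#'
#' @param dataset A `dyad_dataset`.
#' @param metrics CRQA metrics table from [crqa_dataset()].
#' @param pre_cfg A [preprocess_config()].
#' @param max_lag_s Lag range for the lagged correlation, seconds.
#' @return List of class `synchrony_scores`: `scores` (metrics table plus
#'   `pc1`, `alt_ucs_mean`, `alt_learn_csdiff`, `alt_lagged_r`,
#'   `alt_lagged_lag_s`) and `pca` (the [pca_synchrony()] result).
#' @export
build_predictors <- function(dataset, metrics,
                             pre_cfg = preprocess_config(),
                             max_lag_s = 10) {
  pca <- pca_synchrony(metrics)
  sc <- pca$scores
  sc$alt_ucs_mean <- NA_real_
  sc$alt_learn_csdiff <- NA_real_
  sc$alt_lagged_r <- NA_real_
  sc$alt_lagged_lag_s <- NA_real_
  tf <- pre_cfg$transform
  for (i in seq_len(nrow(sc))) {
    dy <- dataset$dyads[[sc$dyad_id[i]]]
    bl <- dy$blocks[[sc$block[i]]]
    ucs <- ucs_responses(bl$obs_learning, bl$schedule, pre_cfg)
    sc$alt_ucs_mean[i] <- apply_transform(ucs$mean, tf)
    lt <- score_phase(bl$obs_learning, bl$schedule, pre_cfg)
    sc$alt_learn_csdiff[i] <- learning_csdiff(lt)
    lc <- lagged_correlation(prepare_crqa_series(bl$demo_learning, pre_cfg),
                             prepare_crqa_series(bl$obs_learning, pre_cfg),
                             max_lag_s)
    sc$alt_lagged_r[i] <- lc$r
    sc$alt_lagged_lag_s[i] <- lc$lag_s
  }
  structure(list(scores = sc, pca = pca), class = "synchrony_scores")
}
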