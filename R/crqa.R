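#' CRQA settings
#'
#' Parameters of the cross-recurrence pipeline. The recurrence radius is
#' not set here: it is calibrated per dyad so the recurrence rate lands in
#' `target_band` (the conventional 2-4% density window).
#'
#' @param target_band Length-2 recurrence-rate band the radius calibration
#'   must reach (proportions).
#' @param lmin,vmin Minimum diagonal / vertical line length counted by
#'   determinism, entropy and laminarity.
#' @param norm Phase-space distance: `"euclidean"` or `"maximum"`.
#' @param max_lag Largest delay (samples) scanned by the mutual-information
#'   delay selection.
#' @param max_dim Largest embedding dimension tried by the
#'   false-nearest-neighbour search.
#' @param fnn_threshold FNN fraction under which a dimension is accepted.
#' @param fnn_rtol FNN distance-inflation tolerance.
#' @return An object of class `crqa_config`.
#' @export
crqa_config <- function(target_band = c(0.02, 0.04), lmin = 2L, vmin = 2L,
                        norm = c("euclidean", "maximum"), max_lag = 40L,
                        max_dim = 10L, fnn_threshold = 0.02,
                        fnn_rtol = 10) {
  norm <- match.arg(norm)
  stopifnot(length(target_band) == 2L, target_band[1] > 0,
            target_band[1] < target_band[2], target_band[2] <= 1,
            lmin >= 1, vmin >= 1, max_lag >= 2, max_dim >= 1)
  structure(list(target_band = target_band, lmin = as.integer(lmin),
                 vmin = as.integer(vmin), norm = norm,
                 max_lag = as.integer(max_lag),
                 max_dim = as.integer(max_dim),
                 fnn_threshold = fnn_threshold, fnn_rtol = fnn_rtol),
            class = "crqa_config")
}

#' Time-delay embedding
#'
#' Reconstructs a phase-space trajectory from a scalar series: vector `k`
#' is `(x[k], x[k + delay], ..., x[k + (dim - 1) * delay])`.
#'
#' @param series Numeric vector (or [eda_trace()]).
#' @param delay Delay in samples (>= 1).
#' @param dim Embedding dimension (>= 1).
#' @return Matrix with `length(series) - (dim - 1) * delay` rows and `dim`
#'   columns.
#' @export
embed_series <- function(series, delay, dim) {
  if (inherits(series, "eda_trace")) series <- series$values
  delay <- as.integer(delay); dim <- as.integer(dim)
  stopifnot(delay >= 1L, dim >= 1L)
  n <- length(series)
  need <- (dim - 1L) * delay + 1L
  if (n < need) {
    stop("series too short to embed: need at least ", need,
         " samples for dim ", dim, " and delay ", delay, ", got ", n)
  }
  n_emb <- n - (dim - 1L) * delay
  out <- matrix(0, n_emb, dim)
  for (k in seq_len(dim)) {
    out[, k] <- series[seq.int((k - 1L) * delay + 1L,
                               length.out = n_emb)]
  }
  out
}

norm_code <- function(norm) if (norm == "euclidean") 0L else 1L

#' Cross-recurrence matrix
#'
#' `R[i, j] = 1` when the i-th point of the first embedded trajectory lies
#' within `radius` of the j-th point of the second. No Theiler exclusion is
#' applied: the two trajectories belong to different people, so near-zero
#' index differences are substantive, not autocorrelation artifacts.
#'
#' @param x_emb,y_emb Embedded trajectories (matrices from
#'   [embed_series()]), equal column count.
#' @param radius Neighbourhood radius in the units of the (z-scored)
#'   signals.
#' @param norm `"euclidean"` or `"maximum"`.
#' @return A binary integer matrix of class `recurrence_matrix`, rows
#'   indexing `x_emb`, columns `y_emb`.
#' @export
cross_recurrence <- function(x_emb, y_emb, radius,
                             norm = c("euclidean", "maximum")) {
  norm <- match.arg(norm)
  if (ncol(x_emb) != ncol(y_emb)) {
    stop("embedding dimensions differ: ", ncol(x_emb), " vs ", ncol(y_emb))
  }
  stopifnot(nrow(x_emb) >= 1L, nrow(y_emb) >= 1L, radius >= 0)
  D <- .cross_dist(x_emb, y_emb, norm_code(norm))
  recurrence_from_dist(D, radius, norm)
}

recurrence_from_dist <- function(D, radius, norm) {
  R <- matrix(0L, nrow(D), ncol(D))
  R[D <= radius] <- 1L
  structure(R, class = c("recurrence_matrix", class(R)),
            radius = radius, norm = norm)
}

#' Maximal diagonal line lengths of a recurrence matrix
#'
#' Enumerates every maximal run of recurrent points along all diagonals of
#' the (rectangular) matrix.
#'
#' @param R A `recurrence_matrix` (or plain 0/1 matrix).
#' @param lmin Shortest run to keep (`1` keeps all, as needed for maxL).
#' @return Integer vector of run lengths (unordered).
#' @export
diagonal_lines <- function(R, lmin = 1L) {
  runs <- .line_runs(unclass_matrix(R))$diagonal
  runs[runs >= lmin]
}

#' Maximal vertical line lengths of a recurrence matrix
#'
#' As [diagonal_lines()] but along columns.
#'
#' @inheritParams diagonal_lines
#' @param vmin Shortest run to keep.
#' @return Integer vector of run lengths (unordered).
#' @export
vertical_lines <- function(R, vmin = 1L) {
  runs <- .line_runs(unclass_matrix(R))$vertical
  runs[runs >= vmin]
}

unclass_matrix <- function(R) {
  m <- unclass(R)
  storage.mode(m) <- "integer"
  attr(m, "radius") <- NULL; attr(m, "norm") <- NULL
  m
}

#' Recurrence metrics of a cross-recurrence matrix
#'
#' * `rr` — recurrence rate, density of recurrent points.
#' * `det` — determinism: fraction of recurrent points on diagonal lines
#'   of length >= `lmin` (coupled trajectory evolution).
#' * `lam` — laminarity: fraction on vertical lines of length >= `vmin`
#'   (sustained shared states).
#' * `maxl` — longest diagonal line, any length (maximal uninterrupted
#'   co-evolution).
#' * `entr` / `rentr` — Shannon entropy of the diagonal line-length
#'   distribution (lines >= `lmin`), raw and normalised by the log of the
#'   number of distinct lengths (0 when fewer than two distinct lengths).
#'
#' An empty matrix (no recurrent points) yields all-zero metrics with
#' `degenerate = TRUE` rather than an error.
#'
#' @param R A `recurrence_matrix`.
#' @param lmin,vmin Minimum counted line lengths.
#' @param params Optional list of embedding parameters to carry along.
#' @return An object of class `crqa_metrics`.
#' @export
compute_metrics <- function(R, lmin = 2L, vmin = 2L, params = NULL) {
  n_rec <- sum(unclass_matrix(R) != 0L)
  n_total <- as.numeric(nrow(R)) * ncol(R)
  if (n_rec == 0L) {
    m <- list(rr = 0, det = 0, lam = 0, maxl = 0L, entr = 0, rentr = 0,
              n_recurrent = 0L, n_rows = nrow(R), n_cols = ncol(R),
              degenerate = TRUE, params = params)
    class(m) <- "crqa_metrics"
    return(m)
  }
  d_all <- diagonal_lines(R, 1L)
  d_cnt <- d_all[d_all >= lmin]
  v_cnt <- vertical_lines(R, vmin)
  det <- sum(d_cnt) / n_rec
  lam <- sum(v_cnt) / n_rec
  maxl <- max(d_all)
  if (length(d_cnt) > 0) {
    cnt <- tabulate(d_cnt)
    p <- cnt[cnt > 0] / length(d_cnt)
    entr <- -sum(p * log(p))
    rentr <- if (length(p) > 1L) entr / log(length(p)) else 0
  } else {
    entr <- 0; rentr <- 0
  }
  m <- list(rr = n_rec / n_total, det = det, lam = lam,
            maxl = as.integer(maxl), entr = entr, rentr = rentr,
            n_recurrent = as.integer(n_rec), n_rows = nrow(R),
            n_cols = ncol(R), degenerate = FALSE, params = params)
  class(m) <- "crqa_metrics"
  m
}

#' @export
print.crqa_metrics <- function(x, ...) {
  cat(sprintf(
    "crqa_metrics: RR %.3f | DET %.3f | LAM %.3f | maxL %d | rENTR %.3f\n",
    x$rr, x$det, x$lam, x$maxl, x$rentr))
  if (!is.null(x$params)) {
    cat(sprintf("  delay %s, dim %s, radius %.4g (%s norm)\n",
                x$params$delay, x$params$dim, x$params$radius,
                x$params$norm %||% "euclidean"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Average mutual information between x[t] and x[t + lag], histogram
## estimator on `bins` equiprobable bins.
ami_profile <- function(x, max_lag, bins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3L) stop("degenerate series: too few distinct values")
  d <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  n <- length(d)
  nb <- length(br) - 1L
  vapply(0:max_lag, function(lag) {
    a <- d[seq_len(n - lag)]
    b <- d[seq_len(n - lag) + lag]
    tab <- matrix(tabulate(a + nb * (b - 1L), nb * nb), nb, nb) / (n - lag)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  }, 0)
}

#' Select the embedding delay by average mutual information
#'
#' Returns the first local minimum of the AMI profile over lags
#' `1..max_lag` (10 equiprobable bins). Slowly varying physiological
#' signals often have a monotonically decaying AMI with no interior
#' minimum; the fallback is then the first lag where the AMI decays below
#' `1/e` of its lag-zero value (the standard decay criterion), and only
#' if that never happens the lag with the smallest AMI.
#'
#' @param series Numeric vector or [eda_trace()].
#' @param max_lag Largest lag scanned, samples.
#' @return Delay in samples.
#' @export
select_delay <- function(series, max_lag = 40L) {
  if (inherits(series, "eda_trace")) series <- series$values
  max_lag <- as.integer(max_lag)
  if (max_lag < 2L) stop("max_lag must be at least 2")
  if (length(series) <= 4L * max_lag) {
    max_lag <- max(2L, length(series) %/% 4L)
  }
  ami <- ami_profile(series, max_lag)  # index 1 is lag 0
  ## 3-point smoothing: fast micro-fluctuations put shallow sub-sample
  ## dips into the profile that are not structural minima
  if (length(ami) >= 3L) {
    ami <- c(ami[1L],
             (ami[-c(1L, length(ami))] * 2 + ami[-c(length(ami) - 1L,
                                                    length(ami))] +
                ami[-(1:2)]) / 4,
             ami[length(ami)])
  }
  for (lag in seq_len(max_lag - 1L)) {
    if (ami[lag + 1L] < ami[lag] && ami[lag + 1L] <= ami[lag + 2L]) {
      return(lag)
    }
  }
  decayed <- which(ami[-1L] <= ami[1L] / exp(1))
  if (length(decayed)) decayed[1L] else which.min(ami[-1L])
}

#' Select the embedding dimension by false nearest neighbours
#'
#' Smallest dimension whose FNN fraction (Kennel criterion, inflation
#' tolerance `rtol`) drops to `threshold` or below; `max_dim` if none does.
#'
#' @param series Numeric vector or [eda_trace()].
#' @param delay Embedding delay, samples.
#' @param max_dim Largest dimension tried.
#' @param rtol Distance-inflation tolerance marking a neighbour false.
#' @param threshold Acceptable FNN fraction.
#' @return Embedding dimension.
#' @export
select_dim <- function(series, delay, max_dim = 10L, rtol = 10,
                       threshold = 0.02) {
  if (inherits(series, "eda_trace")) series <- series$values
  if (stats::sd(series) == 0) stop("degenerate series: zero variance")
  need <- as.integer(max_dim) * as.integer(delay) + 1L
  if (length(series) < need) {
    stop("series too short for FNN up to dim ", max_dim, ": need ", need,
         " samples, got ", length(series))
  }
  fr <- .fnn_fractions(as.numeric(series), as.integer(delay),
                       as.integer(max_dim), rtol, 0L, threshold, 400L,
                       0.1 * stats::sd(series))
  ok <- which(!is.na(fr) & fr <= threshold)
  if (length(ok)) ok[1L] else as.integer(max_dim)
}

#' Calibrate the recurrence radius to a target recurrence-rate band
#'
#' Bisection on the radius between 0 and the maximum pairwise phase-space
#' distance, driving the recurrence rate to the band midpoint and stopping
#' once the rate falls inside `target_band` (at most `max_iter` halvings).
#'
#' @param x_emb,y_emb Embedded trajectories.
#' @param target_band Length-2 recurrence-rate band (proportions).
#' @param norm Distance norm.
#' @param max_iter Bisection iteration cap.
#' @return List with `radius` and the achieved `rr`. If the band cannot be
#'   reached (heavily tied distances), an error reports the closest
#'   achievable rate.
#' @export
calibrate_radius <- function(x_emb, y_emb, target_band = c(0.02, 0.04),
                             norm = c("euclidean", "maximum"),
                             max_iter = 60L) {
  norm <- match.arg(norm)
  D <- .cross_dist(x_emb, y_emb, norm_code(norm))
  calibrate_radius_dist(D, target_band, max_iter)
}

calibrate_radius_dist <- function(D, target_band, max_iter = 60L) {
  res <- .calibrate_bisect(D, target_band[1], target_band[2],
                           as.integer(max_iter))
  if (res[2] < target_band[1] || res[2] > target_band[2]) {
    stop(sprintf(
      "recurrence-rate band [%.3f, %.3f] unattainable; closest achieved %.4f",
      target_band[1], target_band[2], res[2]))
  }
  list(radius = res[1], rr = res[2])
}

#' Full cross-recurrence analysis of one dyad-block learning phase
#'
#' Chains the whole parameter-selection pipeline on a preprocessed
#' (downsampled, z-scored) demonstrator/observer pair: delay by mutual
#' information and dimension by false nearest neighbours for each signal
#' separately (the dyad uses the maximum of the two — one embedding must
#' unfold both), radius calibrated to the target recurrence-rate band,
#' then the recurrence matrix and its metrics.
#'
#' @param demo_trace,obs_trace Preprocessed learning-phase [eda_trace()]s
#'   of equal length and rate.
#' @param cfg A [crqa_config()].
#' @param keep_matrix Keep the recurrence matrix in the result (off by
#'   default; the matrices are large).
#' @return A `crqa_metrics` object whose `params` record `delay`, `dim`,
#'   `radius`, `norm` and `n_samples`.
#' @export
run_crqa <- function(demo_trace, obs_trace, cfg = crqa_config(),
                     keep_matrix = FALSE) {
  x <- if (inherits(demo_trace, "eda_trace")) demo_trace$values else demo_trace
  y <- if (inherits(obs_trace, "eda_trace")) obs_trace$values else obs_trace
  if (length(x) != length(y)) {
    ## trailing-sample mismatch from downsampling is tolerated
    n <- min(length(x), length(y))
    if (abs(length(x) - length(y)) > 2L) {
      stop("trace lengths differ by more than 2 samples: ",
           length(x), " vs ", length(y))
    }
    x <- x[seq_len(n)]; y <- y[seq_len(n)]
  }
  delay <- max(select_delay(x, cfg$max_lag), select_delay(y, cfg$max_lag))
  dim <- max(select_dim(x, delay, cfg$max_dim, cfg$fnn_rtol,
                        cfg$fnn_threshold),
             select_dim(y, delay, cfg$max_dim, cfg$fnn_rtol,
                        cfg$fnn_threshold))
  xe <- embed_series(x, delay, dim)
  ye <- embed_series(y, delay, dim)
  D <- .cross_dist(xe, ye, norm_code(cfg$norm))
  cal <- calibrate_radius_dist(D, cfg$target_band)
  R <- recurrence_from_dist(D, cal$radius, cfg$norm)
  m <- compute_metrics(R, cfg$lmin, cfg$vmin,
                       params = list(delay = delay, dim = dim,
                                     radius = cal$radius, norm = cfg$norm,
                                     rr_achieved = cal$rr,
                                     n_samples = length(x)))
  if (keep_matrix) m$matrix <- R
  m
}

#' Cross-recurrence metrics for every dyad-block of a dataset
#'
#' Preprocesses each learning phase (downsample to `pre_cfg$target_hz`,
#' z-score) and runs [run_crqa()]. Dyad-blocks whose radius calibration
#' fails are excluded with a recorded reason.
#'
#' @param dataset A `dyad_dataset`.
#' @param cfg A [crqa_config()].
#' @param pre_cfg A [preprocess_config()].
#' @return A `data.frame`, one row per analysable dyad-block: `dyad_id`,
#'   `block`, `observer_id`, `role_first`, `block_in_role`, `rr`, `det`,
#'   `lam`, `maxl`, `rentr`, `entr`, `delay`, `dim`, `radius`,
#'   `n_samples`. Failures are kept in attribute `"failures"`.
#' @export
crqa_dataset <- function(dataset, cfg = crqa_config(),
                         pre_cfg = preprocess_config()) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  failures <- list()
  rows <- map_blocks(dataset, function(dy, bl, b) {
    res <- tryCatch({
      demo <- prepare_crqa_series(bl$demo_learning, pre_cfg)
      obs <- prepare_crqa_series(bl$obs_learning, pre_cfg)
      m <- run_crqa(demo, obs, cfg)
      data.frame(dyad_id = dy$id, block = b,
                 observer_id = bl$observer_id,
                 role_first = bl$role_first,
                 block_in_role = bl$block_in_role,
                 rr = m$rr, det = m$det, lam = m$lam, maxl = m$maxl,
                 rentr = m$rentr, entr = m$entr,
                 delay = m$params$delay, dim = m$params$dim,
                 radius = m$params$radius,
                 n_samples = m$params$n_samples)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(dyad_id = dy$id, block = b, reason = conditionMessage(e))
      NULL
    })
    res
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "failures") <- failures
  out
}
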