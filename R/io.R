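#' Write a simulated dataset to plain-text files
#'
#' Long-format `signals.csv` (dyad_id, role, block, phase, time_s,
#' eda_us), `events.csv` (dyad_id, block, phase, trial_index, cs, onset_s,
#' duration_s, shock, shock_time_s), `ground_truth.csv` (dyad_id, kappa)
#' and `config.yaml` (design and coupling settings). Blocks and trials are
#' 1-based; times are seconds from phase start.
#'
#' @param dataset A `dyad_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig_rows <- list(); ev_rows <- list(); i <- 0L
  for (dy in dataset$dyads) {
    for (b in seq_along(dy$blocks)) {
      bl <- dy$blocks[[b]]
      for (nm in c("demo_learning", "obs_learning", "demo_testing",
                   "obs_testing")) {
        tr <- bl[[nm]]
        i <- i + 1L
        sig_rows[[i]] <- data.frame(
          dyad_id = dy$id, role = tr$role, block = b, phase = tr$phase,
          time_s = trace_times(tr), eda_us = tr$values,
          stringsAsFactors = FALSE)
      }
      s <- bl$schedule
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        dyad_id = dy$id, block = b, phase = s$phase,
        trial_index = s$trial_index, cs = s$cs, onset_s = s$onset_s,
        duration_s = s$duration_s, shock = as.integer(s$shock),
        shock_time_s = s$shock_time_s, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, sig_rows),
                   file.path(dir, "signals.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, ev_rows),
                   file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(dataset$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- list(design = unclass(dataset$design),
              coupling = unclass(dataset$coupling),
              seed = dataset$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a signals file into traces
#'
#' Validates the column set, sorts rows, and checks each
#' (dyad, role, block, phase) trace for duplicated time stamps and uniform
#' sampling (maximum jitter under half a sample period).
#'
#' @param path Path to a `signals.csv`.
#' @return Nested list: `traces[[dyad]][[block]][[role_phase]]`, each an
#'   [eda_trace()]; `role_phase` in `demo_learning`, `obs_learning`,
#'   `demo_testing`, `obs_testing`.
#' @export
read_signals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad_id", "role", "block", "phase", "time_s", "eda_us")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("signals file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$dyad_id, df$role, df$block, df$phase, df$time_s), ]
  out <- list()
  sp <- split(seq_len(nrow(df)),
              list(df$dyad_id, df$role, df$block, df$phase), drop = TRUE)
  for (key in names(sp)) {
    idx <- sp[[key]]
    tt <- df$time_s[idx]
    if (anyDuplicated(tt)) {
      stop("duplicated time stamps in trace ", key, " (rows ",
           paste(utils::head(idx[duplicated(tt)], 3), collapse = ", "),
           ")")
    }
    dt <- diff(tt)
    if (length(dt)) {
      period <- stats::median(dt)
      bad <- which(abs(dt - period) > period / 2)
      if (length(bad)) {
        stop("non-uniform sampling in trace ", key, " near row ",
             idx[bad[1] + 1L], " (gap ", signif(dt[bad[1]], 4), " s, period ",
             signif(period, 4), " s)")
      }
      rate <- 1 / period
    } else rate <- NA_real_
    d <- df$dyad_id[idx[1]]; role <- df$role[idx[1]]
    b <- df$block[idx[1]]; ph <- df$phase[idx[1]]
    nm <- paste0(if (role == "demonstrator") "demo" else "obs", "_", ph)
    dk <- as.character(d); bk <- as.character(b)
    if (is.null(out[[dk]])) out[[dk]] <- list()
    if (is.null(out[[dk]][[bk]])) out[[dk]][[bk]] <- list()
    out[[dk]][[bk]][[nm]] <- eda_trace(df$eda_us[idx], rate, d, role,
                                       b, ph)
  }
  out
}

#' Read an events file into per-block schedules
#'
#' @param path Path to an `events.csv`.
#' @return Nested list `schedules[[dyad]][[block]]` of `event_schedule`
#'   data frames.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad_id", "block", "phase", "trial_index", "cs", "onset_s",
            "duration_s", "shock", "shock_time_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("events file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- list()
  for (d in unique(df$dyad_id)) {
    dk <- as.character(d)
    out[[dk]] <- list()
    for (b in unique(df$block[df$dyad_id == d])) {
      s <- df[df$dyad_id == d & df$block == b, ]
      s <- s[order(match(s$phase, c("learning", "testing")),
                   s$trial_index), ]
      sched <- data.frame(phase = s$phase, trial_index = s$trial_index,
                          cs = s$cs, onset_s = s$onset_s,
                          duration_s = s$duration_s,
                          shock = s$shock == 1L,
                          shock_time_s = s$shock_time_s,
                          stringsAsFactors = FALSE)
      attr(sched, "block_index") <- as.integer(b)
      class(sched) <- c("event_schedule", "data.frame")
      out[[dk]][[as.character(b)]] <- sched
    }
  }
  out
}

#' Read a dataset directory back into a `dyad_dataset`
#'
#' Inverse of [write_dataset()]. Traces carry no event tables (those are
#' generator internals); everything downstream of the generator works from
#' the files alone.
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `dyad_dataset`.
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  design <- do.call(design_config, cfg$design)
  coupling <- do.call(coupling_config,
                      cfg$coupling[names(cfg$coupling) %in%
                                   names(formals(coupling_config))])
  traces <- read_signals(file.path(dir, "signals.csv"))
  schedules <- read_events(file.path(dir, "events.csv"))
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  half <- ceiling(design$n_blocks / 2)
  dyads <- lapply(sort(as.integer(names(traces))), function(d) {
    dk <- as.character(d)
    blocks <- lapply(seq_len(design$n_blocks), function(b) {
      bk <- as.character(b)
      bl <- traces[[dk]][[bk]]
      bl$schedule <- schedules[[dk]][[bk]]
      bl$observer_id <- if (b <= half) 2L * d - 1L else 2L * d
      bl$role_first <- b <= half
      bl$block_in_role <- if (b <= half) b else b - half
      bl
    })
    list(id = d, kappa = gt$kappa[gt$dyad_id == d], blocks = blocks)
  })
  structure(list(design = design, coupling = coupling, ground_truth = gt,
                 seed = cfg$seed, dyads = dyads),
            class = "dyad_dataset")
}

#' Run the full analysis pipeline
#'
#' Simulation (or a dataset you pass in) -> per-dyad-block CRQA ->
#' synchrony PCA and alternative predictors -> trial assembly -> the three
#' mixed models -> optional pseudo-dyad permutation test. If `out_dir` is
#' given, every stage's table plus a JSON run manifest (seed, settings,
#' package version) is written there.
#'
#' @param dataset A `dyad_dataset`, or `NULL` to simulate one from
#'   `design`.
#' @param design,coupling Passed to [generate_dataset()] when `dataset` is
#'   `NULL`.
#' @param cfg,pre_cfg CRQA and preprocessing settings.
#' @param n_permutations Pseudo-dyad permutations (0 skips the test).
#' @param seed Master seed for simulation and permutations.
#' @param out_dir Optional output directory.
#' @return List with `metrics`, `scores`, `trials`, `fit` (synchrony
#'   model), `stability`, `specificity`, `permutation` (or `NULL`), and
#'   `dataset`.
#' @export
run_pipeline <- function(dataset = NULL, design = design_config(),
                         coupling = coupling_config(),
                         cfg = crqa_config(),
                         pre_cfg = preprocess_config(),
                         n_permutations = 0L, seed = 1L,
                         out_dir = NULL) {
  if (is.null(dataset)) {
    dataset <- generate_dataset(design, coupling, seed = seed)
  }
  metrics <- crqa_dataset(dataset, cfg, pre_cfg)
  preds <- build_predictors(dataset, metrics, pre_cfg)
  trials <- assemble_trials(dataset, preds, pre_cfg)
  fit <- fit_cs_model(trials, "pc1")
  ## block/role contrasts need designs where they vary (>= 4 blocks)
  stability <- if (length(unique(trials$block_code)) > 1L &&
                     length(unique(trials$role_code)) > 1L) {
    stability_model(trials)
  } else NULL
  specificity <- fit_specificity_model(trials)
  permutation <- NULL
  if (n_permutations > 0L) {
    permutation <- pseudo_dyad_null(dataset, n_permutations,
                                    seed = seed + 1L, cfg = cfg,
                                    pre_cfg = pre_cfg)
  }
  res <- list(metrics = metrics, scores = preds$scores, pca = preds$pca,
              trials = trials, fit = fit, stability = stability,
              specificity = specificity, permutation = permutation,
              dataset = dataset)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "crqa_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(preds$scores, file.path(out_dir, "synchrony_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trial_responses.csv"),
                     row.names = FALSE)
    for (nm in c("fit", "stability", "specificity")) {
      if (is.null(res[[nm]])) next
      utils::write.csv(res[[nm]]$fixed,
                       file.path(out_dir, paste0(nm, "_coefficients.csv")),
                       row.names = FALSE)
    }
    if (!is.null(permutation)) {
      jsonlite::write_json(
        list(observed = permutation$observed, p_value = permutation$p_value,
             n_permutations = permutation$n_permutations,
             null = permutation$null),
        file.path(out_dir, "permutation.json"), auto_unbox = TRUE,
        digits = NA)
    }
    manifest <- list(
      package = "dyadsync",
      version = as.character(utils::packageVersion("dyadsync")),
      seed = seed,
      n_dyads = dataset$design$n_dyads,
      n_blocks = dataset$design$n_blocks,
      target_band = cfg$target_band,
      n_permutations = n_permutations,
      n_crqa_failures = length(attr(metrics, "failures")),
      pc1_variance = preds$pca$variance_explained[1],
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
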