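#' Assemble the trial-level analysis table
#'
#' Scores every testing-phase CS presentation of the dataset and joins the
#' per-dyad-block grouping variables (observer id, role/block codes) and,
#' if given, the predictor columns from [build_predictors()].
#'
#' @param dataset A `dyad_dataset`.
#' @param scores Optional `synchrony_scores` (or its `scores` data frame);
#'   its predictor columns are merged by (`dyad_id`, `block`). Dyad-blocks
#'   without scores (e.g. failed calibration) are dropped.
#' @param pre_cfg A [preprocess_config()].
#' @return Trial-level `data.frame`: one row per testing-phase CS
#'   presentation with `amplitude_raw`, `amplitude_tx`, `cs_code`,
#'   `observer_id`, `role_code`, `block_code` (both deviation coded
#'   +0.5/-0.5) and `trial_num` (within-CS presentation number).
#' @export
assemble_trials <- function(dataset, scores = NULL,
                            pre_cfg = preprocess_config()) {
  rows <- map_blocks(dataset, function(dy, bl, b) {
    tr <- score_phase(bl$obs_testing, bl$schedule, pre_cfg)
    tr$observer_id <- bl$observer_id
    tr$role_code <- if (bl$role_first) 0.5 else -0.5
    tr$block_code <- if (bl$block_in_role == 1L) -0.5 else 0.5
    tr$trial_num <- stats::ave(seq_len(nrow(tr)), tr$cs, FUN = seq_along)
    tr
  })
  trials <- do.call(rbind, rows)
  if (!is.null(scores)) {
    sc <- if (inherits(scores, "synchrony_scores")) scores$scores else scores
    keep <- setdiff(names(sc), c("observer_id", "role_first",
                                 "block_in_role"))
    trials <- merge(trials, sc[, keep], by = c("dyad_id", "block"))
  }
  trials[order(trials$dyad_id, trials$block, trials$trial_index), ]
}

check_cs_code <- function(trials) {
  if (!all(sort(unique(trials$cs_code)) == c(-0.5, 0.5))) {
    stop("cs_code must be deviation coded exactly {+0.5, -0.5}")
  }
}

## standardize the named columns in place; error on zero variance
standardize_cols <- function(data, cols) {
  for (cl in cols) {
    v <- data[[cl]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize '", cl, "': zero variance")
    }
    data[[cl]] <- (v - mean(v)) / s
  }
  data
}

fit_result <- function(fixed, ranef = NULL, diagnostics = NULL,
                       backend = "lme4-reml") {
  structure(list(fixed = fixed, ranef = ranef,
                 diagnostics = diagnostics, backend = backend),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Mixed-model fit (", x$backend, ")\n", sep = "")
  print(format(x$fixed, digits = 3))
  if (!is.null(x$ranef)) {
    cat("Random effects (observer): SD(intercept) ",
        sprintf("%.3f", x$ranef$sd_intercept),
        ", SD(cs) ", sprintf("%.3f", x$ranef$sd_cs),
        ", cor ", sprintf("%.2f", x$ranef$cor), "\n", sep = "")
  }
  invisible(x)
}

## Core mixed-model engine: varying intercept and CS slope by observer,
## Wald 95% intervals. Degenerate constant-response data short-circuits to
## an exact flat fit.
fit_mixed <- function(formula, data, seed = NULL) {
  resp <- all.vars(formula)[1]
  if (stats::sd(data[[resp]]) == 0) {
    tt <- stats::terms(formula)
    labs <- attr(tt, "term.labels")
    labs <- labs[!grepl("\\|", labs)]
    est <- c(data[[resp]][1], rep(0, length(labs)))
    fixed <- data.frame(term = c("(Intercept)", labs), estimate = est,
                        se = 0, ci_lo = est, ci_hi = est,
                        stringsAsFactors = FALSE)
    return(fit_result(fixed, backend = "degenerate-constant"))
  }
  ## rank check on the fixed-effect design before lme4 silently drops terms
  fe_formula <- lme4::nobars(formula)
  mm <- stats::model.matrix(fe_formula, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  quiet_lmer <- function(optimizer) {
    withCallingHandlers(
      lme4::lmer(formula, data = data, REML = TRUE,
                 control = lme4::lmerControl(
                   optimizer = optimizer, calc.derivs = FALSE,
                   check.conv.singular = "ignore")),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) {
        if (grepl("convergence code|unable to evaluate scaled gradient",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  fit <- quiet_lmer("nloptwrap")
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    ## roundoff-limited stops on near-flat likelihoods are routine for
    ## small simulated datasets; retry once with a derivative-free
    ## optimizer before declaring failure
    fit <- quiet_lmer("bobyqa")
    conv <- fit@optinfo$conv$opt
    if (!is.null(conv) && conv != 0) {
      stop("mixed model failed to converge (optimizer code ", conv, "): ",
           paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
    }
  }
  co <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  fixed <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      ci_lo = co[, "Estimate"] - z * co[, "Std. Error"],
                      ci_hi = co[, "Estimate"] + z * co[, "Std. Error"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)[["observer_id"]]
  ranef <- NULL
  if (!is.null(vc)) {
    sds <- attr(vc, "stddev")
    corr <- attr(vc, "correlation")
    ranef <- list(sd_intercept = unname(sds[1]),
                  sd_cs = if (length(sds) > 1) unname(sds[2]) else NA_real_,
                  cor = if (!is.null(corr) && nrow(corr) > 1)
                    corr[1, 2] else NA_real_,
                  sd_residual = attr(lme4::VarCorr(fit), "sc"))
  }
  fit_result(fixed, ranef,
             diagnostics = list(
               messages = unlist(fit@optinfo$conv$lme4$messages),
               logLik = as.numeric(stats::logLik(fit))))
}

#' Extract one coefficient row from a fit
#' @param fit A `fit_result`.
#' @param term Coefficient name (e.g. `"cs_code:pc1"`).
#' @return One-row data frame (estimate, se, ci_lo, ci_hi).
#' @export
coef_row <- function(fit, term) {
  row <- fit$fixed[fit$fixed$term == term, ]
  if (nrow(row) != 1L) {
    stop("term '", term, "' not found in fit (have: ",
         paste(fit$fixed$term, collapse = ", "), ")")
  }
  row
}

#' Does synchrony predict CS differentiation?
#'
#' Trial-level mixed-effects regression of the observer's transformed
#' testing-phase response on CS status (deviation coded), one or more
#' standardized continuous predictors and their CS interactions, with a
#' varying intercept and CS slope (and their correlation) per observer.
#' The CS-by-predictor interaction is the synchrony-predicts-learning
#' effect.
#'
#' @param trials Trial table from [assemble_trials()] containing the
#'   predictor columns.
#' @param predictors Character vector of predictor column names
#'   (standardized internally).
#' @param response Response column, default `amplitude_tx`.
#' @param seed Optional seed (the restricted-likelihood backend is
#'   deterministic; kept for backend interchangeability).
#' @return A `fit_result`.
#' @export
fit_cs_model <- function(trials, predictors = "pc1",
                         response = "amplitude_tx", seed = NULL) {
  check_cs_code(trials)
  if (length(unique(trials$observer_id)) < 2L) {
    stop("need at least 2 observers")
  }
  trials <- standardize_cols(trials, predictors)
  rhs <- paste0("cs_code * (",
                paste(predictors, collapse = " + "),
                ") + (1 + cs_code | observer_id)")
  f <- stats::as.formula(paste(response, "~", rhs))
  fit_mixed(f, trials, seed)
}

#' Specificity model: synchrony against the alternative predictors
#'
#' Jointly regresses the synchrony component and the three non-synchrony
#' learning-phase measures (mean UCS response, learning-phase CS
#' differentiation, best lagged correlation), each with its CS
#' interaction.
#'
#' @param trials Trial table containing `pc1`, `alt_ucs_mean`,
#'   `alt_learn_csdiff`, `alt_lagged_r`.
#' @inheritParams fit_cs_model
#' @return A `fit_result`.
#' @export
fit_specificity_model <- function(trials,
                                  predictors = c("pc1", "alt_ucs_mean",
                                                 "alt_learn_csdiff",
                                                 "alt_lagged_r"),
                                  response = "amplitude_tx", seed = NULL) {
  fit_cs_model(trials, predictors, response, seed)
}

#' Stability of the synchrony effect over block, role and trial
#'
#' Adds CS-by-Block and CS-by-Role interactions (both deviation coded) and
#' the CS-by-synchrony-by-trial-number interaction (trial number
#' standardized) to the synchrony model, testing whether the effect is
#' confined to parts of the experiment or decays over test presentations.
#'
#' @param trials Trial table with `pc1`, `block_code`, `role_code`,
#'   `trial_num`.
#' @inheritParams fit_cs_model
#' @return A `fit_result`.
#' @export
stability_model <- function(trials, response = "amplitude_tx",
                            seed = NULL) {
  check_cs_code(trials)
  for (cl in c("block_code", "role_code")) {
    if (length(unique(trials[[cl]])) < 2L) {
      stop("cannot deviation-code '", cl, "': constant column")
    }
    if (!all(sort(unique(trials[[cl]])) == c(-0.5, 0.5))) {
      stop(cl, " must be deviation coded {+0.5, -0.5}")
    }
  }
  trials$trial_z <- trials$trial_num
  trials <- standardize_cols(trials, c("pc1", "trial_z"))
  f <- stats::as.formula(paste(
    response, "~ cs_code * pc1 * trial_z + cs_code * block_code +",
    "cs_code * role_code + (1 + cs_code | observer_id)"))
  fit_mixed(f, trials, seed)
}

## random derangement of 1..n (no fixed points), by rejection
sample_derangement <- function(n) {
  if (n < 2L) stop("a derangement needs at least 2 dyads")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Pseudo-dyad permutation test of synchrony specificity
#'
#' Re-pairs every observer with a demonstrator from a different dyad
#' (a random derangement of dyad ids, block structure preserved), recomputes
#' the full CRQA -> PCA -> mixed-model pipeline on each pseudo-pairing
#' (radius recalibrated per pairing), and compares the observed
#' CS-by-synchrony interaction against the null distribution of
#' pseudo-dyad estimates. Per-signal delay/dimension selections are cached
#' across pairings (they depend only on the individual signal).
#'
#' @param dataset A `dyad_dataset`.
#' @param n_permutations Number of pseudo-pairings.
#' @param seed Integer seed (fixes the derangements).
#' @param cfg A [crqa_config()].
#' @param pre_cfg A [preprocess_config()].
#' @return Object of class `permutation_result`: `observed` (interaction
#'   estimate), `null` (one estimate per permutation), `p_value`
#'   (add-one-corrected upper-tail proportion), `n_permutations`.
#' @export
pseudo_dyad_null <- function(dataset, n_permutations = 1000L, seed = 1L,
                             cfg = crqa_config(),
                             pre_cfg = preprocess_config()) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  n_dyads <- dataset$design$n_dyads
  if (n_dyads < 2L) stop("pseudo-dyad null needs at least 2 dyads")
  n_blocks <- dataset$design$n_blocks

  ## preprocess every learning trace once
  prep <- lapply(dataset$dyads, function(dy) {
    lapply(dy$blocks, function(bl) {
      list(demo = prepare_crqa_series(bl$demo_learning, pre_cfg),
           obs = prepare_crqa_series(bl$obs_learning, pre_cfg),
           observer_id = bl$observer_id)
    })
  })
  trials0 <- assemble_trials(dataset, scores = NULL, pre_cfg)

  delay_cache <- new.env(parent = emptyenv())
  dim_cache <- new.env(parent = emptyenv())
  cached_delay <- function(key, x) {
    if (is.null(delay_cache[[key]]))
      delay_cache[[key]] <- select_delay(x, cfg$max_lag)
    delay_cache[[key]]
  }
  cached_dim <- function(key, x, delay) {
    k <- paste0(key, ".", delay)
    if (is.null(dim_cache[[k]]))
      dim_cache[[k]] <- select_dim(x, delay, cfg$max_dim, cfg$fnn_rtol,
                                   cfg$fnn_threshold)
    dim_cache[[k]]
  }

  pair_metrics <- function(demo_dyad, obs_dyad, block) {
    x <- prep[[demo_dyad]][[block]]$demo$values
    y <- prep[[obs_dyad]][[block]]$obs$values
    n <- min(length(x), length(y))
    x <- x[seq_len(n)]; y <- y[seq_len(n)]
    delay <- max(cached_delay(paste0("d", demo_dyad, ".", block), x),
                 cached_delay(paste0("o", obs_dyad, ".", block), y))
    dim <- max(cached_dim(paste0("d", demo_dyad, ".", block), x, delay),
               cached_dim(paste0("o", obs_dyad, ".", block), y, delay))
    D <- .cross_dist(embed_series(x, delay, dim),
                     embed_series(y, delay, dim), norm_code(cfg$norm))
    cal <- calibrate_radius_dist(D, cfg$target_band)
    m <- compute_metrics(recurrence_from_dist(D, cal$radius, cfg$norm),
                         cfg$lmin, cfg$vmin)
    data.frame(dyad_id = obs_dyad, block = block, rr = m$rr, det = m$det,
               lam = m$lam, maxl = m$maxl, entr = m$entr, rentr = m$rentr)
  }

  stat_for_pairing <- function(demo_of) {
    rows <- list(); i <- 0L
    for (d in seq_len(n_dyads)) {
      for (b in seq_len(n_blocks)) {
        i <- i + 1L
        rows[[i]] <- tryCatch(pair_metrics(demo_of[d], d, b),
                              error = function(e) NULL)
      }
    }
    met <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(met) || nrow(met) < 5L) {
      stop("too few pseudo-pairings calibrated (",
           if (is.null(met)) 0 else nrow(met), " dyad-blocks)")
    }
    pca <- pca_synchrony(met)
    tr <- merge(trials0, pca$scores[, c("dyad_id", "block", "pc1")],
                by = c("dyad_id", "block"))
    fit <- fit_cs_model(tr, "pc1")
    coef_row(fit, "cs_code:pc1")$estimate
  }

  with_seed(seed, {
    observed <- stat_for_pairing(seq_len(n_dyads))
    null_stats <- numeric(n_permutations)
    for (p in seq_len(n_permutations)) {
      null_stats[p] <- stat_for_pairing(sample_derangement(n_dyads))
    }
    p_value <- (1 + sum(null_stats >= observed)) / (n_permutations + 1)
    structure(list(observed = observed, null = null_stats,
                   p_value = p_value,
                   n_permutations = as.integer(n_permutations)),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Pseudo-dyad permutation test: observed b = %.4f, p = %.4f (%d permutations)\n",
    x$observed, x$p_value, x$n_permutations))
  cat(sprintf("  null: mean %.4f, 95th percentile %.4f\n",
              mean(x$null), stats::quantile(x$null, 0.95)))
  invisible(x)
}
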