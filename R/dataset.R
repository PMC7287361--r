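## Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  eval(substitute(expr), envir = parent.frame())
}

#' Generate a full synthetic dyadic experiment
#'
#' Simulates `design$n_dyads` demonstrator-observer dyads over
#' `design$n_blocks` blocks. Each dyad draws one coupling strength `kappa`
#' from `kappa_sampler` (its ground truth); each block gets a fresh trial
#' schedule and four traces (demonstrator/observer x learning/testing).
#' Roles reverse halfway through the experiment: the participant observing
#' in the first half demonstrates in the second, and each dyad-block
#' records the observing participant's id, whether that participant started
#' the experiment as observer, and the block number within that role stint.
#'
#' @param design A [design_config()].
#' @param coupling A [coupling_config()]; its `kappa` is overridden per
#'   dyad by `kappa_sampler`.
#' @param kappa_sampler Function of `n` returning `n` coupling strengths in
#'   \[0, 1\]; default uniform.
#' @param kernels Named list of event [scr_kernel()]s.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `dyad_dataset`: list with `design`,
#'   `coupling`, `ground_truth` (dyad_id, kappa) and `dyads`, each dyad a
#'   list of `blocks` holding `schedule`, `demo_learning`, `obs_learning`,
#'   `demo_testing`, `obs_testing`, `observer_id`, `role_first`,
#'   `block_in_role`.
#' @export
generate_dataset <- function(design, coupling = coupling_config(),
                             kappa_sampler = stats::runif,
                             kernels = default_kernels(),
                             seed = design$seed) {
  stopifnot(inherits(design, "design_config"))
  if (design$n_dyads < 2L) {
    stop("need at least 2 dyads (the pseudo-dyad null requires >= 2)")
  }
  with_seed(seed, {
    kappas <- kappa_sampler(design$n_dyads)
    stopifnot(all(kappas >= 0 & kappas <= 1))
    half <- ceiling(design$n_blocks / 2)
    dyads <- lapply(seq_len(design$n_dyads), function(d) {
      cp <- coupling
      cp$kappa <- kappas[d]
      ## participant A observes in the first half, B in the second
      traits_a <- draw_traits(coupling$trait_sdlog)
      traits_b <- draw_traits(coupling$trait_sdlog)
      blocks <- lapply(seq_len(design$n_blocks), function(b) {
        sched <- make_schedule(design, b)
        first_half <- b <= half
        obs_traits <- if (first_half) traits_a else traits_b
        demo_traits <- if (first_half) traits_b else traits_a
        bl <- list(schedule = sched,
                   observer_id = if (first_half) 2L * d - 1L else 2L * d,
                   role_first = first_half,
                   block_in_role = if (first_half) b else b - half)
        for (ph in c("learning", "testing")) {
          demo <- synth_demonstrator_trace(sched, ph, kernels, cp,
                                           design$sample_rate, demo_traits)
          obs <- synth_observer_trace(attr(demo, "events"), sched, ph, cp,
                                      kernels, design$sample_rate,
                                      obs_traits)
          demo$dyad_id <- d; demo$block <- b
          obs$dyad_id <- d; obs$block <- b
          bl[[paste0("demo_", ph)]] <- demo
          bl[[paste0("obs_", ph)]] <- obs
        }
        bl
      })
      list(id = d, kappa = kappas[d], blocks = blocks)
    })
    structure(list(design = design, coupling = coupling,
                   kernels = kernels,
                   ground_truth = data.frame(dyad_id = seq_len(design$n_dyads),
                                             kappa = kappas),
                   seed = as.integer(seed), dyads = dyads),
              class = "dyad_dataset")
  })
}

#' @export
print.dyad_dataset <- function(x, ...) {
  cat(sprintf("dyad_dataset: %d dyads x %d blocks (seed %d)\n",
              x$design$n_dyads, x$design$n_blocks, x$seed))
  cat(sprintf("  ground-truth kappa: %.2f-%.2f (mean %.2f)\n",
              min(x$ground_truth$kappa), max(x$ground_truth$kappa),
              mean(x$ground_truth$kappa)))
  invisible(x)
}

#' Redraw the testing phases of a dataset
#'
#' Regenerates every observer testing-phase trace (new trial-response
#' noise, nonspecific SCRs and measurement noise) while keeping the
#' learning phases, schedules and ground-truth couplings fixed. Used for
#' conditional power/type-I simulations: the expensive learning-phase
#' synchrony analysis is computed once and only the response side of the
#' experiment is replicated.
#'
#' @param dataset A `dyad_dataset`.
#' @param seed Integer seed for the redraw.
#' @param coupling_override Named list of [coupling_config()] fields to
#'   override (e.g. `list(learning_gain = 0)` for a null redraw).
#' @return The dataset with fresh `obs_testing` traces.
#' @export
redraw_testing <- function(dataset, seed, coupling_override = NULL) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  kernels <- dataset$kernels
  if (is.null(kernels)) kernels <- default_kernels()
  with_seed(seed, {
    dataset$dyads <- lapply(dataset$dyads, function(dy) {
      cp <- dataset$coupling
      cp$kappa <- dy$kappa
      for (nm in names(coupling_override)) cp[[nm]] <- coupling_override[[nm]]
      dy$blocks <- lapply(dy$blocks, function(bl) {
        obs <- synth_observer_trace(NULL, bl$schedule, "testing", cp,
                                    kernels, dataset$design$sample_rate)
        obs$dyad_id <- dy$id
        obs$block <- bl$obs_testing$block
        bl$obs_testing <- obs
        bl
      })
      dy
    })
    dataset
  })
}

## iterate over dyad-blocks: fn(dyad, block_entry, block_index)
map_blocks <- function(dataset, fn) {
  out <- list()
  i <- 0L
  for (dy in dataset$dyads) {
    for (b in seq_along(dy$blocks)) {
      i <- i + 1L
      out[[i]] <- fn(dy, dy$blocks[[b]], b)
    }
  }
  out
}
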