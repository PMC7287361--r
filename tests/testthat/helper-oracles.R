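# Brute-force oracles, independent of the package's compiled path.

# every maximal run of 1s along diagonals of a binary matrix, by explicit
# cell-walking
oracle_diagonal_runs <- function(R) {
  nr <- nrow(R); nc <- ncol(R)
  runs <- integer(0)
  for (off in seq(-(nr - 1), nc - 1)) {
    i <- if (off < 0) -off + 1 else 1
    j <- if (off < 0) 1 else off + 1
    run <- 0L
    while (i <= nr && j <= nc) {
      if (R[i, j] != 0) {
        run <- run + 1L
      } else if (run > 0L) {
        runs <- c(runs, run); run <- 0L
      }
      i <- i + 1L; j <- j + 1L
    }
    if (run > 0L) runs <- c(runs, run)
  }
  runs
}

oracle_vertical_runs <- function(R) {
  runs <- integer(0)
  for (j in seq_len(ncol(R))) {
    run <- 0L
    for (i in seq_len(nrow(R))) {
      if (R[i, j] != 0) {
        run <- run + 1L
      } else if (run > 0L) {
        runs <- c(runs, run); run <- 0L
      }
    }
    if (run > 0L) runs <- c(runs, run)
  }
  runs
}

oracle_metrics <- function(R, lmin = 2L, vmin = 2L) {
  n_rec <- sum(R != 0)
  d <- oracle_diagonal_runs(R)
  v <- oracle_vertical_runs(R)
  dk <- d[d >= lmin]
  vk <- v[v >= vmin]
  if (n_rec == 0) {
    return(list(rr = 0, det = 0, lam = 0, maxl = 0L, entr = 0, rentr = 0))
  }
  if (length(dk)) {
    p <- as.numeric(table(dk)) / length(dk)
    entr <- -sum(p * log(p))
    rentr <- if (length(p) > 1) entr / log(length(p)) else 0
  } else {
    entr <- 0; rentr <- 0
  }
  list(rr = n_rec / (nrow(R) * ncol(R)),
       det = sum(dk) / n_rec,
       lam = sum(vk) / n_rec,
       maxl = if (length(d)) max(d) else 0L,
       entr = entr, rentr = rentr)
}

# direct O(n m) embedding by explicit index arithmetic
oracle_embed <- function(x, delay, dim) {
  n_emb <- length(x) - (dim - 1) * delay
  out <- matrix(NA_real_, n_emb, dim)
  for (k in seq_len(n_emb)) {
    for (j in seq_len(dim)) out[k, j] <- x[k + (j - 1) * delay]
  }
  out
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("dyadsync")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# small helper: a quick dataset for pipeline-level tests
tiny_dataset <- function(n_dyads = 4, n_blocks = 1, seed = 7,
                         coupling = coupling_config(), ...) {
  generate_dataset(
    design_config(n_dyads = n_dyads, n_blocks = n_blocks,
                  n_cs_each_learning = 3, n_shocked_csplus = 2,
                  sample_rate = 8, ...),
    coupling, seed = seed)
}

# reduced-scale design used by the heavier simulations: full dyad count,
# shorter learning phases (fewer CS presentations), analysis-rate sampling
desk_design <- function(n_dyads = 69, n_blocks = 1, seed = 1) {
  design_config(n_dyads = n_dyads, n_blocks = n_blocks,
                n_cs_each_learning = 3, n_shocked_csplus = 2,
                sample_rate = 8, seed = seed)
}
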