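#' Generate the trial schedule for one block
#'
#' Builds the learning phase (strictly alternating CS+/CS- presentations,
#' first valence random, a random subset of CS+ trials co-terminating with
#' shock) followed by the testing phase (alternating presentations of each
#' CS, only the final CS+ shocked). Inter-trial intervals are drawn
#' uniformly from `design$iti_range` and measure CS offset to next CS onset.
#' Times are seconds from the start of each phase.
#'
#' @param design A [design_config()].
#' @param block_index 1-based block number (recorded, not used for timing).
#' @return A `data.frame` of class `event_schedule` with columns
#'   `phase`, `trial_index`, `cs`, `onset_s`, `duration_s`, `shock`,
#'   `shock_time_s` (NA when unshocked).
#' @export
make_schedule <- function(design, block_index = 1L) {
  stopifnot(inherits(design, "design_config"))

  alternating <- function(n_each) {
    first <- sample(c("plus", "minus"), 1L)
    other <- setdiff(c("plus", "minus"), first)
    rep(c(first, other), n_each)
  }
  ## a lead-in interval precedes the first CS so pre-onset baselines exist
  onsets <- function(n_trials) {
    lead <- stats::runif(1, design$iti_range[1], design$iti_range[2])
    itis <- stats::runif(n_trials - 1L, design$iti_range[1],
                         design$iti_range[2])
    cumsum(c(lead, itis + design$cs_duration))
  }

  ## learning phase
  cs_l <- alternating(design$n_cs_each_learning)
  n_l <- length(cs_l)
  shock_l <- rep(FALSE, n_l)
  plus_idx <- which(cs_l == "plus")
  shock_l[sample(plus_idx, design$n_shocked_csplus)] <- TRUE
  learning <- data.frame(
    phase = "learning", trial_index = seq_len(n_l), cs = cs_l,
    onset_s = onsets(n_l), duration_s = design$cs_duration,
    shock = shock_l, stringsAsFactors = FALSE)

  ## testing phase: only the final CS+ presentation is shocked
  cs_t <- alternating(design$n_cs_each_testing)
  n_t <- length(cs_t)
  shock_t <- rep(FALSE, n_t)
  shock_t[max(which(cs_t == "plus"))] <- TRUE
  testing <- data.frame(
    phase = "testing", trial_index = seq_len(n_t), cs = cs_t,
    onset_s = onsets(n_t), duration_s = design$cs_duration,
    shock = shock_t, stringsAsFactors = FALSE)

  sched <- rbind(learning, testing)
  sched$shock_time_s <- ifelse(sched$shock,
                               sched$onset_s + sched$duration_s, NA_real_)
  attr(sched, "block_index") <- as.integer(block_index)
  class(sched) <- c("event_schedule", "data.frame")
  validate_schedule(sched, design)
  sched
}

#' Check the structural invariants of an event schedule
#'
#' Trials must be time-ordered and non-overlapping within each phase,
#' learning-phase valences strictly alternate, the learning phase carries
#' exactly the designed number of shocked CS+ trials, and the testing phase
#' exactly one shock, on its final CS+ presentation.
#'
#' @param schedule An `event_schedule`.
#' @param design The [design_config()] it was generated from.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_schedule <- function(schedule, design) {
  for (ph in c("learning", "testing")) {
    s <- schedule[schedule$phase == ph, ]
    if (nrow(s) == 0L) stop("schedule has no ", ph, " phase")
    if (is.unsorted(s$onset_s, strictly = TRUE)) {
      stop(ph, " trials are not strictly time-ordered")
    }
    gaps <- diff(s$onset_s) - s$duration_s[-nrow(s)]
    if (any(gaps < 0)) stop(ph, " trials overlap")
    if (any(s$cs[-1L] == s$cs[-nrow(s)])) {
      stop(ph, " valences do not alternate")
    }
  }
  l <- schedule[schedule$phase == "learning", ]
  if (sum(l$cs == "plus") != design$n_cs_each_learning ||
      sum(l$cs == "minus") != design$n_cs_each_learning) {
    stop("learning phase must have ", design$n_cs_each_learning,
         " presentations of each CS")
  }
  if (sum(l$shock) != design$n_shocked_csplus ||
      any(l$shock & l$cs != "plus")) {
    stop("learning phase must shock exactly ", design$n_shocked_csplus,
         " CS+ trials")
  }
  t <- schedule[schedule$phase == "testing", ]
  if (sum(t$cs == "plus") != design$n_cs_each_testing ||
      sum(t$cs == "minus") != design$n_cs_each_testing) {
    stop("testing phase must have ", design$n_cs_each_testing,
         " presentations of each CS")
  }
  shocked <- which(t$shock)
  if (length(shocked) != 1L || shocked != max(which(t$cs == "plus"))) {
    stop("testing phase must shock only the final CS+ presentation")
  }
  invisible(TRUE)
}

#' Duration of one phase of a schedule
#'
#' Last CS offset plus a post-trial tail so the final response is captured.
#'
#' @param schedule An `event_schedule`.
#' @param phase `"learning"` or `"testing"`.
#' @param tail_s Seconds appended after the final CS offset.
#' @return Duration in seconds from phase start.
#' @export
phase_duration <- function(schedule, phase, tail_s = 8) {
  s <- schedule[schedule$phase == phase, ]
  max(s$onset_s + s$duration_s) + tail_s
}
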