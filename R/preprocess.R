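#' Preprocessing configuration
#'
#' @param target_hz Analysis sampling rate the signals are reduced to, Hz.
#' @param scr_window Post-onset window (seconds, length 2) in which the
#'   response maximum is sought.
#' @param baseline_window Window relative to onset (seconds, length 2,
#'   typically negative) whose mean is the response baseline.
#' @param transform Amplitude transform for analysis: `"log1p"` (default),
#'   `"sqrt"` or `"none"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_hz = 8,
                              scr_window = c(0.5, 4.5),
                              baseline_window = c(-1, 0),
                              transform = c("log1p", "sqrt", "none")) {
  transform <- match.arg(transform)
  stopifnot(target_hz > 0, length(scr_window) == 2L,
            length(baseline_window) == 2L,
            scr_window[1] < scr_window[2],
            baseline_window[1] < baseline_window[2])
  structure(list(target_hz = target_hz, scr_window = scr_window,
                 baseline_window = baseline_window, transform = transform),
            class = "preprocess_config")
}

apply_transform <- function(x, transform) {
  switch(transform, log1p = log1p(x), sqrt = sqrt(x), none = x)
}

#' Downsample a trace by block averaging
#'
#' Non-overlapping block means (an anti-aliasing reduction, not plain
#' decimation). The source rate must be an integer multiple of the target;
#' trailing samples that do not fill a block are dropped.
#'
#' @param trace An [eda_trace()].
#' @param target_hz Target rate, Hz.
#' @return An `eda_trace` at `target_hz`.
#' @export
downsample <- function(trace, target_hz = 8) {
  stopifnot(inherits(trace, "eda_trace"))
  if (target_hz > trace$sample_rate) {
    stop("target_hz (", target_hz, ") exceeds the source rate (",
         trace$sample_rate, ")")
  }
  fac <- trace$sample_rate / target_hz
  if (abs(fac - round(fac)) > 1e-9) {
    stop("source rate must be an integer multiple of target_hz")
  }
  fac <- as.integer(round(fac))
  n_out <- length(trace$values) %/% fac
  if (n_out < 1L) stop("trace too short to downsample")
  v <- trace$values[seq_len(n_out * fac)]
  out <- colMeans(matrix(v, nrow = fac))
  eda_trace(out, target_hz, trace$dyad_id, trace$role, trace$block,
            trace$phase)
}

#' Z-score a trace
#'
#' Centers and scales to sample SD 1. Applied per signal per phase, so
#' every learning-phase series enters the recurrence analysis on a common
#' scale.
#'
#' @param trace An [eda_trace()].
#' @return An `eda_trace` with mean 0 and SD 1.
#' @export
zscore <- function(trace) {
  stopifnot(inherits(trace, "eda_trace"))
  v <- trace$values
  if (length(v) < 2L) stop("need at least 2 samples to z-score")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: zero variance, cannot z-score (dyad ",
         trace$dyad_id, ", ", trace$role, ", block ", trace$block, ")")
  }
  eda_trace((v - mean(v)) / s, trace$sample_rate, trace$dyad_id,
            trace$role, trace$block, trace$phase)
}

#' Prepare one learning-phase trace for recurrence analysis
#'
#' Downsample to the analysis rate, then z-score.
#'
#' @param trace An [eda_trace()].
#' @param cfg A [preprocess_config()].
#' @return An `eda_trace` at `cfg$target_hz`, mean 0, SD 1.
#' @export
prepare_crqa_series <- function(trace, cfg = preprocess_config()) {
  zscore(downsample(trace, cfg$target_hz))
}

#' Score one event-related skin conductance response
#'
#' Trough-to-peak style rule: maximum of the trace in the post-onset
#' response window minus the mean over the pre-onset baseline window,
#' floored at zero (responses are onset-locked increases).
#'
#' @param trace An [eda_trace()], raw microsiemens.
#' @param onset Event onset, seconds from phase start.
#' @param cfg A [preprocess_config()].
#' @return Response amplitude, microsiemens (>= 0).
#' @export
score_scr <- function(trace, onset, cfg = preprocess_config()) {
  tt <- trace_times(trace)
  lo_b <- onset + cfg$baseline_window[1]
  hi_r <- onset + cfg$scr_window[2]
  if (lo_b < -1e-9 || hi_r > max(tt) + 1e-9) {
    stop(sprintf(
      "scoring window [%.2f, %.2f] s exceeds trace span [0, %.2f] s (onset %.2f)",
      lo_b, hi_r, max(tt), onset))
  }
  base_idx <- tt >= lo_b & tt <= onset + cfg$baseline_window[2]
  resp_idx <- tt >= onset + cfg$scr_window[1] & tt <= hi_r
  if (!any(base_idx) || !any(resp_idx)) {
    stop("empty scoring window at onset ", onset, " s")
  }
  max(0, max(trace$values[resp_idx]) - mean(trace$values[base_idx]))
}

#' Score every CS presentation of one phase
#'
#' @param trace The observer's raw [eda_trace()] for the phase.
#' @param schedule The block's `event_schedule`.
#' @param cfg A [preprocess_config()].
#' @return A `data.frame` with one row per CS presentation: `dyad_id`,
#'   `block`, `phase`, `trial_index`, `cs`, `cs_code` (+0.5 CS+, -0.5 CS-),
#'   `amplitude_raw` and `amplitude_tx` (transform applied).
#' @export
score_phase <- function(trace, schedule, cfg = preprocess_config()) {
  stopifnot(inherits(trace, "eda_trace"))
  ph <- trace$phase
  s <- schedule[schedule$phase == ph, ]
  if (nrow(s) == 0L) stop("schedule has no '", ph, "' trials")
  amp <- vapply(s$onset_s, function(o) score_scr(trace, o, cfg), 0)
  data.frame(dyad_id = trace$dyad_id, block = trace$block, phase = ph,
             trial_index = s$trial_index, cs = s$cs,
             cs_code = ifelse(s$cs == "plus", 0.5, -0.5),
             amplitude_raw = amp,
             amplitude_tx = apply_transform(amp, cfg$transform),
             stringsAsFactors = FALSE)
}

#' Observer responses to the social unconditioned stimulus
#'
#' Scores the observer's response to each demonstrator shock in the
#' learning phase, with the scoring windows anchored at shock delivery.
#'
#' @param observer_trace The observer's raw learning-phase [eda_trace()].
#' @param schedule The block's `event_schedule`.
#' @param cfg A [preprocess_config()].
#' @return List with `amplitudes` (one per shock, microsiemens) and their
#'   `mean`.
#' @export
ucs_responses <- function(observer_trace, schedule,
                          cfg = preprocess_config()) {
  s <- schedule[schedule$phase == "learning" & schedule$shock, ]
  if (nrow(s) == 0L) stop("no shock events in the learning phase")
  amp <- vapply(s$shock_time_s,
                function(o) score_scr(observer_trace, o, cfg), 0)
  list(amplitudes = amp, mean = mean(amp))
}
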