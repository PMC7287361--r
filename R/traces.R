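#' Phasic skin conductance trace
#'
#' A uniformly sampled phasic electrodermal signal for one participant,
#' phase and block. Time starts at 0 at phase onset.
#'
#' @param values Numeric vector of conductance samples, microsiemens.
#' @param sample_rate Sampling rate, Hz.
#' @param dyad_id,role,block,phase Identity metadata; `role` is
#'   `"demonstrator"` or `"observer"`.
#' @return An object of class `eda_trace`.
#' @export
eda_trace <- function(values, sample_rate, dyad_id = NA_integer_,
                      role = NA_character_, block = NA_integer_,
                      phase = NA_character_) {
  stopifnot(is.numeric(values), length(values) >= 1L, sample_rate > 0)
  structure(list(values = as.numeric(values),
                 sample_rate = sample_rate,
                 dyad_id = dyad_id, role = role,
                 block = as.integer(block), phase = phase),
            class = "eda_trace")
}

#' @export
print.eda_trace <- function(x, ...) {
  cat(sprintf("eda_trace: dyad %s %s, block %s, %s phase\n",
              x$dyad_id, x$role, x$block, x$phase))
  cat(sprintf("  %d samples at %g Hz (%.1f s), range [%.3f, %.3f]\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Time axis of a trace
#' @param trace An `eda_trace`.
#' @return Seconds from phase start, one per sample.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$values) - 1) / trace$sample_rate
}

#' Evaluate an SCR kernel
#'
#' Peak-normalised difference of exponentials: zero for `t < latency`, then
#' `amplitude * (exp(-s/tau_decay) - exp(-s/tau_rise)) / norm` with
#' `s = t - latency` and `norm` such that the maximum equals `amplitude`.
#'
#' @param kernel An [scr_kernel()].
#' @param t Time(s) in seconds, relative to event onset.
#' @return Conductance in microsiemens, same length as `t`.
#' @export
scr_kernel_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "scr_kernel"))
  s <- t - kernel$latency
  out <- numeric(length(t))
  pos <- s > 0
  if (any(pos)) {
    sp <- s[pos]
    raw <- exp(-sp / kernel$tau_decay) - exp(-sp / kernel$tau_rise)
    s_peak <- scr_kernel_peak_time(kernel) - kernel$latency
    norm <- exp(-s_peak / kernel$tau_decay) - exp(-s_peak / kernel$tau_rise)
    out[pos] <- kernel$amplitude * raw / norm
  }
  out
}

#' Peak time of an SCR kernel
#'
#' Closed-form argmax of the two-exponential kernel, measured from event
#' onset (latency included).
#'
#' @param kernel An [scr_kernel()].
#' @return Time of the kernel maximum, seconds.
#' @export
scr_kernel_peak_time <- function(kernel) {
  td <- kernel$tau_decay
  tr <- kernel$tau_rise
  kernel$latency + log(td / tr) * td * tr / (td - tr)
}

#' Individual signal traits of one participant
#'
#' Stable between-person differences in phasic EDA: overall event-response
#' amplitude, background-drive strength and micro-fluctuation roughness.
#' Coupling makes a dyad's two signals dynamically similar because the
#' observer inherits a kappa-share of the demonstrator's process — traits
#' included — while the residual share carries the observer's own traits.
#'
#' @param amp_scale Multiplier on event-response amplitudes.
#' @param drive_scale Multiplier on the slow arousal drive.
#' @param micro_scale Multiplier on the fast micro-fluctuation drive.
#' @return A list of class `eda_traits`.
#' @export
eda_traits <- function(amp_scale = 1, drive_scale = 1, micro_scale = 1,
                       tau_rise = 0.75, tau_decay = 2.5, latency = 1) {
  stopifnot(amp_scale >= 0, drive_scale >= 0, micro_scale >= 0,
            tau_rise > 0, tau_decay > tau_rise, latency >= 0)
  structure(list(amp_scale = amp_scale, drive_scale = drive_scale,
                 micro_scale = micro_scale, tau_rise = tau_rise,
                 tau_decay = tau_decay, latency = latency),
            class = "eda_traits")
}

#' Draw random participant traits
#' @param sdlog Log-scale SD of the lognormal trait multipliers.
#' @return An [eda_traits()].
#' @export
draw_traits <- function(sdlog = 0.6, shape_sdlog = 0.15) {
  v <- stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  tr <- 0.75 * stats::rlnorm(1, sdlog = shape_sdlog)
  td <- 2.5 * stats::rlnorm(1, sdlog = shape_sdlog)
  eda_traits(amp_scale = v[1], drive_scale = v[2], micro_scale = v[3],
             tau_rise = tr, tau_decay = max(td, 2 * tr),
             latency = stats::rlnorm(1, sdlog = shape_sdlog))
}

## event kernels re-shaped with one participant's response-form traits
## (amplitudes kept, time constants replaced)
trait_kernels <- function(kernels, traits) {
  lapply(kernels, function(k) {
    scr_kernel(k$amplitude, traits$tau_rise, traits$tau_decay,
               traits$latency)
  })
}

## unjittered amplitude for an event type
event_base_amp <- function(type, kernels, spont_amplitude = 0.25) {
  if (type == "spontaneous") spont_amplitude
  else kernels[[type]]$amplitude
}

## Slow arousal envelope: a smooth standardized process (white noise on a
## coarse knot grid, spline-interpolated) that modulates SCR amplitudes
## over tens of seconds.
make_envelope <- function(duration, knot_spacing = 8) {
  n_knots <- max(4L, ceiling(duration / knot_spacing) + 1L)
  kt <- seq(0, duration, length.out = n_knots)
  kv <- stats::rnorm(n_knots)
  f <- stats::splinefun(kt, kv, method = "natural")
  ## standardize the realised path so every envelope has unit variance
  ## over the phase (removes realisation-to-realisation scale noise)
  grid <- f(seq(0, duration, by = 0.25))
  mu <- mean(grid); sg <- stats::sd(grid)
  if (!is.finite(sg) || sg == 0) sg <- 1
  function(t) (f(pmin(pmax(t, 0), duration)) - mu) / sg
}

## amplitude scale at event times under envelope s(t): 1 + mod * s(t),
## floored so amplitudes stay positive
envelope_scale <- function(env_fn, t, arousal_mod) {
  pmax(0.05, 1 + arousal_mod * env_fn(t))
}

## mean-one lognormal amplitude jitter
amp_jitter <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Nonspecific (event-unrelated) SCRs: a Poisson stream at `rate`/minute.
spont_events <- function(duration, rate, amp_jitter_sdlog,
                         spont_amplitude = 0.25) {
  n_spont <- as.integer(round(rate * duration / 60))
  data.frame(
    time_s = stats::runif(n_spont, 0, max(0, duration - 4)),
    type = rep("spontaneous", n_spont),
    trial_index = rep(NA_integer_, n_spont),
    cs = rep(NA_character_, n_spont),
    amplitude = spont_amplitude * amp_jitter(n_spont, amp_jitter_sdlog),
    stringsAsFactors = FALSE)
}

## Sum event-locked kernels onto a uniform grid and add measurement
## noise. `events` is a data.frame: time_s, type, amplitude.
render_trace <- function(events, duration, sample_rate, kernels,
                         noise_sd, spont_kernel = NULL) {
  n <- ceiling(duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  spont_kernel <- if (is.null(spont_kernel)) scr_kernel(amplitude = 1)
    else scr_kernel(1, spont_kernel$tau_rise, spont_kernel$tau_decay,
                    spont_kernel$latency)
  for (i in seq_len(nrow(events))) {
    k <- if (events$type[i] == "spontaneous") spont_kernel
         else kernels[[events$type[i]]]
    if (events$amplitude[i] == 0) next
    ## kernel support is effectively over after ~10 decay constants
    lo <- events$time_s[i] + k$latency
    hi <- lo + 10 * k$tau_decay
    idx <- which(tt > lo & tt <= hi)
    if (!length(idx)) next
    ku <- scr_kernel(1, k$tau_rise, k$tau_decay, k$latency)
    x[idx] <- x[idx] +
      events$amplitude[i] * scr_kernel_eval(ku, tt[idx] - events$time_s[i])
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
  x
}

## scheduled events for one phase, with demonstrator-side amplitudes
phase_events <- function(schedule, phase, kernels, amp_jitter_sdlog) {
  s <- schedule[schedule$phase == phase, ]
  type <- ifelse(s$cs == "plus", "cs_plus", "cs_minus")
  ev <- data.frame(time_s = s$onset_s, type = type,
                   trial_index = s$trial_index, cs = s$cs,
                   stringsAsFactors = FALSE)
  shocked <- s[s$shock, ]
  if (nrow(shocked) > 0) {
    ev <- rbind(ev, data.frame(time_s = shocked$shock_time_s,
                               type = "shock",
                               trial_index = shocked$trial_index,
                               cs = shocked$cs, stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$time_s), ]
  base_amp <- vapply(ev$type, function(tp) kernels[[tp]]$amplitude, 0)
  ev$amplitude <- base_amp * amp_jitter(nrow(ev), amp_jitter_sdlog)
  ev
}

#' Simulate a demonstrator's phasic conductance trace for one phase
#'
#' The trace is the sum of event-locked SCR kernels for every scheduled CS
#' onset and shock (amplitudes jittered by a mean-one lognormal), a Poisson
#' process of nonspecific SCRs, and additive Gaussian noise. During the
#' testing phase the demonstrator sits with eyes closed and contributes
#' only nonspecific activity.
#'
#' @param schedule An `event_schedule`.
#' @param phase `"learning"` or `"testing"`.
#' @param kernels Named list of [scr_kernel()]s for `shock`, `cs_plus`,
#'   `cs_minus` (see [default_kernels()]); the shock kernel should dominate.
#' @param coupling A [coupling_config()] (noise and spontaneous settings).
#' @param sample_rate Hz.
#' @return An `eda_trace`; the event table (with realised per-event
#'   amplitudes) is attached as attribute `"events"`.
#' @export
synth_demonstrator_trace <- function(schedule, phase, kernels, coupling,
                                     sample_rate, traits = eda_traits()) {
  s <- schedule[schedule$phase == phase, ]
  if (nrow(s) == 0L) stop("schedule has no '", phase, "' events")
  duration <- phase_duration(schedule, phase)
  if (phase == "learning") {
    ev <- phase_events(schedule, phase, kernels, coupling$amp_jitter_sdlog)
  } else {
    ev <- data.frame(time_s = numeric(0), type = character(0),
                     trial_index = integer(0), cs = character(0),
                     amplitude = numeric(0), stringsAsFactors = FALSE)
  }
  ev <- rbind(ev, spont_events(duration, coupling$spontaneous_rate,
                               coupling$amp_jitter_sdlog))
  ev <- ev[order(ev$time_s), ]
  ev$amplitude <- ev$amplitude * traits$amp_scale
  ## arousal waves modulate response strength and contribute a wandering
  ## background drive during the learning phase, on a slow (tens of
  ## seconds) and a fast (seconds) timescale; the drive carries the
  ## participant's individual trait scales
  env_fn <- make_envelope(duration)
  micro_fn <- make_envelope(duration, knot_spacing = 0.3)
  drive_fn <- function(t) {
    coupling$arousal_drive * traits$drive_scale * env_fn(t) +
      coupling$micro_drive * traits$micro_scale * micro_fn(t)
  }
  x_drive <- 0
  if (phase == "learning") {
    if (nrow(ev) > 0) {
      ev$amplitude <- ev$amplitude *
        envelope_scale(env_fn, ev$time_s, coupling$arousal_mod)
    }
    tt <- (seq_len(ceiling(duration * sample_rate)) - 1) / sample_rate
    x_drive <- drive_fn(tt)
  }
  x <- render_trace(ev[, c("time_s", "type", "amplitude")], duration,
                    sample_rate, trait_kernels(kernels, traits),
                    coupling$noise_sd, spont_kernel = traits) + x_drive
  attr(ev, "envelope") <- env_fn
  attr(ev, "drive_fn") <- drive_fn
  tr <- eda_trace(x, sample_rate, role = "demonstrator", phase = phase)
  attr(tr, "events") <- ev
  tr
}

#' Simulate an observer's phasic conductance trace for one phase
#'
#' Learning phase: the observer's event-response drive is a kappa-mixture
#' of the demonstrator's drive and an independent one, realised per event.
#' Each demonstrator CS response is mirrored with probability `kappa`
#' (shared amplitude, delayed by `coupling$lag` with Gaussian timing
#' jitter of SD `(1 - kappa) * latency_jitter_sd`) and otherwise replaced
#' by an independent response (own amplitude, random time), so the
#' expected drive is `kappa * demonstrator + (1 - kappa) * independent`
#' while event count and amplitude distribution stay kappa-invariant.
#' Responses to the social unconditioned stimulus (the demonstrator being
#' shocked) are always time-locked — every observer reacts to seeing a
#' shock — with amplitude `kappa * demonstrator amplitude + (1 - kappa) *
#' independent draw`. At `kappa = 1` (zero lag, noise and nonspecific
#' activity off) the observer trace equals the demonstrator trace; at
#' `kappa = 0` the CS-related drive is fully independent. Testing phase:
#' CS-onset amplitudes follow the threat-learning model
#' `a = beta0 + (beta_cs_base + learning_gain * kappa) * cs_code *
#' exp(-extinction_rate * (k - 1)) + noise`, `cs_code` deviation-coded
#' (+0.5 CS+, -0.5 CS-), `k` the within-CS presentation number, noise a
#' scaled mean-centred lognormal, amplitudes floored at zero; the final
#' (shocked) CS+ also elicits an independent shock response. Both phases
#' add independent nonspecific SCRs and Gaussian noise.
#'
#' @param demo_events Event table from [synth_demonstrator_trace()]
#'   (attribute `"events"`); needed for the learning phase.
#' @param schedule An `event_schedule`.
#' @param phase `"learning"` or `"testing"`.
#' @param coupling A [coupling_config()].
#' @param kernels Named list of [scr_kernel()]s.
#' @param sample_rate Hz.
#' @param a_noise_scale Scale of the testing-phase amplitude noise,
#'   microsiemens.
#' @return An `eda_trace` with the observer's event table attached as
#'   attribute `"events"`.
#' @export
synth_observer_trace <- function(demo_events, schedule, phase, coupling,
                                 kernels, sample_rate,
                                 traits = eda_traits(),
                                 a_noise_scale = 0.15) {
  kappa <- coupling$kappa
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (phase == "learning") {
    ev <- demo_events
    if (is.null(ev) || nrow(ev) == 0L) {
      stop("learning-phase observer needs the demonstrator event table")
    }
    is_shock <- ev$type == "shock"
    span <- phase_duration(schedule, "learning")
    ## observer's arousal process: kappa-share of the demonstrator's
    ## (traits included) plus an independent remainder carrying the
    ## observer's own traits
    env_d <- attr(demo_events, "envelope")
    if (is.null(env_d)) env_d <- make_envelope(span)
    env_i <- make_envelope(span)
    env_o <- function(t) {
      kappa * env_d(pmax(0, t - coupling$lag)) +
        sqrt(1 - kappa^2) * env_i(t)
    }
    drive_d <- attr(demo_events, "drive_fn")
    if (is.null(drive_d)) drive_d <- function(t) 0 * t
    micro_i <- make_envelope(span, knot_spacing = 0.3)
    own_drive <- function(t) {
      coupling$arousal_drive * traits$drive_scale * env_i(t) +
        coupling$micro_drive * traits$micro_scale * micro_i(t)
    }
    drive_o <- function(t) {
      kappa * drive_d(pmax(0, t - coupling$lag)) +
        sqrt(1 - kappa^2) * own_drive(t)
    }
    base_amp <- vapply(ev$type, event_base_amp, 0, kernels = kernels) *
      traits$amp_scale
    indep_amp <- base_amp * amp_jitter(nrow(ev), coupling$amp_jitter_sdlog)
    ## each demonstrator response (CS-locked or nonspecific) is mirrored
    ## with probability kappa (shared amplitude, tight timing) or replaced
    ## by an independent response at a random time: Bernoulli thinning
    ## keeps event count and amplitude distribution kappa-invariant while
    ## the expected drive is kappa * demonstrator + (1 - kappa) * own
    mirrored <- is_shock | (stats::runif(nrow(ev)) < kappa)
    jit <- (1 - kappa) * coupling$latency_jitter_sd
    t_mirror <- pmax(0, ev$time_s + coupling$lag +
                          if (jit > 0) stats::rnorm(nrow(ev), sd = jit)
                          else 0)
    t_new <- ifelse(mirrored, t_mirror,
                    stats::runif(nrow(ev), 0, span - 4))
    ## mirrored responses inherit the demonstrator's realised amplitude
    ## (envelope included); independent ones ride the observer's own
    ## arousal envelope
    indep_amp <- indep_amp *
      envelope_scale(env_o, t_new, coupling$arousal_mod)
    ev$amplitude <- ifelse(
      is_shock,
      coupling$vicarious_gain *
        (kappa * ev$amplitude + (1 - kappa) * indep_amp),
      ifelse(mirrored, ev$amplitude, indep_amp))
    ev$time_s <- t_new
    ev <- ev[order(ev$time_s), ]
  } else {
    s <- schedule[schedule$phase == "testing", ]
    cs_code <- ifelse(s$cs == "plus", 0.5, -0.5)
    k_within <- stats::ave(seq_len(nrow(s)), s$cs, FUN = seq_along)
    det <- coupling$beta0 +
      (coupling$beta_cs_base + coupling$learning_gain * kappa) * cs_code *
      exp(-coupling$extinction_rate * (k_within - 1))
    noise <- a_noise_scale *
      (amp_jitter(nrow(s), coupling$amp_jitter_sdlog) - 1)
    amp <- pmax(0, det + noise)
    ev <- data.frame(time_s = s$onset_s,
                     type = ifelse(s$cs == "plus", "cs_plus", "cs_minus"),
                     trial_index = s$trial_index, cs = s$cs,
                     amplitude = amp, stringsAsFactors = FALSE)
    shocked <- s[s$shock, ]
    if (nrow(shocked) > 0) {
      ev <- rbind(ev, data.frame(
        time_s = shocked$shock_time_s, type = "shock",
        trial_index = shocked$trial_index, cs = shocked$cs,
        amplitude = kernels$shock$amplitude *
          amp_jitter(nrow(shocked), coupling$amp_jitter_sdlog),
        stringsAsFactors = FALSE))
    }
    ev <- rbind(ev, spont_events(phase_duration(schedule, "testing"),
                                 coupling$spontaneous_rate,
                                 coupling$amp_jitter_sdlog))
    ev <- ev[order(ev$time_s), ]
  }
  duration <- phase_duration(schedule, phase)
  x_drive <- 0
  if (phase == "learning") {
    tt <- (seq_len(ceiling(duration * sample_rate)) - 1) / sample_rate
    x_drive <- drive_o(tt)
  }
  x <- render_trace(ev[, c("time_s", "type", "amplitude")], duration,
                    sample_rate, trait_kernels(kernels, traits),
                    coupling$noise_sd, spont_kernel = traits) + x_drive
  tr <- eda_trace(x, sample_rate, role = "observer", phase = phase)
  attr(tr, "events") <- ev
  tr
}
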