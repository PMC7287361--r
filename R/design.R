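#' Experimental design configuration
#'
#' Bundles the constants of the dyadic observational-conditioning design:
#' each block is a learning phase (alternating CS+/CS- presentations watched
#' by the observer while the demonstrator is conditioned) followed by a
#' testing phase (both CSs shown repeatedly to the observer alone).
#'
#' @param n_dyads Number of demonstrator-observer dyads.
#' @param n_blocks Number of blocks; roles reverse after the first half.
#' @param n_cs_each_learning Presentations of each CS in the learning phase.
#' @param n_shocked_csplus How many learning CS+ presentations end in shock.
#' @param cs_duration CS image duration, seconds.
#' @param iti_range Length-2 numeric, uniform inter-trial-interval bounds in
#'   seconds (offset of one CS to onset of the next).
#' @param n_cs_each_testing Presentations of each CS in the testing phase;
#'   only the final CS+ presentation is shocked.
#' @param sample_rate Sampling rate of the simulated conductance traces, Hz.
#' @param seed Integer seed recorded with the design.
#'
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_dyads = 69L,
                          n_blocks = 4L,
                          n_cs_each_learning = 6L,
                          n_shocked_csplus = 4L,
                          cs_duration = 6,
                          iti_range = c(10, 16),
                          n_cs_each_testing = 7L,
                          sample_rate = 32,
                          seed = 1L) {
  n_dyads <- as.integer(n_dyads)
  n_blocks <- as.integer(n_blocks)
  n_cs_each_learning <- as.integer(n_cs_each_learning)
  n_shocked_csplus <- as.integer(n_shocked_csplus)
  n_cs_each_testing <- as.integer(n_cs_each_testing)
  stopifnot(n_dyads >= 1L, n_blocks >= 1L,
            n_cs_each_learning >= 1L, n_cs_each_testing >= 1L,
            cs_duration > 0, length(iti_range) == 2L)
  if (n_shocked_csplus > n_cs_each_learning) {
    stop("n_shocked_csplus (", n_shocked_csplus,
         ") cannot exceed n_cs_each_learning (", n_cs_each_learning, ")")
  }
  if (iti_range[1] > iti_range[2]) {
    stop("iti_range must be ordered (min <= max)")
  }
  if (sample_rate < 8) {
    stop("sample_rate must be at least 8 Hz (the analysis rate)")
  }
  structure(
    list(n_dyads = n_dyads, n_blocks = n_blocks,
         n_cs_each_learning = n_cs_each_learning,
         n_shocked_csplus = n_shocked_csplus,
         cs_duration = cs_duration, iti_range = as.numeric(iti_range),
         n_cs_each_testing = n_cs_each_testing,
         sample_rate = sample_rate, seed = as.integer(seed)),
    class = "design_config"
  )
}

#' Skin conductance response kernel
#'
#' Canonical phasic-EDA impulse shape: a peak-normalised difference of
#' exponentials (Bateman form). The response is zero before `latency`,
#' rises with time constant `tau_rise` and decays with `tau_decay`; the
#' peak height equals `amplitude` microsiemens.
#'
#' @param amplitude Peak height, microsiemens.
#' @param tau_rise Rise time constant, seconds.
#' @param tau_decay Decay time constant, seconds; must exceed `tau_rise`.
#' @param latency Onset-to-response delay, seconds.
#' @return An object of class `scr_kernel`.
#' @export
scr_kernel <- function(amplitude = 1, tau_rise = 0.75, tau_decay = 2.5,
                       latency = 1) {
  stopifnot(amplitude >= 0, tau_rise > 0, latency >= 0)
  if (tau_rise >= tau_decay) {
    stop("tau_rise must be strictly smaller than tau_decay")
  }
  structure(list(amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, latency = latency),
            class = "scr_kernel")
}

#' Demonstrator-to-observer coupling configuration
#'
#' Controls how much of the observer's event-related arousal is inherited
#' from the demonstrator, and how coupling translates into later threat
#' learning.
#'
#' @param kappa Coupling strength in \[0, 1\]: the fraction of each
#'   observer event-response amplitude copied from the demonstrator's
#'   amplitude for the same event (the remainder is drawn independently).
#' @param lag Demonstrator-to-observer response delay, seconds.
#' @param spontaneous_rate Rate of nonspecific (event-unrelated) SCRs,
#'   events per minute, for each participant independently.
#' @param noise_sd Additive Gaussian measurement noise, microsiemens.
#' @param learning_gain Slope linking `kappa` to the observer's testing-phase
#'   CS+/CS- amplitude difference (microsiemens per unit kappa).
#' @param extinction_rate Per-presentation exponential decay of the
#'   testing-phase differential response.
#' @param beta0 Baseline testing-phase response amplitude, microsiemens.
#' @param beta_cs_base Coupling-independent part of the testing-phase
#'   differential response, microsiemens.
#' @param amp_jitter_sdlog Log-scale SD of the mean-one lognormal jitter
#'   applied to every event amplitude.
#' @param latency_jitter_sd SD (seconds) of the observer's response-timing
#'   jitter at `kappa = 0`; the jitter shrinks linearly to 0 at
#'   `kappa = 1`, so a fully coupled observer tracks the demonstrator's
#'   event responses tightly while an uncoupled one responds loosely.
#' @param vicarious_gain Scale of the observer's response to the social
#'   unconditioned stimulus (seeing the demonstrator shocked) relative to
#'   the demonstrator's own shock response.
#' @param arousal_mod Depth of the slow arousal-envelope modulation of
#'   learning-phase response amplitudes (0 disables it); the observer's
#'   envelope shares a `kappa` fraction of the demonstrator's.
#' @param arousal_drive SD (microsiemens) of the additive slow drive
#'   component the envelope contributes to the learning-phase signal — the
#'   wandering background level of phasic sympathetic activity.
#' @param micro_drive SD (microsiemens) of the fast (seconds-scale)
#'   micro-fluctuation drive; like the slow envelope, the observer shares
#'   a `kappa` fraction of the demonstrator's micro-fluctuations.
#' @param trait_sdlog Log-scale SD of the lognormal individual-difference
#'   multipliers drawn per participant (see [draw_traits()]).
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(kappa = 0.5, lag = 1, spontaneous_rate = 4,
                            noise_sd = 0.005, learning_gain = 0.5,
                            extinction_rate = 0.12, beta0 = 0.4,
                            beta_cs_base = 0.1, amp_jitter_sdlog = 0.4,
                            latency_jitter_sd = 2.5,
                            vicarious_gain = 0.6, arousal_mod = 0.5,
                            arousal_drive = 0.3, micro_drive = 0.1,
                            trait_sdlog = 0.6) {
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  stopifnot(lag >= 0, spontaneous_rate >= 0, noise_sd >= 0,
            extinction_rate >= 0, amp_jitter_sdlog >= 0,
            latency_jitter_sd >= 0, vicarious_gain >= 0, arousal_mod >= 0,
            arousal_drive >= 0, micro_drive >= 0, trait_sdlog >= 0)
  structure(list(kappa = kappa, lag = lag,
                 spontaneous_rate = spontaneous_rate, noise_sd = noise_sd,
                 learning_gain = learning_gain,
                 extinction_rate = extinction_rate, beta0 = beta0,
                 beta_cs_base = beta_cs_base,
                 amp_jitter_sdlog = amp_jitter_sdlog,
                 latency_jitter_sd = latency_jitter_sd,
                 vicarious_gain = vicarious_gain,
                 arousal_mod = arousal_mod,
                 arousal_drive = arousal_drive,
                 micro_drive = micro_drive,
                 trait_sdlog = trait_sdlog),
            class = "coupling_config")
}

#' Default event kernels
#'
#' Shock responses are the largest; CS+ and CS- onset responses are smaller
#' and nearly matched so that learning-phase differentiation is not built in.
#'
#' @return Named list of `scr_kernel` objects for event types
#'   `shock`, `cs_plus`, `cs_minus`.
#' @export
default_kernels <- function() {
  list(shock = scr_kernel(amplitude = 1.0),
       cs_plus = scr_kernel(amplitude = 0.4),
       cs_minus = scr_kernel(amplitude = 0.35))
}

#' @export
print.design_config <- function(x, ...) {
  cat("Dyadic conditioning design\n")
  cat(sprintf("  %d dyads x %d blocks\n", x$n_dyads, x$n_blocks))
  cat(sprintf("  learning: %d CS+ / %d CS- (alternating), %d CS+ shocked\n",
              x$n_cs_each_learning, x$n_cs_each_learning,
              x$n_shocked_csplus))
  cat(sprintf("  testing: %d per CS, final CS+ shocked\n",
              x$n_cs_each_testing))
  cat(sprintf("  CS %.1f s, ITI %.0f-%.0f s, %.0f Hz\n",
              x$cs_duration, x$iti_range[1], x$iti_range[2], x$sample_rate))
  invisible(x)
}
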