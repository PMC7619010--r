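#' Truncated geometric distribution over event sizes
#'
#' Probability weights for the number of vesicles in a single multivesicular
#' release event, a geometric law truncated to \code{1:kmax} and renormalised.
#'
#' @param p success probability of the underlying geometric (larger = more
#'   uniquantal events).
#' @param kmax largest event size.
#' @return numeric vector of length \code{kmax} summing to 1.
#' @export
mvr_geometric <- function(p = 0.55, kmax = 5) {
  stopifnot(p > 0, p < 1, kmax >= 1)
  w <- p * (1 - p)^(seq_len(kmax) - 1)
  w / sum(w)
}

#' Synapse condition regime
#'
#' Parameter bundle describing the release statistics and imaging noise of a
#' bipolar-cell synapse under one experimental condition.
#'
#' @param spont_rate spontaneous release, vesicles per second.
#' @param evoked_max Hill scale of the stimulus-locked response; the expected
#'   quanta per stimulus cycle at contrast C is
#'   \code{evoked_max * C^h / (C^h + c50^h)}.
#' @param hill_c50 half-maximal contrast, percent.
#' @param hill_h Hill coefficient.
#' @param mvr_weights probability weights over event sizes \code{1:length(mvr_weights)}
#'   (multivesicular release).
#' @param quantal_dff reporter response per vesicle, dF/F0 units.
#' @param noise_sd additive recording noise SD, dF/F0 units.
#' @param bleach_tau mono-exponential bleaching time constant, seconds
#'   (\code{Inf} disables bleaching).
#' @param phase_jitter_sd SD of the timing jitter of stimulus-locked events,
#'   seconds.
#' @param label optional condition label.
#' @return an object of class \code{"synapse_regime"}.
#' @export
synapse_regime <- function(spont_rate = 0.8, evoked_max = 5.19,
                           hill_c50 = 35, hill_h = 1.5,
                           mvr_weights = mvr_geometric(),
                           quantal_dff = 0.5, noise_sd = 0.1,
                           bleach_tau = 300, phase_jitter_sd = 0.010,
                           label = NA_character_) {
  stopifnot(spont_rate >= 0, evoked_max >= 0,
            hill_c50 > 0, hill_c50 <= 100, hill_h > 0,
            all(mvr_weights >= 0), abs(sum(mvr_weights) - 1) < 1e-8,
            quantal_dff > 0, noise_sd >= 0, bleach_tau > 0,
            phase_jitter_sd >= 0)
  structure(list(spont_rate = spont_rate, evoked_max = evoked_max,
                 hill_c50 = hill_c50, hill_h = hill_h,
                 mvr_weights = mvr_weights / sum(mvr_weights),
                 quantal_dff = quantal_dff, noise_sd = noise_sd,
                 bleach_tau = bleach_tau, phase_jitter_sd = phase_jitter_sd,
                 label = label),
            class = "synapse_regime")
}

#' Behavioral condition regime
#'
#' Parameters of optomotor swimming under one condition. Bout frequency
#' depends on contrast through a Hill function; turn amplitude does not (the
#' same angle parameters are shared across the default diurnal regimes).
#' Spontaneous (base-rate) bouts are unbiased in direction; only
#' stimulus-evoked bouts are signed toward the drift with probability
#' \code{p_correct}, so at zero contrast left and right turns are equally
#' probable.
#'
#' @param base_bout_rate spontaneous bout rate at zero contrast, bouts/s.
#' @param max_bout_rate bout rate at saturating contrast, bouts/s.
#' @param bout_hill_c50 half-maximal contrast of bout-rate modulation, percent.
#' @param bout_hill_h Hill coefficient of bout-rate modulation.
#' @param p_correct probability a stimulus-evoked turn is toward the drift.
#' @param angle_mean,angle_sd mean and SD of the unsigned turn angle, radians.
#' @param scoot_fraction probability a bout is a forward scoot (negligible turn).
#' @param frame_rate camera sampling rate, Hz.
#' @param label optional condition label.
#' @return an object of class \code{"behavior_regime"}.
#' @export
behavior_regime <- function(base_bout_rate = 0.5, max_bout_rate = 2.1,
                            bout_hill_c50 = 31, bout_hill_h = 1.9,
                            p_correct = 0.85, angle_mean = 0.45,
                            angle_sd = 0.15, scoot_fraction = 0.4,
                            frame_rate = 150, label = NA_character_) {
  stopifnot(base_bout_rate >= 0, max_bout_rate >= base_bout_rate,
            bout_hill_c50 > 0, bout_hill_h > 0,
            p_correct >= 0, p_correct <= 1,
            angle_mean >= 0, angle_sd >= 0,
            scoot_fraction >= 0, scoot_fraction <= 1,
            frame_rate > 0)
  structure(list(base_bout_rate = base_bout_rate,
                 max_bout_rate = max_bout_rate,
                 bout_hill_c50 = bout_hill_c50, bout_hill_h = bout_hill_h,
                 p_correct = p_correct, angle_mean = angle_mean,
                 angle_sd = angle_sd, scoot_fraction = scoot_fraction,
                 frame_rate = frame_rate, label = label),
            class = "behavior_regime")
}

#' Stimulus protocol
#'
#' A sequence of fixed-contrast trials presented at a given temporal
#' frequency. The default trial-based protocol presents each contrast
#' \code{n_repeats} times in pseudo-random order.
#'
#' @param contrasts contrast levels, percent (0-100).
#' @param duration trial duration, seconds (recycled across contrasts).
#' @param n_repeats presentations per contrast.
#' @param temporal_freq stimulus temporal frequency, Hz.
#' @param randomize pseudo-randomise trial order (deterministically, from
#'   \code{order_seed}).
#' @param order_seed seed used only for the trial ordering.
#' @return an object of class \code{"stim_protocol"} with a trial
#'   \code{schedule} data frame (columns \code{contrast}, \code{duration},
#'   \code{start}, \code{trial}).
#' @export
stim_protocol <- function(contrasts, duration = 2, n_repeats = 100,
                          temporal_freq = 5, randomize = TRUE,
                          order_seed = 1L) {
  stopifnot(length(contrasts) >= 1, all(contrasts >= 0), all(contrasts <= 100),
            all(duration > 0), temporal_freq > 0, n_repeats >= 1)
  sched <- data.frame(
    contrast = rep(rep(contrasts, length.out = length(contrasts)), n_repeats),
    duration = rep(rep(duration, length.out = length(contrasts)), n_repeats)
  )
  if (randomize && nrow(sched) > 1) {
    ord <- withr_seed(order_seed, sample.int(nrow(sched)))
    sched <- sched[ord, , drop = FALSE]
  }
  sched$start <- cumsum(c(0, sched$duration[-nrow(sched)]))
  sched$trial <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  structure(list(contrasts = sort(unique(contrasts)), schedule = sched,
                 temporal_freq = temporal_freq, n_repeats = n_repeats),
            class = "stim_protocol")
}

#' Single-contrast protocol
#'
#' Convenience wrapper for one long fixed-contrast presentation (the 30-60 s
#' free-swimming protocol, or a no-stimulus recording at contrast 0).
#'
#' @param contrast percent contrast.
#' @param duration seconds.
#' @param temporal_freq Hz.
#' @export
protocol_constant <- function(contrast, duration, temporal_freq = 5) {
  stim_protocol(contrast, duration = duration, n_repeats = 1,
                temporal_freq = temporal_freq, randomize = FALSE)
}

#' Hill contrast-response value
#'
#' \code{rmax * C^h / (C^h + c50^h)}, the saturating contrast-response
#' function used throughout.
#'
#' @param contrast percent contrast (scalar or vector).
#' @param rmax response scale.
#' @param c50 half-maximal contrast, percent.
#' @param h Hill coefficient.
#' @export
hill_response <- function(contrast, rmax, c50, h) {
  ifelse(contrast <= 0, 0, rmax * contrast^h / (contrast^h + c50^h))
}

protocol_duration <- function(protocol) sum(protocol$schedule$duration)

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
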