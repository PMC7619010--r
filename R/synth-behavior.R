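#' Simulate free-swimming optomotor trajectories
#'
#' Generates, per fish, a continuous trajectory covering every trial of the
#' protocol. Bout onsets arise from two superposed Poisson processes: a
#' spontaneous process at the regime's base rate whose turns are unbiased,
#' and a stimulus-evoked process at
#' \code{(max - base) * Hill(contrast)} whose turns are signed toward the
#' drift direction with probability \code{p_correct}. Each bout is a forward
#' scoot with probability \code{scoot_fraction}, otherwise a turn of
#' unsigned angle |N(angle_mean, angle_sd)|. Heading integrates a smooth
#' (raised-cosine) angular-velocity waveform per bout; position integrates a
#' matching speed waveform plus frame-wise tracking noise. Drift direction
#' alternates left/right across trials.
#'
#' @param regime a [behavior_regime()].
#' @param protocol a [stim_protocol()] (temporal frequency is not used by
#'   the behavior model; contrast and durations are).
#' @param n_fish number of fish.
#' @param seed integer seed.
#' @param bout_duration bout length, s.
#' @param peak_speed mean peak swim speed, mm/s.
#' @param pos_noise_sd tracking noise on position per frame, mm.
#' @return list of \code{"trajectory"} data frames (columns \code{time_s},
#'   \code{x_mm}, \code{y_mm}, \code{heading_rad}, \code{trial_id},
#'   \code{contrast_pct}, \code{drift_sign}) with the trial table and the
#'   ground-truth bout list as attributes.
#' @export
simulate_behavior <- function(regime, protocol, n_fish, seed,
                              bout_duration = 0.2, peak_speed = 20,
                              pos_noise_sd = 0.01) {
  stopifnot(inherits(regime, "behavior_regime"), n_fish >= 1)
  set.seed(seed)
  sched <- protocol$schedule
  sched$drift_sign <- rep(c(1, -1), length.out = nrow(sched))
  fr <- regime$frame_rate
  dt <- 1 / fr
  lapply(seq_len(n_fish), function(fish) {
    total <- sum(sched$duration)
    n_frames <- floor(total * fr)
    tgrid <- (seq_len(n_frames) - 1) * dt
    ang_vel <- numeric(n_frames)
    speed <- numeric(n_frames)
    gt <- list()
    for (i in seq_len(nrow(sched))) {
      tr <- sched[i, ]
      ev_rate <- (regime$max_bout_rate - regime$base_bout_rate) *
        hill_response(tr$contrast, 1, regime$bout_hill_c50,
                      regime$bout_hill_h)
      # bouts cannot overlap (dead time = bout + minimum gap); inflate the
      # generating rates so the *realized* bout rate matches the regime's
      # configured rate after refractory thinning
      dead <- bout_duration + 0.1
      lam <- regime$base_bout_rate + ev_rate
      infl <- 1 / (1 - min(lam * dead, 0.75))
      sp <- poisson_times(regime$base_bout_rate * infl, tr$duration)
      ev <- poisson_times(ev_rate * infl, tr$duration)
      onsets <- c(sp, ev)
      evoked <- c(rep(FALSE, length(sp)), rep(TRUE, length(ev)))
      ord <- order(onsets)
      onsets <- onsets[ord]; evoked <- evoked[ord]
      # minimum inter-bout interval: drop onsets within a bout's duration
      keep <- rep(TRUE, length(onsets))
      last_end <- -Inf
      for (j in seq_along(onsets)) {
        if (onsets[j] < last_end + 0.1) keep[j] <- FALSE
        else last_end <- onsets[j] + bout_duration
      }
      onsets <- onsets[keep]; evoked <- evoked[keep]
      if (!length(onsets)) next
      n_b <- length(onsets)
      is_scoot <- stats::runif(n_b) < regime$scoot_fraction
      mag <- abs(stats::rnorm(n_b, regime$angle_mean, regime$angle_sd))
      mag[is_scoot] <- abs(stats::rnorm(sum(is_scoot), 0, 0.01))
      sgn <- ifelse(evoked,
                    ifelse(stats::runif(n_b) < regime$p_correct, 1, -1),
                    sample(c(-1, 1), n_b, replace = TRUE))
      angle <- sgn * mag * tr$drift_sign  # drift_sign maps "toward drift"
                                          # onto the lab frame
      pk <- pmax(stats::rnorm(n_b, peak_speed, 0.15 * peak_speed),
                 peak_speed / 3)
      n_w <- max(2L, round(bout_duration * fr))
      w <- 0.5 * (1 - cos(2 * pi * (seq_len(n_w) - 0.5) / n_w))  # raised cos
      for (j in seq_len(n_b)) {
        i0 <- floor((tr$start + onsets[j]) * fr) + 1L
        idx <- i0:min(i0 + n_w - 1L, n_frames)
        wv <- w[seq_along(idx)]
        ang_vel[idx] <- ang_vel[idx] + angle[j] * wv / (sum(w) * dt)
        speed[idx] <- speed[idx] + pk[j] * wv
      }
      gt[[length(gt) + 1]] <- data.frame(
        trial_id = tr$trial, onset = tr$start + onsets,
        angle = angle, evoked = evoked, scoot = is_scoot)
    }
    heading <- cumsum(ang_vel) * dt
    xx <- cumsum(speed * cos(heading)) * dt +
      stats::rnorm(n_frames, 0, pos_noise_sd)
    yy <- cumsum(speed * sin(heading)) * dt +
      stats::rnorm(n_frames, 0, pos_noise_sd)
    trial_of <- findInterval(tgrid, c(sched$start, Inf),
                             rightmost.closed = FALSE)
    out <- data.frame(time_s = tgrid, x_mm = xx, y_mm = yy,
                      heading_rad = heading,
                      trial_id = sched$trial[trial_of],
                      contrast_pct = sched$contrast[trial_of],
                      drift_sign = sched$drift_sign[trial_of])
    structure(out, class = c("trajectory", "data.frame"),
              frame_rate = fr, trials = sched, fish = fish,
              ground_truth = if (length(gt)) do.call(rbind, gt)
                             else data.frame())
  })
}

poisson_times <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}
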