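#' Detect swim bouts in a trajectory
#'
#' The frame-by-frame swim speed is computed from position; a Gaussian is
#' fitted to the noise mode of the speed distribution (mode of the kernel
#' density, SD from the reflected lower half), and bouts are excursions
#' above mode + \code{threshold_mult} SD, with start/end at the threshold
#' crossings. Bouts closer than \code{min_interval} are merged.
#'
#' @param recording a \code{"trajectory"} data frame.
#' @param threshold_mult threshold in noise SDs above the noise mode.
#' @param min_interval minimum inter-bout interval, s.
#' @return \code{"bout_list"} data frame with columns \code{start},
#'   \code{end}, \code{peak_speed}, \code{trial_id}; attributes
#'   \code{threshold}, \code{noise_mu}, \code{noise_sd}.
#' @export
detect_bouts <- function(recording, threshold_mult = 3,
                         min_interval = 0.1) {
  fr <- attr(recording, "frame_rate")
  dt <- 1 / fr
  stopifnot(nrow(recording) >= 2 * fr)
  # a short running mean on position suppresses frame-to-frame tracking
  # noise before differentiation (window ~ 1/30 s, well under bout duration)
  w <- max(1L, round(fr / 30))
  xs <- running_mean(recording$x_mm, w)
  ys <- running_mean(recording$y_mm, w)
  sp <- c(0, sqrt(diff(xs)^2 + diff(ys)^2) / dt)
  dens <- stats::density(sp)
  mu <- dens$x[which.max(dens$y)]
  # the Gaussian tracking noise is per-axis; its SD (robust, insensitive to
  # the sparse bouts) sets the width of the speed noise mode
  sigma <- stats::median(c(stats::mad(diff(xs)), stats::mad(diff(ys)))) / dt
  if (!is.finite(sigma) || sigma <= 0 || mu > 10 * sigma)
    stop("no resolvable noise mode in the speed distribution")
  thr <- mu + threshold_mult * sigma
  above <- sp > thr
  if (!any(above)) {
    return(structure(data.frame(start = numeric(0), end = numeric(0),
                                peak_speed = numeric(0),
                                trial_id = integer(0)),
                     class = c("bout_list", "data.frame"),
                     threshold = thr, noise_mu = mu, noise_sd = sigma))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  gap <- max(1L, round(min_interval / dt))
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    last <- merged[[length(merged)]]
    if (runs[i, 1] - last[2] <= gap) merged[[length(merged)]][2] <- runs[i, 2]
    else merged[[length(merged) + 1]] <- runs[i, ]
  }
  out <- do.call(rbind, lapply(merged, function(rg) {
    i0 <- rg[1]; i1 <- rg[2]
    data.frame(start = recording$time_s[i0], end = recording$time_s[i1],
               peak_speed = max(sp[i0:i1]),
               trial_id = recording$trial_id[i0])
  }))
  structure(out, class = c("bout_list", "data.frame"),
            threshold = thr, noise_mu = mu, noise_sd = sigma)
}

# centred running mean with shrinking windows at the edges
running_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Measure signed bout angles and classify bouts
#'
#' The turning angle of each bout is the heading change between its start
#' and end (the heading trace is already unwrapped), signed so that positive
#' means toward the drift direction. Bouts with |angle| below
#' \code{scoot_threshold} are scoots; the rest are correct turns (positive)
#' or errors (negative).
#'
#' @param recording the \code{"trajectory"} the bouts came from.
#' @param bouts a [detect_bouts()] result.
#' @param scoot_threshold unsigned angle below which a bout is a scoot, rad.
#' @return the bout list with added columns \code{angle} (signed, rad) and
#'   \code{class} (\code{"correct"}, \code{"error"}, \code{"scoot"}).
#' @export
measure_bout_angles <- function(recording, bouts, scoot_threshold = 0.1) {
  fr <- attr(recording, "frame_rate")
  pad <- max(1L, round(0.05 * fr))  # settle margin around threshold crossings
  idx0 <- pmax(1L, round(bouts$start * fr) + 1L - pad)
  idx1 <- pmin(nrow(recording), round(bouts$end * fr) + 1L + pad)
  drift <- recording$drift_sign[pmax(1L, round(bouts$start * fr) + 1L)]
  angle <- (recording$heading_rad[idx1] - recording$heading_rad[idx0]) * drift
  cls <- ifelse(abs(angle) < scoot_threshold, "scoot",
                ifelse(angle > 0, "correct", "error"))
  bouts$angle <- angle
  bouts$class <- cls
  bouts
}

#' Summarise a trial's optomotor kinematics
#'
#' The cumulative turning angle is the sum of signed bout angles in the
#' trial; turning speed divides it by trial duration, and factorises exactly
#' into bout frequency times mean signed angle per bout.
#'
#' @param bouts an angled bout list (from [measure_bout_angles()]),
#'   restricted to one trial.
#' @param duration trial duration, s.
#' @return one-row data frame: \code{cumulative_angle}, \code{turning_speed},
#'   \code{bout_frequency}, \code{mean_angle_per_bout}.
#' @export
summarize_trial <- function(bouts, duration) {
  stopifnot(duration > 0)
  n <- nrow(bouts)
  cum <- if (n) sum(bouts$angle) else 0
  data.frame(cumulative_angle = cum,
             turning_speed = cum / duration,
             bout_frequency = n / duration,
             mean_angle_per_bout = if (n) cum / n else 0)
}

#' Per-trial kinematics for a whole trajectory
#'
#' Runs bout detection, angle measurement and per-trial summaries over every
#' trial of a recording.
#'
#' @param recording a \code{"trajectory"}.
#' @param threshold_mult bout threshold multiplier.
#' @param scoot_threshold scoot angle threshold, rad.
#' @return data frame of per-trial summaries with \code{trial_id},
#'   \code{contrast} and the [summarize_trial()] columns; the angled bout
#'   list is attached as attribute \code{bouts}.
#' @export
analyze_trajectory <- function(recording, threshold_mult = 3,
                               scoot_threshold = 0.1) {
  trials <- attr(recording, "trials")
  bouts <- detect_bouts(recording, threshold_mult)
  bouts <- measure_bout_angles(recording, bouts, scoot_threshold)
  out <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    b <- bouts[bouts$trial_id == tr$trial, , drop = FALSE]
    cbind(data.frame(trial_id = tr$trial, contrast = tr$contrast),
          summarize_trial(b, tr$duration))
  }))
  structure(out, bouts = bouts)
}

#' Behavioral contrast-response function across fish
#'
#' Averages turning speed per contrast within each fish, then returns the
#' mean and standard error across fish per contrast.
#'
#' @param cohort list of \code{"trajectory"} recordings (one per fish).
#' @param threshold_mult,scoot_threshold passed to [analyze_trajectory()].
#' @return a \code{"crf"} data frame: \code{contrast}, \code{response}
#'   (mean turning speed, rad/s), \code{sem}, \code{n}.
#' @export
build_behavior_crf <- function(cohort, threshold_mult = 3,
                               scoot_threshold = 0.1) {
  per_fish <- lapply(cohort, function(rec) {
    s <- analyze_trajectory(rec, threshold_mult, scoot_threshold)
    stats::aggregate(turning_speed ~ contrast, s, mean)
  })
  all <- do.call(rbind, Map(function(df, i) {
    df$fish <- i; df
  }, per_fish, seq_along(per_fish)))
  agg <- do.call(rbind, lapply(split(all, all$contrast), function(g) {
    data.frame(contrast = g$contrast[1], response = mean(g$turning_speed),
               sem = stats::sd(g$turning_speed) / sqrt(nrow(g)),
               n = nrow(g))
  }))
  agg <- agg[order(agg$contrast), ]
  rownames(agg) <- NULL
  structure(agg, class = c("crf", "data.frame"))
}
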