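#' Simulate a ground-truth vesicle release train
#'
#' Superposes a homogeneous Poisson spontaneous process with stimulus-locked
#' multivesicular release. Within each stimulus cycle, the number of release
#' events is Poisson with mean chosen so that the expected total quanta per
#' cycle equals the regime's Hill response at that trial's contrast; event
#' sizes are drawn from the regime's multivesicular weight vector and event
#' times sit at one preferred phase per cycle, jittered by
#' \code{phase_jitter_sd}.
#'
#' @param regime a [synapse_regime()].
#' @param protocol a [stim_protocol()].
#' @param seed integer seed; identical (regime, protocol, seed) give an
#'   identical train.
#' @return a \code{"release_train"}: data frame with columns \code{time} (s,
#'   strictly increasing) and \code{quanta} (integer >= 1), with the protocol,
#'   regime and seed stored as attributes.
#' @export
simulate_release <- function(regime, protocol, seed) {
  stopifnot(inherits(regime, "synapse_regime"),
            inherits(protocol, "stim_protocol"))
  if (protocol_duration(protocol) <= 0) stop("protocol has zero total duration")
  set.seed(seed)
  w <- regime$mvr_weights
  kmax <- length(w)
  mu_w <- sum(seq_len(kmax) * w)
  tf <- protocol$temporal_freq
  cycle <- 1 / tf
  pref_phase <- 0.5 * cycle

  times <- numeric(0)
  sizes <- integer(0)
  for (i in seq_len(nrow(protocol$schedule))) {
    tr <- protocol$schedule[i, ]
    # spontaneous events: Poisson in vesicle rate, sizes from the MVR law
    n_sp <- stats::rpois(1, regime$spont_rate / mu_w * tr$duration)
    t_sp <- stats::runif(n_sp, 0, tr$duration)
    # evoked events, one preferred phase per cycle
    m_c <- hill_response(tr$contrast, regime$evoked_max,
                         regime$hill_c50, regime$hill_h)
    t_ev <- numeric(0)
    if (m_c > 0) {
      cyc_starts <- seq(0, tr$duration - cycle + 1e-12, by = cycle)
      n_ev <- stats::rpois(length(cyc_starts), m_c / mu_w)
      t_ev <- rep(cyc_starts, n_ev) + pref_phase +
        stats::rnorm(sum(n_ev), 0, regime$phase_jitter_sd)
      t_ev <- pmin(pmax(t_ev, 0), tr$duration - 1e-9)
    }
    t_all <- c(t_sp, t_ev)
    n_all <- length(t_all)
    s_all <- if (n_all) sample.int(kmax, n_all, replace = TRUE, prob = w)
             else integer(0)
    times <- c(times, tr$start + t_all)
    sizes <- c(sizes, s_all)
  }
  ord <- order(times)
  times <- times[ord]; sizes <- sizes[ord]
  # enforce strictly increasing times (coincident draws get an epsilon shift)
  if (length(times) > 1) {
    for (j in which(diff(times) <= 0)) times[j + 1] <- times[j] + 1e-9
  }
  structure(data.frame(time = times, quanta = as.integer(sizes)),
            class = c("release_train", "data.frame"),
            protocol = protocol, regime = regime, seed = seed)
}

#' Glutamate reporter impulse response
#'
#' The difference-of-exponentials kernel
#' \code{h(t) = A * exp(-t/tau_f) * (1 - exp(-t/tau_r))} describing an
#' iGluSnFR transient: fast rise (\code{tau_r}), slower decay (\code{tau_f}).
#' Returned sampled at \code{dt} and normalised to unit peak, so that an
#' event of amplitude a produces a transient peaking at a.
#'
#' @param dt sample interval, s.
#' @param tau_r rise time constant, s.
#' @param tau_f fall time constant, s (must exceed \code{tau_r}).
#' @param dur kernel support, s.
#' @export
iglu_kernel <- function(dt, tau_r = 0.001, tau_f = 0.06, dur = 8 * tau_f) {
  stopifnot(tau_r > 0, tau_f > tau_r, dt > 0)
  t <- seq(0, dur, by = dt)
  h <- exp(-t / tau_f) * (1 - exp(-t / tau_r))
  h / max(h)
}

#' Render a synthetic linescan from a release train
#'
#' Forward model of a 1 kHz linescan across a synaptic compartment: each
#' release event contributes \code{quanta * quantal_dff} (dF/F0) convolved
#' with the reporter kernel, multiplying the resting fluorescence of its
#' spatial component (a Gaussian along the scan line); the fluorescent signal
#' bleaches mono-exponentially and additive Gaussian recording noise is
#' applied.
#'
#' @param train a [simulate_release()] train.
#' @param components data frame with columns \code{center} (um), \code{width}
#'   (um, Gaussian sigma), \code{amplitude} (resting fluorescence); default a
#'   single component centred on the line. An optional \code{component}
#'   column on \code{train} assigns events to components (default all to the
#'   first).
#' @param regime the [synapse_regime()] supplying \code{quantal_dff},
#'   \code{noise_sd} and \code{bleach_tau} (defaults to the train's regime).
#' @param dt line period, s; must be <= 2 ms for event-resolution imaging.
#' @param n_pixels,dx scan geometry (pixels, um per pixel).
#' @param tau_r,tau_f reporter kernel time constants, s.
#' @param f_dark dark (non-fluorescent) offset, a.u.
#' @param seed integer seed for the recording noise.
#' @return a \code{"linescan"}: numeric matrix (pixels x time) with
#'   attributes \code{dt}, \code{dx}, \code{components}, \code{regime} and
#'   \code{ground_truth} (the train).
#' @export
render_linescan <- function(train, components = NULL, regime = NULL,
                            dt = 0.001, n_pixels = 32, dx = 0.25,
                            tau_r = 0.001, tau_f = 0.06,
                            f_dark = 10, seed = 1L) {
  stopifnot(inherits(train, "release_train"))
  if (dt > 0.002) stop("dt must be <= 2 ms for event-resolved linescans")
  if (is.null(regime)) regime <- attr(train, "regime")
  protocol <- attr(train, "protocol")
  total <- protocol_duration(protocol)
  if (is.null(components)) {
    components <- data.frame(center = n_pixels * dx / 2, width = 1.5,
                             amplitude = 100)
  }
  line_len <- n_pixels * dx
  if (any(components$center < 0 | components$center > line_len))
    stop("component centers outside the scan line")
  set.seed(seed)

  n_t <- ceiling(total / dt)
  tgrid <- (seq_len(n_t) - 1) * dt
  x <- (seq_len(n_pixels) - 0.5) * dx
  kern <- iglu_kernel(dt, tau_r, tau_f)
  comp_of <- if (!is.null(train$component)) train$component
             else rep(1L, nrow(train))

  bleach <- if (is.finite(regime$bleach_tau)) exp(-tgrid / regime$bleach_tau)
            else rep(1, n_t)
  img <- matrix(f_dark, n_pixels, n_t)
  for (ci in seq_len(nrow(components))) {
    imp <- numeric(n_t)
    ev <- which(comp_of == ci)
    if (length(ev)) {
      idx <- pmin(floor(train$time[ev] / dt) + 1L, n_t)
      amp <- train$quanta[ev] * regime$quantal_dff
      for (j in seq_along(ev)) imp[idx[j]] <- imp[idx[j]] + amp[j]
    }
    s <- fft_convolve(imp, kern)
    g <- exp(-(x - components$center[ci])^2 / (2 * components$width[ci]^2))
    img <- img + components$amplitude[ci] * (g %o% ((1 + s) * bleach))
  }
  if (regime$noise_sd > 0) {
    base_amp <- max(components$amplitude)
    img <- img + matrix(stats::rnorm(length(img), 0,
                                     regime$noise_sd * base_amp),
                        n_pixels, n_t)
  }
  structure(img, dt = dt, dx = dx, components = components, regime = regime,
            ground_truth = train, tau_r = tau_r, tau_f = tau_f,
            f_dark = f_dark, class = c("linescan", "matrix", "array"))
}

# linear convolution via FFT, returning the first length(x) samples
fft_convolve <- function(x, k) {
  n <- length(x) + length(k) - 1
  n2 <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, numeric(n2 - length(x))))
  kf <- stats::fft(c(k, numeric(n2 - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_along(x)] / n2
}
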