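#' Fit spatial Gaussian components to a linescan
#'
#' The time-averaged spatial profile of the linescan is fitted with a sum of
#' Gaussians on a constant offset; each Gaussian represents a point source
#' (an active zone). The number of components grows while the Bayesian
#' information criterion improves, up to \code{max_components}.
#'
#' @param recording a \code{"linescan"} matrix (pixels x time) with
#'   attributes \code{dx}.
#' @param max_components largest number of Gaussians considered.
#' @return data frame with columns \code{center}, \code{width} (um) and
#'   \code{amplitude}, sorted by center, with the fitted constant offset as
#'   attribute \code{baseline}. Zero rows if the profile is flat (peak less
#'   than 3 spatial-noise SDs above the median).
#' @export
fit_spatial_components <- function(recording, max_components = 4) {
  stopifnot(nrow(recording) >= 16)
  dx <- attr(recording, "dx")
  prof <- rowMeans(recording)
  x <- (seq_along(prof) - 0.5) * dx
  noise_sd <- stats::mad(diff(prof)) / sqrt(2)
  if (max(prof) - stats::median(prof) < 3 * max(noise_sd, 1e-12)) {
    out <- data.frame(center = numeric(0), width = numeric(0),
                      amplitude = numeric(0))
    attr(out, "baseline") <- stats::median(prof)
    return(out)
  }
  len <- max(x) + 0.5 * dx
  best <- NULL
  best_bic <- Inf
  pars <- NULL
  for (k in seq_len(max_components)) {
    pars <- init_gaussians(x, prof, pars, dx)
    fit <- try(fit_gauss_sum(x, prof, pars, dx, len), silent = TRUE)
    if (inherits(fit, "try-error")) break
    rss <- sum(stats::residuals(fit)^2)
    bic <- length(prof) * log(rss / length(prof)) +
      (1 + 3 * k) * log(length(prof))
    if (bic < best_bic - 10) {   # demand a clear margin: extra Gaussians
                                  # fitting noise are worse than useless
                                  # downstream (their traces have no baseline)
      best_bic <- bic
      best <- fit
      pars <- coef_gaussians(fit, k)
    } else break
  }
  cf <- stats::coef(best)
  k <- (length(cf) - 1) / 3
  out <- data.frame(center = cf[paste0("c", seq_len(k))],
                    width = cf[paste0("s", seq_len(k))],
                    amplitude = cf[paste0("a", seq_len(k))])
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- unname(cf["b0"])
  out
}

# greedy initialisation: add a Gaussian at the largest residual peak
init_gaussians <- function(x, prof, pars, dx) {
  if (is.null(pars)) {
    resid <- prof - min(prof)
  } else {
    resid <- prof - predict_gauss_sum(x, pars)
  }
  i <- which.max(resid)
  new <- list(center = x[i], width = max(3 * dx, diff(range(x)) / 12),
              amplitude = max(resid[i], 1e-6))
  if (is.null(pars)) list(b0 = min(prof), g = list(new))
  else { pars$g <- c(pars$g, list(new)); pars }
}

predict_gauss_sum <- function(x, pars) {
  y <- rep(pars$b0, length(x))
  for (g in pars$g)
    y <- y + g$amplitude * exp(-(x - g$center)^2 / (2 * g$width^2))
  y
}

fit_gauss_sum <- function(x, prof, pars, dx, len) {
  k <- length(pars$g)
  start <- c(b0 = pars$b0)
  lower <- c(b0 = -Inf)
  upper <- c(b0 = Inf)
  for (i in seq_len(k)) {
    g <- pars$g[[i]]
    start <- c(start, stats::setNames(c(g$amplitude, g$center, g$width),
                                      paste0(c("a", "c", "s"), i)))
    lower <- c(lower, stats::setNames(c(0, 0, dx / 2),
                                      paste0(c("a", "c", "s"), i)))
    upper <- c(upper, stats::setNames(c(Inf, len, len),
                                      paste0(c("a", "c", "s"), i)))
  }
  terms <- paste0("a", seq_len(k), " * exp(-(x - c", seq_len(k),
                  ")^2 / (2 * s", seq_len(k), "^2))", collapse = " + ")
  form <- stats::as.formula(paste("prof ~ b0 +", terms))
  minpack.lm::nlsLM(form, data = data.frame(x = x, prof = prof),
                    start = as.list(start), lower = lower, upper = upper,
                    control = minpack.lm::nls.lm.control(maxiter = 200))
}

coef_gaussians <- function(fit, k) {
  cf <- stats::coef(fit)
  list(b0 = unname(cf["b0"]),
       g = lapply(seq_len(k), function(i)
         list(amplitude = unname(cf[paste0("a", i)]),
              center = unname(cf[paste0("c", i)]),
              width = unname(cf[paste0("s", i)]))))
}

#' Extract per-component time series by spatial unmixing
#'
#' At each time point the linescan is fitted with a weighted sum of the fixed
#' spatial Gaussian components (plus a constant offset absorbing dark
#' fluorescence); the weight series of each component is its fluorescence
#' trace. Nearly coincident components (centres closer than half the smaller
#' width) are merged with a warning, since their weights are not separable.
#'
#' @param recording a \code{"linescan"} matrix.
#' @param components data frame from [fit_spatial_components()].
#' @return numeric matrix (components x time) with attributes \code{dt} and
#'   \code{components} (possibly merged).
#' @export
extract_timeseries <- function(recording, components) {
  stopifnot(nrow(components) >= 1)
  dx <- attr(recording, "dx")
  x <- (seq_len(nrow(recording)) - 0.5) * dx
  components <- merge_close_components(components)
  G <- cbind(1, vapply(seq_len(nrow(components)), function(i)
    exp(-(x - components$center[i])^2 / (2 * components$width[i]^2)),
    numeric(length(x))))
  W <- solve(crossprod(G), crossprod(G, unclass(recording)))
  traces <- W[-1, , drop = FALSE]
  structure(traces, dt = attr(recording, "dt"), components = components)
}

merge_close_components <- function(components) {
  repeat {
    if (nrow(components) < 2) return(components)
    d <- as.matrix(stats::dist(components$center))
    diag(d) <- Inf
    lim <- outer(components$width, components$width, pmin) / 2
    if (!any(d < lim)) return(components)
    ij <- which(d < lim, arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    wsum <- components$amplitude[i] + components$amplitude[j]
    components$center[i] <- sum(components$center[c(i, j)] *
                                components$amplitude[c(i, j)]) / wsum
    components$width[i] <- max(components$width[c(i, j)])
    components$amplitude[i] <- wsum
    components <- components[-j, , drop = FALSE]
    warning("nearly coincident spatial components merged")
  }
}

#' Relative fluorescence change dF/F0
#'
#' Optionally detrends mono-exponential bleaching (fitted robustly to
#' per-segment low quantiles of the trace, so release transients do not bias
#' the fit), then takes the baseline F0 as the most frequent value of the
#' trace, estimated from a Freedman-Diaconis histogram with parabolic
#' refinement of the peak bin, and returns (F - F0)/F0.
#'
#' @param trace numeric fluorescence trace (>= 100 samples).
#' @param dt sample interval, s.
#' @param bleach_correction detrend bleaching before estimating F0.
#' @return dF/F0 trace with attributes \code{F0}, \code{dt} and (when
#'   correction ran) \code{bleach_tau}.
#' @export
compute_dff <- function(trace, dt, bleach_correction = TRUE) {
  trace <- as.numeric(trace)
  stopifnot(length(trace) >= 100, dt > 0)
  tau <- NA_real_
  t <- (seq_along(trace) - 1) * dt
  if (bleach_correction) {
    fit <- try(fit_bleach(trace, t), silent = TRUE)
    # only correct a real decay: amplitude at least 2% of the offset
    if (!inherits(fit, "try-error") && is.finite(fit["tau"]) &&
        fit["tau"] > 0 && fit["a"] > 0.02 * abs(fit["c"])) {
      tau <- unname(fit["tau"])
      trace <- (trace - fit["c"]) / exp(-t / tau) + fit["c"]
    }
  }
  f0 <- trace_mode(trace)
  if (f0 <= 0) stop("estimated baseline F0 is non-positive")
  structure((trace - f0) / f0, F0 = f0, dt = dt, bleach_tau = tau)
}

# robust mono-exponential fit to the trace's lower envelope
# (per-segment 5% quantiles follow the bleaching baseline even when release
# transients occupy most of the recording)
fit_bleach <- function(trace, t) {
  nseg <- max(10L, min(60L, floor(length(trace) / 1000)))
  idx <- split(seq_along(trace), cut(seq_along(trace), nseg, labels = FALSE))
  tb <- vapply(idx, function(i) mean(t[i]), 0)
  qb <- vapply(idx, function(i) stats::quantile(trace[i], 0.05, names = FALSE), 0)
  a0 <- max(unname(qb[1] - qb[length(qb)]), 1e-6)
  # tau is bounded below by half the recording: bleaching is a slow trend;
  # faster apparent decays are stimulus structure, not bleaching
  fit <- minpack.lm::nlsLM(qb ~ a * exp(-tb / tau) + c,
                           start = list(a = a0, tau = unname(max(t)),
                                        c = unname(qb[length(qb)])),
                           lower = c(a = 0, tau = max(t) / 2, c = -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 100))
  cf <- stats::coef(fit)
  # reject fits losing almost the whole initial fluorescence over the
  # recording: that is signal structure, not bleaching
  loss <- cf["a"] * (1 - exp(-max(t) / cf["tau"]))
  if (loss > 0.9 * abs(cf["a"] + cf["c"])) stop("implausible bleach fit")
  # a genuine bleaching trend dominates the envelope's sampling noise: only
  # correct when the exponential explains most of the envelope variance,
  # otherwise the "trend" is event-occupancy noise and correction would
  # distort the trace far more than the (negligible) bleach it removes
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((qb - mean(qb))^2)
  if (rss1 > 0.4 * rss0) stop("no significant bleach trend")
  cf
}

# mode of a trace: Freedman-Diaconis histogram, parabolic peak refinement
trace_mode <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr <= 0) return(stats::median(x))
  bw <- 2 * iqr / length(x)^(1 / 3)
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  i <- which.max(h$counts)
  if (i == 1 || i == length(h$counts)) return(h$mids[i])
  y0 <- h$counts[i - 1]; y1 <- h$counts[i]; y2 <- h$counts[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
  h$mids[i] + delta * bw
}

#' Wiener deconvolution of a dF/F0 trace
#'
#' Applies the frequency-domain Wiener inverse of the reporter kernel, so
#' that release transients become approximate impulses whose heights are the
#' event amplitudes (dF/F0 per event). The output is calibrated on the
#' filter's own response to a unit kernel-shaped transient: a unit transient
#' yields a unit-height impulse at the transient onset.
#'
#' If \code{snr} is not given, the noise power is estimated from the trace's
#' spectrum above \code{noise_freq} Hz, and the prior signal power from the
#' kernel spectrum scaled to the remaining trace power.
#'
#' @param dff dF/F0 trace (from [compute_dff()]).
#' @param dt sample interval, s (taken from the trace attribute if absent).
#' @param tau_r,tau_f kernel time constants, s.
#' @param snr optional signal-to-noise override; \code{Inf} gives the pure
#'   inverse filter.
#' @param noise_freq frequency above which the trace spectrum is treated as
#'   noise, Hz.
#' @return impulse trace with attributes \code{dt}, \code{unit_area} (sum of
#'   the calibrated unit-event response, used for area-based amplitudes) and
#'   \code{snr_lambda} (the regularisation actually applied).
#' @export
wiener_deconvolve <- function(dff, dt = attr(dff, "dt"),
                              tau_r = 0.001, tau_f = 0.06,
                              snr = NULL, noise_freq = 100) {
  stopifnot(!is.null(dt), dt > 0)
  if (!is.null(snr) && snr <= 0) stop("snr must be positive")
  kern <- iglu_kernel(dt, tau_r, tau_f)
  n <- length(dff)
  if (n < length(kern)) stop("trace shorter than the kernel support")
  n2 <- stats::nextn(n + length(kern), 2)
  K <- stats::fft(c(kern, numeric(n2 - length(kern))))
  Y <- stats::fft(c(dff - stats::median(dff), numeric(n2 - n)))
  K2 <- Mod(K)^2
  if (is.null(snr)) {
    f <- seq(0, n2 - 1) / (n2 * dt)
    f <- pmin(f, 1 / dt - f)                    # folded frequency axis
    hi <- f > noise_freq
    if (!any(hi)) stop("trace too short to estimate the noise spectrum")
    n0 <- mean(Mod(Y[hi])^2)
    sig <- max(mean(Mod(Y)^2) - n0, n0 * 1e-3)
    lambda <- n0 / (sig / mean(K2))
  } else if (is.infinite(snr)) {
    lambda <- 0
  } else {
    lambda <- max(K2) / snr^2
  }
  G <- Conj(K) / pmax(K2 + lambda, 1e-300)
  x <- Re(stats::fft(G * Y, inverse = TRUE))[seq_len(n)] / n2
  # unit-event response over lags -L..L (the regularised filter is acausal:
  # its pre-onset lobe wraps to the end of the FFT buffer)
  ufull <- Re(stats::fft(G * K, inverse = TRUE)) / n2
  L <- length(kern)
  unit <- c(ufull[(n2 - L + 1):n2], ufull[seq_len(L + 1)])
  peak <- max(unit)
  structure(x / peak, dt = dt, unit_response = unit / peak,
            unit_peak_idx = which.max(unit), snr_lambda = lambda)
}

#' Detect release events in a deconvolved impulse trace
#'
#' The baseline SD is estimated robustly (median absolute deviation, which is
#' insensitive to the sparse impulses); samples more than \code{k_sd} SDs
#' above the baseline are grouped into events, and supra-threshold runs
#' separated by less than \code{merge_gap} are merged into one event.
#'
#' Each event reports its peak time and height, and an area-based
#' \code{amplitude}: the integral of the deconvolved trace over the event
#' extent divided by the integral of a calibrated unit-event response.
#' Deconvolution is linear, so the area of a merged run equals the summed
#' amplitudes of its constituent events even when stimulus-locked events
#' partially overlap; downstream quantal clustering therefore uses the area.
#'
#' @param impulse deconvolved trace from [wiener_deconvolve()].
#' @param k_sd detection threshold in baseline SDs (2-6; default 3.5).
#' @param dt sample interval, s.
#' @param merge_gap runs closer than this are one event, s.
#' @return \code{"event_series"} data frame with columns \code{time},
#'   \code{amplitude} (area-based) and \code{peak}; attributes
#'   \code{threshold}, \code{sigma}, \code{k_sd}, \code{duration}.
#' @export
detect_events <- function(impulse, k_sd = 3.5, dt = attr(impulse, "dt"),
                          merge_gap = 0.005) {
  stopifnot(k_sd >= 2, k_sd <= 6, !is.null(dt))
  x <- as.numeric(impulse)
  center <- stats::median(x)
  # MAD is robust to the sparse impulses; the floor keeps noise-free traces
  # (numerically zero baseline) from yielding junk detections
  sigma <- max(stats::mad(x), 4e-3 * max(abs(x - center)), 1e-12)
  thr <- center + k_sd * sigma
  above <- x > thr
  empty <- structure(data.frame(time = numeric(0), amplitude = numeric(0),
                                peak = numeric(0)),
                     class = c("event_series", "data.frame"),
                     threshold = thr, sigma = sigma, k_sd = k_sd,
                     duration = length(x) * dt)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  gap <- max(1L, round(merge_gap / dt))
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    last <- merged[[length(merged)]]
    if (runs[i, 1] - last[2] <= gap) merged[[length(merged)]][2] <- runs[i, 2]
    else merged[[length(merged) + 1]] <- runs[i, ]
  }
  unit <- attr(impulse, "unit_response")
  upk <- attr(impulse, "unit_peak_idx")
  pad <- gap
  out <- do.call(rbind, lapply(merged, function(rg) {
    i0 <- rg[1]; i1 <- rg[2]
    ipk <- i0 + which.max(x[i0:i1]) - 1L
    e0 <- max(1L, i0 - pad); e1 <- min(length(x), i1 + pad)
    area <- sum(x[e0:e1] - center)
    amp <- x[ipk] - center
    if (!is.null(unit)) {
      # normalise by the unit response integrated over the same window
      # (relative to its peak), so event and calibration areas match
      uidx <- upk + ((e0:e1) - ipk)
      uidx <- uidx[uidx >= 1 & uidx <= length(unit)]
      ua <- sum(unit[uidx])
      if (is.finite(ua) && ua > 0.1) amp <- area / ua
    }
    data.frame(time = (ipk - 1) * dt, amplitude = amp, peak = x[ipk] - center)
  }))
  # shape consistency: a genuine transient has area ~ peak (both calibrated
  # on the unit response); single-sample noise spikes clear the threshold
  # with almost no area and are rejected
  bad <- out$amplitude < 0.5 * out$peak
  n_rejected <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("event_series", "data.frame"),
            threshold = thr, sigma = sigma, k_sd = k_sd,
            n_rejected = n_rejected, duration = length(x) * dt)
}

#' Partition event amplitudes into numbers of quanta
#'
#' Fits, by maximum likelihood, a Gaussian mixture whose component means are
#' integer multiples \code{k * q} of a unitary amplitude \code{q}
#' (k = 1..kmax) with a shared relative width (SD = cv * k * q), then assigns
#' each event the \code{k} of highest posterior probability. Events larger
#' than \code{kmax} quanta are clipped to \code{kmax}.
#'
#' @param events an [detect_events()] series (>= 20 events unless
#'   \code{quantal_size} is supplied).
#' @param kmax largest number of quanta per event.
#' @param quantal_size optional known unitary amplitude; mandatory below 20
#'   events, where the mixture is not identifiable.
#' @param restarts random-restart count for the likelihood optimisation.
#' @param seed seed for the restarts.
#' @return \code{"quantal_series"} data frame with columns \code{time},
#'   \code{quanta}; attributes \code{quantal_size}, \code{cv},
#'   \code{weights}, \code{logLik}, \code{duration}.
#' @export
cluster_quanta <- function(events, kmax = 5, quantal_size = NULL,
                           restarts = 10, seed = 1L) {
  a <- events$amplitude
  # marginal detections can integrate to <= 0; floor them at the smallest
  # positive amplitude so the scale-family mixture stays defined
  if (any(a <= 0)) {
    floor_a <- if (any(a > 0)) min(a[a > 0]) else 1e-6
    a <- pmax(a, floor_a)
  }
  if (length(a) < 20 && is.null(quantal_size))
    stop("fewer than 20 events: supply quantal_size")
  if (is.null(quantal_size)) {
    # the unitary amplitude is identified by the mixture over 1..kmax; very
    # large amplitudes (chains of merged events) would distort that scale,
    # so the mixture is fitted to amplitudes within its own range and larger
    # events are assigned as extrapolated integer multiples of q
    fit <- fit_quantal_mixture(a[a <= (kmax + 0.5) * stats::median(a)],
                               kmax, restarts, seed)
    in_range <- a <= (kmax + 0.5) * fit$q
    if (sum(in_range) >= 20) {
      fit <- fit_quantal_mixture(a[in_range], kmax, restarts, seed)
      in_range <- a <= (kmax + 0.5) * fit$q
    }
    q <- fit$q
    k <- pmax(1L, as.integer(round(a / q)))
    post <- quantal_posteriors(a[in_range], q, fit$cv, fit$weights)
    k[in_range] <- max.col(post)
    attrs <- list(quantal_size = q, cv = fit$cv, weights = fit$weights,
                  logLik = fit$logLik, n_beyond_kmax = sum(!in_range))
  } else {
    q <- quantal_size
    k <- pmax(1L, as.integer(round(a / q)))
    attrs <- list(quantal_size = q, cv = NA_real_, weights = NULL,
                  logLik = NA_real_, n_beyond_kmax = sum(k > kmax))
  }
  out <- structure(data.frame(time = events$time, quanta = as.integer(k)),
                   class = c("quantal_series", "data.frame"),
                   duration = attr(events, "duration"))
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  out
}

quantal_posteriors <- function(a, q, cv, w) {
  kmax <- length(w)
  d <- vapply(seq_len(kmax), function(k)
    w[k] * stats::dnorm(a, k * q, cv * k * q), numeric(length(a)))
  d / pmax(rowSums(d), 1e-300)
}

fit_quantal_mixture <- function(a, kmax, restarts, seed) {
  # q must be commensurate with the amplitude bulk: below q_lo the mixture
  # is absorbing spread rather than quantisation, above q_hi the smallest
  # events would be sub-quantal
  q_lo <- stats::quantile(a, 0.05, names = FALSE) / 2
  q_hi <- 2 * stats::median(a)
  negll <- function(par) {
    q <- exp(par[1]); cv <- exp(par[2])
    if (cv > 0.4 || cv < 0.02 || q < q_lo || q > q_hi) return(1e10)
    w <- exp(c(0, par[-(1:2)]))
    w <- w / sum(w)
    d <- rowSums(vapply(seq_len(kmax), function(k)
      w[k] * stats::dnorm(a, k * q, cv * k * q), numeric(length(a))))
    -sum(log(pmax(d, 1e-300)))
  }
  q_starts <- unique(c(stats::median(a) / seq_len(kmax),
                       stats::quantile(a, 0.15, names = FALSE)))
  q_starts <- q_starts[q_starts > 0]
  fits <- list()
  withr_seed(seed, {
    trials <- c(q_starts,
                exp(stats::runif(max(0, restarts - length(q_starts)),
                                 log(min(a) / 2), log(stats::median(a)))))
    for (q0 in trials) {
      par0 <- c(log(q0), log(0.12), rep(0, kmax - 1))
      opt <- try(stats::optim(par0, negll, method = "BFGS",
                              control = list(maxit = 500)), silent = TRUE)
      if (inherits(opt, "try-error") || !is.finite(opt$value) ||
          opt$value >= 1e10) next
      fits[[length(fits) + 1]] <- opt
    }
  })
  if (!length(fits))
    stop("quantal mixture did not converge after restarts (n = ",
         length(a), " events)")
  # a population of k-quantum events is equally well described with q/m and
  # quanta m*k; among likelihood ties prefer the largest unitary size
  vals <- vapply(fits, `[[`, 0, "value")
  near <- which(vals <= min(vals) + 0.5)
  best <- fits[[near[which.max(vapply(fits[near],
                                      function(f) f$par[1], 0))]]]
  w <- exp(c(0, best$par[-(1:2)]))
  list(q = exp(best$par[1]), cv = exp(best$par[2]), weights = w / sum(w),
       logLik = -best$value)
}

#' Vesicle release rate
#'
#' Total quanta in a time window divided by its duration.
#'
#' @param series a \code{"quantal_series"} (or any data frame with
#'   \code{time} and \code{quanta}).
#' @param window \code{c(start, end)} in seconds; defaults to the full
#'   recording when the series carries a \code{duration} attribute.
#' @return vesicles per second.
#' @export
release_rate <- function(series, window = NULL) {
  if (is.null(window)) {
    dur <- attr(series, "duration")
    if (is.null(dur)) stop("supply a window or a series with a duration")
    window <- c(0, dur)
  }
  stopifnot(length(window) == 2, diff(window) > 0)
  inw <- series$time >= window[1] & series$time < window[2]
  sum(series$quanta[inw]) / diff(window)
}

#' Full quantal decomposition of a linescan
#'
#' Runs the six-step sequence: spatial component fitting, time-series
#' extraction, dF/F0 with bleach correction, Wiener deconvolution, event
#' detection and quantal clustering. Returns one quantal series per spatial
#' component.
#'
#' @param recording a \code{"linescan"}.
#' @param k_sd detection threshold, baseline SDs.
#' @param kmax largest event size for quantal clustering.
#' @param snr optional Wiener SNR override.
#' @param quantal_size optional known unitary amplitude (used when few
#'   events are detected).
#' @param max_components cap on the number of spatial Gaussians.
#' @param bleach_correction passed to [compute_dff()].
#' @return list of \code{"quantal_series"}, one per component, with the
#'   fitted components attached as attribute \code{components}.
#' @export
quantal_decompose <- function(recording, k_sd = 3.5, kmax = 5, snr = NULL,
                              quantal_size = NULL, max_components = 4,
                              bleach_correction = TRUE) {
  comps <- fit_spatial_components(recording, max_components)
  if (nrow(comps) == 0) return(structure(list(), components = comps))
  traces <- extract_timeseries(recording, comps)
  dt <- attr(recording, "dt")
  res <- lapply(seq_len(nrow(attr(traces, "components"))), function(i) {
    dff <- try(compute_dff(traces[i, ], dt, bleach_correction), silent = TRUE)
    if (inherits(dff, "try-error")) {
      warning("component ", i, " has no physical baseline; skipped")
      return(NULL)
    }
    imp <- wiener_deconvolve(dff, dt,
                             tau_r = attr(recording, "tau_r") %||% 0.001,
                             tau_f = attr(recording, "tau_f") %||% 0.06,
                             snr = snr)
    ev <- detect_events(imp, k_sd = k_sd, dt = dt)
    if (nrow(ev) == 0) {
      return(structure(data.frame(time = numeric(0), quanta = integer(0)),
                       class = c("quantal_series", "data.frame"),
                       quantal_size = NA_real_,
                       duration = attr(ev, "duration")))
    }
    # below ~50 events the quantal mixture is not reliably identifiable;
    # use the amplitude density mode as the unitary size instead (sparse
    # spontaneous activity is dominated by single-quantum events)
    qs <- if (nrow(ev) < 50 && is.null(quantal_size))
      cluster_quanta(ev, kmax, quantal_size = amplitude_mode(ev$amplitude))
    else cluster_quanta(ev, kmax, quantal_size = quantal_size)
    qs
  })
  keep <- !vapply(res, is.null, logical(1))
  structure(res[keep],
            components = attr(traces, "components")[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mode of an amplitude sample by kernel density (unitary event size when
# single-quantum events dominate)
amplitude_mode <- function(a) {
  a <- a[a > 0]
  if (length(a) < 3) return(stats::median(a))
  d <- stats::density(a)
  d$x[which.max(d$y)]
}
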