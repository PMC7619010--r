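#' Fit a Hill function to a contrast-response function
#'
#' Nonlinear least squares of \code{R = Rmax * S^h / (S^h + C50^h)} with
#' bounds h in (0.1, 10], C50 in (1, 200]; initialisation from the half-max
#' crossing. When the CRF carries SEMs the fit is weighted by 1/SEM^2.
#'
#' @param crf data frame with columns \code{contrast}, \code{response} and
#'   optionally \code{sem} (a [build_behavior_crf()] result qualifies).
#' @return a \code{"hill_fit"} list: \code{rmax}, \code{h}, \code{c50},
#'   \code{vcov}, \code{fitted}, and \code{extrapolated} (TRUE when C50
#'   falls outside the sampled contrast range).
#' @export
fit_hill <- function(crf) {
  stopifnot(nrow(crf) >= 4)
  s <- crf$contrast
  r <- crf$response
  wts <- if (!is.null(crf$sem) && all(is.finite(crf$sem)) &&
             all(crf$sem > 0)) 1 / crf$sem^2 else rep(1, length(r))
  rmax0 <- max(r)
  half <- rmax0 / 2
  above <- which(r >= half)
  c50_0 <- if (length(above) && min(above) > 1) {
    i <- min(above)
    stats::approx(r[(i - 1):i], s[(i - 1):i], xout = half)$y
  } else stats::median(s)
  if (!is.finite(c50_0)) c50_0 <- stats::median(s)
  fit <- minpack.lm::nlsLM(
    response ~ rmax * contrast^h / (contrast^h + c50^h),
    data = data.frame(contrast = s, response = r),
    start = list(rmax = rmax0, h = 2, c50 = c50_0),
    lower = c(rmax = 0, h = 0.1, c50 = 1),
    upper = c(rmax = Inf, h = 10, c50 = 200),
    weights = wts,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(rmax = unname(cf["rmax"]), h = unname(cf["h"]),
                 c50 = unname(cf["c50"]),
                 vcov = tryCatch(stats::vcov(fit),
                                 error = function(e) NULL),
                 fitted = stats::fitted(fit),
                 extrapolated = cf["c50"] < min(s) || cf["c50"] > max(s)),
            class = "hill_fit")
}

#' Maximum contrast gain from an 11-point window
#'
#' Ordinary least-squares slope of response against contrast over 11
#' contrasts evenly spaced across a 20-percent window (the maximum contrast
#' gain, response units per percent contrast).
#'
#' @param contrasts 11 evenly spaced contrast values spanning 20 percent.
#' @param responses responses at those contrasts.
#' @return a \code{"gain_fit"} list: \code{mcg} (slope), \code{intercept},
#'   \code{window}.
#' @export
measure_mcg <- function(contrasts, responses) {
  stopifnot(length(contrasts) == 11, length(responses) == 11)
  d <- diff(sort(contrasts))
  if (max(abs(d - d[1])) > 1e-6 ||
      abs(diff(range(contrasts)) - 20) > 1e-6)
    stop("MCG needs 11 evenly spaced contrasts spanning a 20% window")
  fit <- stats::lm(responses ~ contrasts)
  structure(list(mcg = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 window = range(contrasts)),
            class = "gain_fit")
}

#' Gain window from a coarse contrast-response function
#'
#' For synapses, whose contrast sensitivity varies widely, the half-maximal
#' contrast is first estimated coarsely (11 points over 0-100 percent) and
#' the fine gain window is then placed at +/- 10 percent around it, clamped
#' inside 0-100 while keeping its 20-percent width.
#'
#' @param coarse_crf data frame (\code{contrast}, \code{response}) sampled
#'   over the full contrast range.
#' @return list with \code{window} (lo, hi), the coarse \code{c50} and the
#'   11 fine contrasts.
#' @export
mcg_window_from_coarse <- function(coarse_crf) {
  fit <- fit_hill(coarse_crf)
  lo <- max(0, min(fit$c50 - 10, 80))
  window <- c(lo, lo + 20)
  list(window = window, c50 = fit$c50,
       contrasts = seq(window[1], window[2], length.out = 11))
}

#' Fit a power law to efficiency versus release rate
#'
#' Least squares of log E against log R: \code{E = a * R^b}.
#'
#' @param efficiency bits per vesicle, one value per synapse (> 0).
#' @param rate vesicles per second, one per synapse (> 0).
#' @return a \code{"power_fit"} list: \code{a} (prefactor), \code{b}
#'   (exponent), \code{n}, \code{r_squared}, \code{domain} (range of R).
#' @export
fit_power_law <- function(efficiency, rate) {
  stopifnot(length(efficiency) == length(rate), length(rate) >= 5,
            all(efficiency > 0), all(rate > 0))
  fit <- stats::lm(log(efficiency) ~ log(rate))
  structure(list(a = exp(unname(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 n = length(rate),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 domain = range(rate)),
            class = "power_fit")
}

#' Pool synapses into efficiency-rate group averages
#'
#' Synapses are sorted by release rate and grouped into consecutive blocks
#' of \code{group_size} (4-8); each block contributes its mean rate and mean
#' efficiency. A short leftover block is merged into the last full one.
#'
#' @param rate vesicles per second per synapse.
#' @param efficiency bits per vesicle per synapse.
#' @param group_size synapses per pooled point (4 to 8).
#' @return data frame with columns \code{rate}, \code{efficiency} and
#'   \code{n} per pooled point.
#' @export
pool_efficiency <- function(rate, efficiency, group_size = 6) {
  stopifnot(group_size >= 4, group_size <= 8,
            length(rate) == length(efficiency))
  ord <- order(rate)
  rate <- rate[ord]; efficiency <- efficiency[ord]
  n <- length(rate)
  grp <- ceiling(seq_len(n) / group_size)
  # a trailing fragment would under-represent its block: merge it
  if (sum(grp == max(grp)) < group_size && max(grp) > 1)
    grp[grp == max(grp)] <- max(grp) - 1
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(i)
    data.frame(rate = mean(rate[i]), efficiency = mean(efficiency[i]),
               n = length(i))))
  rownames(out) <- NULL
  out
}

#' Ratio of two fitted efficiency power laws over a rate range
#'
#' @param fit_num,fit_den \code{"power_fit"} objects (numerator and
#'   denominator laws).
#' @param rates release-rate grid, vesicles per second.
#' @return data frame with \code{rate} and \code{ratio}.
#' @export
efficiency_ratio_curve <- function(fit_num, fit_den,
                                   rates = exp(seq(log(1), log(20),
                                                   length.out = 50))) {
  data.frame(rate = rates,
             ratio = (fit_num$a * rates^fit_num$b) /
                     (fit_den$a * rates^fit_den$b))
}

#' Correlate a neural metric with behavioral gain across conditions
#'
#' Pearson correlation on the values and Spearman on the ranks, with
#' two-sided p-values (exact permutation distribution for the Spearman at
#' small n, as implemented by \code{cor.test}). Behavioral gains are
#' normalised to a reference condition when given.
#'
#' @param neural numeric vector, e.g. mean information rate per condition.
#' @param behavioral numeric vector, e.g. behavioral MCG per condition.
#' @param normalize_to optional index or name of the reference condition.
#' @return a \code{"correlation_result"} list: \code{pearson_r},
#'   \code{pearson_p}, \code{spearman_rho}, \code{spearman_p}, \code{n},
#'   \code{behavioral_relative}.
#' @export
correlate_levels <- function(neural, behavioral, normalize_to = NULL) {
  stopifnot(length(neural) == length(behavioral), length(neural) >= 3)
  rel <- behavioral
  if (!is.null(normalize_to)) rel <- behavioral / behavioral[[normalize_to]]
  pe <- stats::cor.test(neural, rel, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(neural, rel, method = "spearman"))
  structure(list(pearson_r = unname(pe$estimate),
                 pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 n = length(neural),
                 behavioral_relative = rel),
            class = "correlation_result")
}

#' Sample a noisy behavioral contrast-response cohort from a Hill curve
#'
#' Draws per-fish CRFs as the Hill curve plus i.i.d. Gaussian noise at each
#' contrast, then averages across fish: the standard construction for
#' benchmarking CRF fitting at a known ground truth.
#'
#' @param contrasts contrast levels, percent.
#' @param rmax,c50,h Hill parameters of the generating curve.
#' @param n_fish fish per cohort.
#' @param noise_sd per-fish response noise SD (response units).
#' @param seed integer seed.
#' @return a \code{"crf"} data frame (\code{contrast}, \code{response},
#'   \code{sem}, \code{n}).
#' @export
simulate_crf_cohort <- function(contrasts, rmax, c50, h, n_fish,
                                noise_sd, seed) {
  set.seed(seed)
  true <- hill_response(contrasts, rmax, c50, h)
  per_fish <- replicate(n_fish, true + stats::rnorm(length(true), 0,
                                                    noise_sd))
  structure(data.frame(contrast = contrasts,
                       response = rowMeans(per_fish),
                       sem = apply(per_fish, 1, stats::sd) / sqrt(n_fish),
                       n = n_fish),
            class = c("crf", "data.frame"))
}
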