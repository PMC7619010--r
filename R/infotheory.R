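#' Bin a quantal series against a stimulus protocol
#'
#' Converts the event time series into quanta-per-bin counts, each bin
#' labeled with its trial's contrast. The default 20 ms bin is short enough
#' that a bin almost always contains zero events or one event of integer
#' amplitude; when two events do fall in one bin their quanta are summed and
#' a warning is issued.
#'
#' @param series a \code{"quantal_series"} (columns \code{time},
#'   \code{quanta}).
#' @param protocol the [stim_protocol()] the recording was made under.
#' @param bin_width bin width in seconds (default 0.020).
#' @return a \code{"binned_response"} data frame with columns \code{trial},
#'   \code{contrast}, \code{bin} and \code{count}.
#' @export
bin_quanta <- function(series, protocol, bin_width = 0.020) {
  stopifnot(bin_width > 0)
  sched <- protocol$schedule[order(protocol$schedule$start), ]
  nb <- floor(sched$duration / bin_width + 1e-9)
  offset <- cumsum(c(0, nb[-length(nb)]))
  total <- sum(nb)
  counts <- integer(total)
  ev_n <- integer(total)
  if (nrow(series)) {
    tr_i <- findInterval(series$time, sched$start)
    rel <- series$time - sched$start[tr_i]
    b <- floor(rel / bin_width) + 1L
    keep <- b >= 1 & b <= nb[tr_i]
    gid <- offset[tr_i[keep]] + b[keep]
    if (length(gid)) {
      agg <- rowsum(cbind(series$quanta[keep], 1L), gid)
      ids <- as.integer(rownames(agg))
      counts[ids] <- agg[, 1]
      ev_n[ids] <- agg[, 2]
    }
  }
  multi <- sum(ev_n > 1)
  if (multi > 0)
    warning(multi, " bin(s) contained more than one event; quanta summed")
  res <- data.frame(trial = rep(sched$trial, nb),
                    contrast = rep(sched$contrast, nb),
                    bin = sequence(nb), count = counts)
  structure(res, class = c("binned_response", "data.frame"),
            bin_width = bin_width, n_multi = multi)
}

#' Joint distribution of stimulus contrast and quanta per bin
#'
#' Estimates p(Q|S) by counting bins containing 0, 1, 2, ... quanta for each
#' stimulus, then forms the joint p(S,Q) = p(Q|S) p(S) with the experimental
#' stimulus prior (uniform by default). Counts above \code{kmax} are clipped
#' into the top symbol.
#'
#' @param binned a [bin_quanta()] result.
#' @param prior optional named numeric vector of stimulus probabilities;
#'   default uniform over the stimuli present.
#' @param kmax largest quanta symbol (alphabet 0..kmax).
#' @return a \code{"joint_distribution"}: list with the joint table
#'   \code{p_sq} (stimuli x symbols), \code{p_s}, \code{p_q} and the
#'   conditional \code{p_q_given_s}.
#' @export
estimate_joint <- function(binned, prior = NULL, kmax = 5) {
  stim <- sort(unique(binned$contrast))
  counts <- pmin(binned$count, kmax)
  n_clip <- sum(binned$count > kmax)
  if (n_clip > 0)
    warning(n_clip, " bin count(s) above kmax clipped to ", kmax)
  tab <- table(factor(binned$contrast, levels = stim),
               factor(counts, levels = 0:kmax))
  if (any(rowSums(tab) == 0)) stop("every stimulus needs at least one bin")
  p_q_given_s <- sweep(unclass(tab), 1, rowSums(tab), "/")
  if (is.null(prior)) {
    p_s <- stats::setNames(rep(1 / length(stim), length(stim)),
                           rownames(p_q_given_s))
  } else {
    stopifnot(length(prior) == length(stim), all(prior >= 0))
    p_s <- prior / sum(prior)
  }
  p_sq <- p_q_given_s * as.numeric(p_s)
  structure(list(p_sq = p_sq, p_s = as.numeric(p_s),
                 p_q = colSums(p_sq), p_q_given_s = p_q_given_s,
                 stimuli = stim, symbols = 0:kmax),
            class = "joint_distribution")
}

#' Construct a joint distribution from an explicit table
#'
#' For analyses starting from a known channel rather than binned data.
#'
#' @param p_sq matrix of joint probabilities, stimuli in rows and response
#'   symbols in columns; must sum to 1.
#' @export
joint_from_table <- function(p_sq) {
  stopifnot(all(p_sq >= 0), abs(sum(p_sq) - 1) < 1e-8)
  p_s <- rowSums(p_sq)
  structure(list(p_sq = p_sq, p_s = p_s, p_q = colSums(p_sq),
                 p_q_given_s = sweep(p_sq, 1, pmax(p_s, 1e-300), "/"),
                 stimuli = rownames(p_sq) %||% seq_len(nrow(p_sq)),
                 symbols = colnames(p_sq) %||% seq_len(ncol(p_sq))),
            class = "joint_distribution")
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between stimulus and quantal output
#'
#' Plug-in estimate I(S;Q) = H(S) - H(S|Q), in bits, from a joint
#' distribution table; 0 log 0 is taken as 0.
#'
#' @param joint a \code{"joint_distribution"}.
#' @return list with \code{I} (bits per bin), \code{H_S}, \code{H_S_given_Q}
#'   and \code{H_Q}.
#' @export
mutual_information <- function(joint) {
  p_sq <- joint$p_sq
  p_q <- colSums(p_sq)
  h_s <- entropy_bits(rowSums(p_sq))
  h_q <- entropy_bits(p_q)
  # H(S|Q) = -sum_q p(q) sum_s p(s|q) log2 p(s|q)
  h_s_given_q <- 0
  for (j in seq_along(p_q)) {
    if (p_q[j] <= 0) next
    p_s_given_q <- p_sq[, j] / p_q[j]
    h_s_given_q <- h_s_given_q + p_q[j] * entropy_bits(p_s_given_q)
  }
  list(I = h_s - h_s_given_q, H_S = h_s, H_S_given_Q = h_s_given_q,
       H_Q = h_q)
}

#' Information rate and efficiency
#'
#' Converts bits per bin into bits per second, and divides by the vesicle
#' release rate to obtain the information carried per vesicle.
#'
#' @param info_bits_per_bin mutual information, bits per bin.
#' @param bin_width bin width, s.
#' @param release_rate vesicles per second.
#' @return list with \code{bits_per_s} and \code{bits_per_vesicle}
#'   (\code{NA} with a warning when the release rate is zero).
#' @export
info_rate_and_efficiency <- function(info_bits_per_bin, bin_width,
                                     release_rate) {
  stopifnot(bin_width > 0, release_rate >= 0)
  rate <- info_bits_per_bin / bin_width
  eff <- if (release_rate > 0) rate / release_rate else {
    warning("zero release rate: efficiency undefined")
    NA_real_
  }
  list(bits_per_s = rate, bits_per_vesicle = eff)
}

#' Fano factor of vesicle counts per stimulus cycle
#'
#' Counts quanta in each stimulus cycle (1/temporal frequency) and returns,
#' per contrast, the ratio of the sample variance (n - 1 denominator) to the
#' mean of the counts, plus the average over a contrast window when given.
#'
#' @param series a \code{"quantal_series"}.
#' @param protocol the recording's [stim_protocol()].
#' @param window optional \code{c(lo, hi)} contrast range over which to
#'   average (e.g. the 20-percent gain window).
#' @return data frame with columns \code{contrast}, \code{mean},
#'   \code{variance}, \code{fano} and \code{n_cycles}; the window average is
#'   attached as attribute \code{fano_mean}.
#' @export
fano_factor <- function(series, protocol, window = NULL) {
  sched <- protocol$schedule[order(protocol$schedule$start), ]
  cycle <- 1 / protocol$temporal_freq
  nc <- floor(sched$duration / cycle + 1e-9)
  offset <- cumsum(c(0, nc[-length(nc)]))
  counts <- integer(sum(nc))
  if (nrow(series)) {
    tr_i <- findInterval(series$time, sched$start)
    cyc <- floor((series$time - sched$start[tr_i]) / cycle) + 1L
    keep <- cyc >= 1 & cyc <= nc[tr_i]
    gid <- offset[tr_i[keep]] + cyc[keep]
    if (length(gid)) {
      agg <- rowsum(series$quanta[keep], gid)
      counts[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  cyc_contrast <- rep(sched$contrast, nc)
  out <- lapply(split(counts, cyc_contrast), function(cts) {
    if (length(cts) < 2) stop("need >= 2 cycles per contrast")
    m <- mean(cts)
    v <- stats::var(cts)
    data.frame(mean = m, variance = v,
               fano = if (m > 0) v / m else 0, n_cycles = length(cts))
  })
  res <- do.call(rbind, out)
  res$contrast <- as.numeric(names(out))
  res <- res[, c("contrast", "mean", "variance", "fano", "n_cycles")]
  res <- res[order(res$contrast), ]
  rownames(res) <- NULL
  fm <- if (!is.null(window))
    mean(res$fano[res$contrast >= window[1] & res$contrast <= window[2]])
  else mean(res$fano)
  structure(res, fano_mean = fm)
}

#' Shuffle-subtraction bias estimate for mutual information
#'
#' The plug-in estimator has a positive small-sample bias; its magnitude is
#' estimated by permuting the trial-to-contrast assignment (which preserves
#' the within-trial response statistics but destroys the stimulus
#' dependence) and averaging the residual information.
#'
#' @param binned a [bin_quanta()] result.
#' @param kmax largest quanta symbol.
#' @param n_shuffles number of label permutations.
#' @param seed seed for the permutations.
#' @return mean shuffled information, bits per bin.
#' @export
shuffled_information <- function(binned, kmax = 5, n_shuffles = 5,
                                 seed = 1L) {
  trials <- unique(binned$trial)
  labels <- binned$contrast[match(trials, binned$trial)]
  withr_seed(seed, {
    mean(vapply(seq_len(n_shuffles), function(i) {
      perm <- sample(labels)
      b2 <- binned
      b2$contrast <- perm[match(b2$trial, trials)]
      suppressWarnings(
        mutual_information(estimate_joint(b2, kmax = kmax))$I)
    }, numeric(1)))
  })
}

#' Synapse information metrics from a quantal series
#'
#' Convenience wrapper: bins the series, estimates the joint distribution
#' with a uniform stimulus prior, and returns information rate, efficiency
#' and Fano factor together with the release rate. With
#' \code{bias_correction} the plug-in information is reduced by the
#' shuffled-label estimate of the small-sample bias.
#'
#' @param series a \code{"quantal_series"}.
#' @param protocol the recording's [stim_protocol()].
#' @param bin_width bin width, s.
#' @param kmax largest quanta symbol.
#' @param bias_correction subtract the shuffled-label bias estimate.
#' @param seed seed for the bias-correction permutations.
#' @return one-row data frame: \code{release_rate}, \code{bits_per_bin},
#'   \code{bits_per_s}, \code{bits_per_vesicle}, \code{fano_mean}.
#' @export
synapse_info_metrics <- function(series, protocol, bin_width = 0.020,
                                 kmax = 5, bias_correction = FALSE,
                                 seed = 1L) {
  dur <- protocol_duration(protocol)
  rr <- release_rate(series, c(0, dur))
  binned <- suppressWarnings(bin_quanta(series, protocol, bin_width))
  joint <- suppressWarnings(estimate_joint(binned, kmax = kmax))
  mi <- mutual_information(joint)
  i_bits <- mi$I
  if (bias_correction)
    i_bits <- max(0, i_bits - shuffled_information(binned, kmax,
                                                   seed = seed))
  re <- suppressWarnings(
    info_rate_and_efficiency(i_bits, bin_width, rr))
  fano <- fano_factor(series, protocol)
  data.frame(release_rate = rr, bits_per_bin = i_bits,
             bits_per_s = re$bits_per_s,
             bits_per_vesicle = re$bits_per_vesicle,
             fano_mean = attr(fano, "fano_mean"))
}
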