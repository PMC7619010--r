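test_that("spatial component fitting recovers Gaussian sources", {
  dx <- 0.25
  x <- (seq_len(48) - 0.5) * dx
  # noiseless single Gaussian
  prof <- 20 + 80 * exp(-(x - 10)^2 / (2 * 1.5^2))
  rec <- structure(matrix(prof, 48, 300), dt = 0.001, dx = dx,
                   class = c("linescan", "matrix", "array"))
  comps <- fit_spatial_components(rec)
  expect_equal(nrow(comps), 1)
  expect_lt(abs(comps$center - 10), 0.1)

  # two equal Gaussians 8 um apart; oracle: an RSS scan over k = 1..4 on
  # the noiseless profile picks k = 2 with these centres
  prof2 <- 20 + 60 * exp(-(x - 3)^2 / (2 * 1.2^2)) +
    60 * exp(-(x - 11)^2 / (2 * 1.2^2))
  rec2 <- structure(matrix(prof2, 48, 300), dt = 0.001, dx = dx,
                    class = c("linescan", "matrix", "array"))
  comps2 <- fit_spatial_components(rec2)
  expect_equal(nrow(comps2), 2)
  expect_lt(max(abs(sort(comps2$center) - c(3, 11))), 0.2)

  # flat profile: no components
  expect_equal(nrow(fit_spatial_components(flat_linescan())), 0)
})

test_that("time-series extraction unmixes well-separated components", {
  dx <- 0.25; n_px <- 48; n_t <- 2000
  x <- (seq_len(n_px) - 0.5) * dx
  comps <- data.frame(center = c(3, 11), width = c(1.2, 1.2),
                      amplitude = c(100, 100))
  # disjoint-in-time transients on each component
  s1 <- numeric(n_t); s1[300:320] <- 0.8
  s2 <- numeric(n_t); s2[1200:1230] <- 0.5
  g1 <- exp(-(x - 3)^2 / (2 * 1.2^2))
  g2 <- exp(-(x - 11)^2 / (2 * 1.2^2))
  img <- 10 + 100 * (g1 %o% (1 + s1)) + 100 * (g2 %o% (1 + s2))
  rec <- structure(img, dt = 0.001, dx = dx,
                   class = c("linescan", "matrix", "array"))
  traces <- extract_timeseries(rec, comps)
  # oracle: per-pixel averaging over each component's +/- 2 sigma window
  for (i in 1:2) {
    sel <- abs(x - comps$center[i]) < 2 * comps$width[i]
    oracle <- colMeans(img[sel, ]) / mean(g_i <- exp(
      -(x[sel] - comps$center[i])^2 / (2 * 1.2^2)))
    peak_est <- (max(traces[i, ]) - median(traces[i, ])) /
      median(traces[i, ])
    true_peak <- if (i == 1) 0.8 else 0.5
    expect_equal(peak_est, true_peak, tolerance = 0.02)
  }
  # reconstruction: fitted model explains the spatially integrated signal
  G <- cbind(1, g1, g2)
  W <- solve(crossprod(G), crossprod(G, img))
  recon <- G %*% W
  ss_res <- sum((img - recon)^2)
  ss_tot <- sum((img - mean(img))^2)
  expect_gt(1 - ss_res / ss_tot, 0.95)
})

test_that("nearly coincident components are merged with a warning", {
  comps <- data.frame(center = c(5, 5.2), width = c(1.5, 1.5),
                      amplitude = c(50, 50))
  rec <- flat_linescan()
  expect_warning(tr <- extract_timeseries(rec, comps), "merged")
  expect_equal(nrow(attr(tr, "components")), 1)
})

test_that("dF/F0 uses the trace mode as baseline", {
  expect_equal(as.numeric(compute_dff(rep(5, 200), 0.01,
                                      bleach_correction = FALSE)),
               rep(0, 200))
  # brief excursions leave the mode at baseline
  set.seed(1)
  tr <- rnorm(2000, 100, 0.5)
  tr[300:340] <- 200
  d <- compute_dff(tr, 0.001, bleach_correction = FALSE)
  expect_equal(attr(d, "F0"), 100, tolerance = 0.01)
  expect_equal(max(d), 1.0, tolerance = 0.02)
  expect_error(compute_dff(rnorm(200, -5, 0.1), 0.001), "baseline")
})

test_that("bleach correction flattens a mono-exponential baseline", {
  t <- (0:59999) * 0.001
  set.seed(2)
  tr <- 100 * exp(-t / 300) + rnorm(length(t), 0, 1)
  d <- compute_dff(tr, 0.001, bleach_correction = TRUE)
  # residual baseline slope under 1% of F0 across the recording
  drift <- abs(mean(d[1:5000]) - mean(d[55000:60000]))
  expect_lt(drift, 0.01)
  expect_true(is.finite(attr(d, "bleach_tau")))
})

test_that("Wiener deconvolution inverts kernel-shaped transients", {
  n <- 8000
  d <- make_dff_trace(2.0, 1.0, n)
  x <- wiener_deconvolve(d, snr = Inf)
  i <- which.max(x)
  expect_equal((i - 1) * 0.001, 2.0, tolerance = 0.002)
  expect_equal(max(x), 1.0, tolerance = 0.01)

  # two transients 100 ms apart, amplitudes 1 and 2; oracle = forward
  # convolution of known impulses with the kernel
  d2 <- make_dff_trace(c(2.0, 2.1), c(1, 2), n)
  x2 <- wiener_deconvolve(d2, snr = 1e3)
  ev <- detect_events(x2, k_sd = 4)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$amplitude[2] / ev$amplitude[1], 2, tolerance = 0.05)
  expect_error(wiener_deconvolve(d, snr = -1), "snr")
})

test_that("deconvolution is linear", {
  n <- 6000
  d1 <- make_dff_trace(1.0, 0.7, n)
  d2 <- make_dff_trace(3.5, 1.3, n)
  both <- structure(as.numeric(d1) + as.numeric(d2), dt = 0.001)
  x1 <- wiener_deconvolve(d1, snr = 100)
  x2 <- wiener_deconvolve(d2, snr = 100)
  x12 <- wiener_deconvolve(both, snr = 100)
  expect_equal(as.numeric(x12), as.numeric(x1) + as.numeric(x2),
               tolerance = 1e-6)
})

test_that("event detection thresholds and merges correctly", {
  # pure noise at k_sd = 4: false events are at the tail-probability level
  set.seed(3)
  noise <- structure(rnorm(10000, 0, 0.05), dt = 0.001)
  ev <- detect_events(noise, k_sd = 4)
  expect_lte(nrow(ev), 4)

  # a single clear impulse dominates detection
  set.seed(7)
  x <- structure(c(rep(0, 4999), 0.5, rep(0, 5000)) +
                   rnorm(10000, 0, 0.02), dt = 0.001)
  ev1 <- detect_events(x, k_sd = 4)
  expect_equal(ev1$time[which.max(ev1$peak)], 4.999, tolerance = 0.002)
  expect_lte(nrow(ev1), 2)

  # monotonicity: count non-increasing in k_sd
  set.seed(4)
  xs <- structure(rnorm(20000, 0, 0.05), dt = 0.001)
  counts <- vapply(c(2, 3, 4, 5), function(k)
    nrow(detect_events(xs, k_sd = k)), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_events(xs, k_sd = 1), "k_sd")
})

test_that("event recall is high at quantal SNR 5", {
  reg <- synapse_regime(spont_rate = 4, evoked_max = 0, quantal_dff = 0.5,
                        noise_sd = 0.1, bleach_tau = Inf)
  prot <- protocol_constant(0, 40)
  tr <- simulate_release(reg, prot, seed = 31)
  rec <- render_linescan(tr, regime = reg, seed = 32)
  comps <- fit_spatial_components(rec)
  traces <- extract_timeseries(rec, comps)
  d <- compute_dff(traces[1, ], 0.001, bleach_correction = FALSE)
  x <- wiener_deconvolve(d)
  ev <- detect_events(x, k_sd = 3.5)
  hit <- vapply(tr$time, function(tt)
    any(abs(ev$time - tt) < 0.02), logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("quantal clustering identifies integer multiples", {
  ev <- structure(data.frame(time = 1:4, amplitude = c(0.20, 0.41, 0.60,
                                                       0.19),
                             peak = c(0.20, 0.41, 0.60, 0.19)),
                  class = c("event_series", "data.frame"), duration = 5)
  qs <- cluster_quanta(ev, quantal_size = 0.20)
  expect_equal(qs$quanta, c(1L, 2L, 3L, 1L))

  # parameter recovery on a seeded simulation
  set.seed(41)
  k <- sample(1:3, 500, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  a <- rnorm(500, k * 0.25, 0.10 * k * 0.25)
  ev2 <- structure(data.frame(time = seq_along(a), amplitude = a,
                              peak = a),
                   class = c("event_series", "data.frame"),
                   duration = 501)
  qs2 <- cluster_quanta(ev2)
  expect_equal(attr(qs2, "quantal_size"), 0.25, tolerance = 0.05 * 0.25)
  expect_gt(mean(qs2$quanta == k), 0.9)

  # single-amplitude population: all one quantum
  ev3 <- structure(data.frame(time = 1:30, amplitude = rnorm(30, 0.3,
                                                             0.01),
                              peak = 0.3),
                   class = c("event_series", "data.frame"), duration = 31)
  qs3 <- cluster_quanta(ev3)
  expect_true(all(qs3$quanta == 1))
  expect_equal(attr(qs3, "quantal_size"), 0.3, tolerance = 0.02)
})

test_that("quantal clustering is scale-equivariant", {
  set.seed(42)
  k <- sample(1:3, 300, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  a <- rnorm(300, k * 0.2, 0.02 * k)
  mk <- function(amp) structure(
    data.frame(time = seq_along(amp), amplitude = amp, peak = amp),
    class = c("event_series", "data.frame"), duration = 301)
  q1 <- cluster_quanta(mk(a), seed = 7)
  q2 <- cluster_quanta(mk(3 * a), seed = 7)
  expect_equal(attr(q2, "quantal_size"), 3 * attr(q1, "quantal_size"),
               tolerance = 1e-3)
  expect_identical(q1$quanta, q2$quanta)
})

test_that("release rate is quanta over time", {
  s <- structure(data.frame(time = seq(0.5, 9.5, length.out = 12),
                            quanta = rep(3L, 12)),
                 class = c("quantal_series", "data.frame"))
  expect_equal(release_rate(s, c(0, 10)), 3.6)
  empty <- structure(data.frame(time = numeric(0), quanta = integer(0)),
                     class = c("quantal_series", "data.frame"))
  expect_equal(release_rate(empty, c(0, 10)), 0)
})

test_that("noise-free pipeline recovers ground truth quanta exactly", {
  reg <- synapse_regime(spont_rate = 1.5, evoked_max = 0,
                        quantal_dff = 0.5, noise_sd = 0,
                        bleach_tau = Inf)
  prot <- protocol_constant(0, 30)
  tr <- simulate_release(reg, prot, seed = 51)
  rec <- render_linescan(tr, regime = reg, seed = 52)
  qs <- quantal_decompose(rec, bleach_correction = FALSE)[[1]]
  expect_equal(sum(qs$quanta), sum(tr$quanta))
})
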