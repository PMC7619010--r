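test_that("release trains are reproducible and strictly ordered", {
  reg <- synapse_regime(spont_rate = 2, evoked_max = 4, hill_c50 = 35,
                        hill_h = 1.5)
  prot <- stim_protocol(c(20, 40, 80), duration = 2, n_repeats = 5)
  a <- simulate_release(reg, prot, seed = 11)
  b <- simulate_release(reg, prot, seed = 11)
  expect_identical(a, b)
  expect_true(all(diff(a$time) > 0))
  expect_true(all(a$quanta >= 1))
  c2 <- simulate_release(reg, prot, seed = 12)
  expect_false(isTRUE(all.equal(a$time, c2$time)))
})

test_that("a silent synapse yields an empty train and zero-duration errors", {
  reg <- quiet_regime()
  prot <- protocol_constant(50, 10)
  expect_equal(nrow(simulate_release(reg, prot, 1)), 0)
  expect_error(stim_protocol(50, duration = 0), "duration")
})

test_that("spontaneous rate converges to the configured value", {
  reg <- synapse_regime(spont_rate = 3.6, evoked_max = 0, noise_sd = 0)
  prot <- protocol_constant(0, 200)
  tr <- simulate_release(reg, prot, seed = 3)
  rate <- sum(tr$quanta) / 200
  # compound Poisson: var of total = rate_events * E[K^2] * T
  w <- reg$mvr_weights
  ek2 <- sum(seq_along(w)^2 * w)
  mu <- sum(seq_along(w) * w)
  se <- sqrt(3.6 / mu * ek2 * 200) / 200
  expect_lt(abs(rate - 3.6), 3 * se)
})

test_that("evoked quanta per cycle match the Hill expectation", {
  # oracle: expectation recomputed from the Hill formula, compared with a
  # direct tally of generated quanta grouped by stimulus cycle
  reg <- synapse_regime(spont_rate = 0, evoked_max = 5.19, hill_c50 = 35,
                        hill_h = 1.5)
  prot <- protocol_constant(100, 200)  # 1000 cycles at 5 Hz
  tr <- simulate_release(reg, prot, seed = 5)
  cyc <- factor(floor(tr$time * 5), levels = 0:999)
  tallies <- as.numeric(tapply(tr$quanta, cyc, sum, default = 0))
  expected <- hill_response(100, reg$evoked_max, 35, 1.5)
  se <- sd(tallies) / sqrt(1000)
  expect_lt(abs(mean(tallies) - expected), 3 * se)
  # and the Hill expectation itself matches the printed afternoon response
  expect_equal(expected, 4.3, tolerance = 0.01)
})

test_that("rendered linescans are deterministic and reflect the kernel", {
  reg <- quiet_regime(quantal_dff = 0.5)
  prot <- protocol_constant(0, 2)
  tr <- simulate_release(reg, prot, 1)
  a <- render_linescan(tr, regime = reg, seed = 4)
  b <- render_linescan(tr, regime = reg, seed = 4)
  expect_identical(unclass(a), unclass(b))
  # empty train, no noise, no bleach: every pixel's trace is constant
  expect_equal(max(apply(a, 1, function(r) diff(range(r)))), 0)

  # single 1-quantum event: peak dF/F at the component centre equals
  # quantal_dff times the kernel maximum (kernel is peak-normalised)
  tr1 <- structure(data.frame(time = 0.5, quanta = 1L),
                   class = c("release_train", "data.frame"),
                   protocol = prot, regime = reg, seed = 1)
  rec <- render_linescan(tr1, regime = reg, seed = 4)
  centre_px <- which.max(rowMeans(rec))
  trace <- rec[centre_px, ]
  f0 <- trace[1]
  dff_peak <- (max(trace) - f0) / (f0 - 10)  # 10 = dark offset
  expect_equal(dff_peak, 0.5, tolerance = 0.01)
})

test_that("rendering rejects bad geometry and timing", {
  reg <- quiet_regime()
  tr <- simulate_release(reg, protocol_constant(0, 1), 1)
  expect_error(render_linescan(tr, regime = reg, dt = 0.01), "dt")
  expect_error(render_linescan(tr,
    components = data.frame(center = 50, width = 1, amplitude = 100),
    regime = reg), "outside")
})

test_that("generated bouts obey the turning-speed identity and contrast-0 symmetry", {
  reg <- behavior_regime(base_bout_rate = 1, max_bout_rate = 3)
  prot <- stim_protocol(c(0, 60), duration = 10, n_repeats = 3)
  fish <- simulate_behavior(reg, prot, n_fish = 6, seed = 21)
  gt <- do.call(rbind, lapply(fish, attr, "ground_truth"))
  # turning speed from the generator equals bout frequency x mean angle
  dur <- sum(attr(fish[[1]], "trials")$duration)
  ts <- sum(gt$angle) / (dur * length(fish))
  bf <- nrow(gt) / (dur * length(fish))
  expect_equal(ts, bf * mean(gt$angle), tolerance = 1e-12)
  # at contrast 0 only unbiased spontaneous bouts occur
  trials <- attr(fish[[1]], "trials")
  zero_ids <- trials$trial[trials$contrast == 0]
  gt0 <- gt[gt$trial_id %in% zero_ids, ]
  expect_false(any(gt0$evoked))
  se <- sd(gt0$angle) / sqrt(nrow(gt0))
  expect_lt(abs(mean(gt0$angle)), 3 * se)
})

test_that("all-scoot fish barely turn", {
  reg <- behavior_regime(scoot_fraction = 1, max_bout_rate = 3)
  prot <- protocol_constant(80, 20)
  fish <- simulate_behavior(reg, prot, n_fish = 2, seed = 8)
  gt <- do.call(rbind, lapply(fish, attr, "ground_truth"))
  expect_lt(max(abs(gt$angle)), 0.05)
})

test_that("behavior simulation is seed-deterministic", {
  reg <- behavior_regime()
  prot <- stim_protocol(c(20, 35), duration = 2, n_repeats = 2)
  a <- simulate_behavior(reg, prot, 2, seed = 5)
  b <- simulate_behavior(reg, prot, 2, seed = 5)
  expect_identical(a, b)
})

test_that("the default cohort encodes the six conditions and their spans", {
  tab <- cohort_table()
  expect_equal(nrow(tab), 6)
  expect_equal(max(tab$rel_info) / min(tab$rel_info), 4, tolerance = 1e-9)
  expect_equal(max(tab$rel_mcg) / min(tab$rel_mcg), 2.4, tolerance = 1e-9)
  coh <- configure_cohort()
  expect_named(coh, tab$condition)
  # angle statistics are shared across conditions: modulation acts on bout
  # frequency, not amplitude
  angles <- vapply(coh, function(x) x$behavior$angle_mean, 0)
  expect_true(all(angles == angles[1]))
  # the diurnal controls carry the printed release physiology
  am <- coh$am_control$synapse; pm <- coh$pm_control$synapse
  expect_equal(am$spont_rate, 3.6)
  expect_equal(pm$spont_rate, 0.8)
  expect_equal(hill_response(100, am$evoked_max, am$hill_c50, am$hill_h),
               2.7, tolerance = 1e-6)
  expect_equal(hill_response(100, pm$evoked_max, pm$hill_c50, pm$hill_h),
               4.3, tolerance = 1e-6)
  expect_error(configure_cohort("noon_control"), "unknown condition")
})
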