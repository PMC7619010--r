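# shared fixtures: small regimes and synthetic traces built in code

quiet_regime <- function(...) {
  synapse_regime(spont_rate = 0, evoked_max = 0, noise_sd = 0,
                 bleach_tau = Inf, ...)
}

# dff trace containing impulses convolved with the reporter kernel
make_dff_trace <- function(times_s, amps, n, dt = 0.001,
                           noise_sd = 0, seed = 1) {
  imp <- numeric(n)
  idx <- round(times_s / dt) + 1
  for (j in seq_along(idx)) imp[idx[j]] <- imp[idx[j]] + amps[j]
  kern <- iglu_kernel(dt)
  y <- retinfo:::fft_convolve(imp, kern)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n, 0, noise_sd)
  }
  structure(y, dt = dt)
}

# spatial profile helper: linescan-like matrix from a constant trace
flat_linescan <- function(n_pixels = 32, n_t = 500, value = 100,
                          dx = 0.25, dt = 0.001) {
  structure(matrix(value, n_pixels, n_t), dt = dt, dx = dx,
            class = c("linescan", "matrix", "array"))
}
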