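#!/usr/bin/env Rscript
# Stage 1 — generate the six-condition synthetic cohort.
#
# Writes, under results/cohort/: one linescan (TIFF + JSON sidecar) and one
# ground-truth release train per example synapse, and the free-swimming
# trajectories (CSV) for every condition. Later stages re-derive everything
# from these files, so the whole analysis can be audited from disk.

suppressMessages(library(retinfo))

seed <- 20260927L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- configure_cohort()
cat("Conditions:", paste(names(cohort), collapse = ", "), "\n")

for (ci in seq_along(cohort)) {
  cond <- names(cohort)[ci]
  reg <- cohort[[ci]]$synapse
  # two example synapses per condition are rendered as full linescans
  for (s in 1:2) {
    prot <- synapse_gain_protocol(reg, n_repeats = 6,
                                  order_seed = seed + ci * 10 + s)
    train <- simulate_release(reg, prot, seed + ci * 100 + s)
    rec <- render_linescan(train, regime = reg, seed = seed + ci * 100 +
                             50 + s)
    write_linescan(rec, file.path(out, sprintf("%s_syn%02d.tif", cond, s)))
  }
  # a 12-fish behavioral cohort per condition
  bprot <- stim_protocol(seq(15, 35, 2), duration = 2, n_repeats = 10,
                         order_seed = seed + ci)
  fish <- simulate_behavior(cohort[[ci]]$behavior, bprot, n_fish = 12,
                            seed = seed + 500 + ci)
  write_trajectories(fish, file.path(out, sprintf("%s_fish.csv", cond)))
  cat(sprintf("  %-12s: 2 linescans, 12 fish written\n", cond))
}
cat("Stage 1 complete ->", out, "\n")
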