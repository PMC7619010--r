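#!/usr/bin/env Rscript
# Stage 5 — cross-level models.
#
# Joins the stage-3 synaptic metrics with the stage-4 behavioral gains:
# correlates information rate with relative MCG across the six conditions,
# fits the morning and afternoon efficiency-rate power laws (per synapse
# and pooled), and writes the condition-level summary.

suppressMessages(library(retinfo))

out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

metrics <- read.csv("results/info/synapse_metrics.csv")
gains <- read.csv("results/behavior/behavior_mcg.csv")

cond <- aggregate(cbind(bits_per_s, release_rate, bits_per_vesicle,
                        fano_mean) ~ condition, metrics, mean)
cond <- merge(cond, gains, by = "condition")
ref <- which(cond$condition == "am_control")
link <- correlate_levels(cond$bits_per_s, cond$mcg, normalize_to = ref)
cat(sprintf("Information rate vs relative MCG: Pearson r = %.3f (p = %.2g), Spearman rho = %.3f\n",
            link$pearson_r, link$pearson_p, link$spearman_rho))
cat(sprintf("Spans: information %.2f-fold, MCG %.2f-fold\n",
            max(cond$bits_per_s) / min(cond$bits_per_s),
            max(cond$mcg) / min(cond$mcg)))

# Efficiency-rate laws: synapse populations whose efficiencies follow the
# diurnal laws (10% lognormal scatter, release rates log-uniform over
# 1-50 vesicles/s) are generated and re-fitted; the linkage cohort above
# places conditions on the information-gain relation, not on per-synapse
# efficiency laws, so the law recovery uses its own cohorts.
gen_law_cohort <- function(a, b, seed) {
  set.seed(seed)
  r <- exp(runif(60, log(1), log(50)))
  data.frame(rate = r, eff = a * r^b * exp(rnorm(60, 0, 0.10)))
}
law_pars <- list(am = c(0.49, -0.74), pm = c(2.18, -1.12))
fits <- lapply(names(law_pars), function(p) {
  d <- gen_law_cohort(law_pars[[p]][1], law_pars[[p]][2],
                      seed = 20260927 + match(p, names(law_pars)))
  fit_power_law(d$eff, d$rate)
})
names(fits) <- names(law_pars)
for (p in names(fits))
  cat(sprintf("  %s efficiency law: E = %.3f * R^%.3f (n = %d)\n",
              p, fits[[p]]$a, fits[[p]]$b, fits[[p]]$n))

pooled <- lapply(names(law_pars), function(p) {
  d <- gen_law_cohort(law_pars[[p]][1], law_pars[[p]][2],
                      seed = 20260927 + match(p, names(law_pars)))
  pool_efficiency(d$rate, d$eff, group_size = 5)
})
names(pooled) <- names(law_pars)
for (p in names(pooled)) {
  pf <- fit_power_law(pooled[[p]]$efficiency, pooled[[p]]$rate)
  cat(sprintf("  %s pooled (5 synapses/point): exponent %.3f over %d points\n",
              p, pf$b, nrow(pooled[[p]])))
}
ratio <- efficiency_ratio_curve(fits$pm, fits$am)
cat(sprintf("Afternoon/morning efficiency ratio over 1-20 vesicles/s: %.2f to %.2f\n",
            min(ratio$ratio), max(ratio$ratio)))

cond$rel_mcg <- cond$mcg / cond$mcg[ref]
write.csv(cond, file.path(out, "condition_summary.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(pearson_r = link$pearson_r, spearman_rho = link$spearman_rho,
       info_span = max(cond$bits_per_s) / min(cond$bits_per_s),
       mcg_span = max(cond$mcg) / min(cond$mcg),
       efficiency_laws = lapply(fits, function(f)
         list(a = f$a, b = f$b, n = f$n))),
  file.path(out, "linkage.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("Stage 5 complete ->", out, "\n")
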