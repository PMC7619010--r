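#' End-to-end cohort pipeline
#'
#' Runs the full analysis chain over a multi-condition cohort: simulate
#' synaptic release and swimming, recover quantal series (from rendered
#' linescans for a validation subset, or for every synapse), compute
#' per-synapse information metrics and per-condition behavioral gain, then
#' fit the cross-level models (information rate versus behavioral gain,
#' efficiency-rate power laws).
#'
#' All randomness derives from \code{seed}: each (stage, condition, unit)
#' gets the child seed \code{seed * 1000 + stage_offset + unit}, with fixed
#' per-stage offsets, so identical configurations reproduce byte-identical
#' outputs.
#'
#' @param seed master integer seed.
#' @param conditions condition names (default: the full six-condition
#'   table).
#' @param n_synapses synapses per condition.
#' @param n_fish fish per condition.
#' @param n_repeats_syn trials per contrast for the synapse protocol.
#' @param n_repeats_beh trials per contrast for the behavior protocol.
#' @param render_linescans \code{FALSE} (neural metrics from ground-truth
#'   trains), \code{TRUE} (render and decompose every synapse) or
#'   \code{"subset"} (render the first two synapses per condition as an
#'   imaging-recovery check while metrics still come from full trains).
#' @param bias_correction shuffle-subtract the information estimator bias.
#' @param out_dir optional directory; per-stage CSV/JSON outputs are
#'   written there.
#' @return a \code{"cohort_report"} list: \code{synapses} (per-synapse
#'   metrics), \code{conditions} (per-condition summary), \code{linkage}
#'   (correlation of information rate with behavioral gain),
#'   \code{efficiency} (per-period power-law fits), \code{render_check}.
#' @export
run_pipeline <- function(seed, conditions = NULL, n_synapses = 12,
                         n_fish = 30, n_repeats_syn = 100,
                         n_repeats_beh = 30,
                         render_linescans = "subset",
                         bias_correction = TRUE, out_dir = NULL) {
  cohort <- configure_cohort(conditions)
  if (length(cohort) == 0) stop("empty cohort: no conditions configured")
  if (n_synapses < 1) stop("simulate stage needs n_synapses >= 1")

  syn_rows <- list()
  render_rows <- list()
  beh_rows <- list()
  for (ci in seq_along(cohort)) {
    cond <- names(cohort)[ci]
    reg <- cohort[[ci]]$synapse
    breg <- cohort[[ci]]$behavior
    # --- synaptic level -------------------------------------------------
    for (s in seq_len(n_synapses)) {
      child <- seed * 1000 + ci * 100 + s
      prot <- synapse_gain_protocol(reg, n_repeats_syn,
                                    order_seed = child)
      train <- simulate_release(reg, prot, child)
      series <- train
      attr(series, "duration") <- protocol_duration(prot)
      do_render <- isTRUE(render_linescans) ||
        (identical(render_linescans, "subset") && s <= 2)
      if (do_render) {
        rec <- render_linescan(train, regime = reg, seed = child + 1L)
        qs <- quantal_decompose(rec)
        if (length(qs)) {
          if (isTRUE(render_linescans)) series <- qs[[1]]
          render_rows[[length(render_rows) + 1]] <- data.frame(
            condition = cond, synapse = s,
            gt_quanta = sum(train$quanta),
            recovered_quanta = sum(qs[[1]]$quanta))
        }
      }
      m <- synapse_info_metrics(series, prot,
                                bias_correction = bias_correction,
                                seed = child)
      syn_rows[[length(syn_rows) + 1]] <-
        cbind(data.frame(condition = cond, synapse = s), m)
    }
    # --- behavioral level -----------------------------------------------
    bprot <- stim_protocol(seq(15, 35, 2), duration = 2,
                           n_repeats = n_repeats_beh,
                           order_seed = seed * 1000 + ci)
    fish <- simulate_behavior(breg, bprot, n_fish,
                              seed = seed * 1000 + 500 + ci)
    crf <- build_behavior_crf(fish)
    gain <- measure_mcg(crf$contrast, crf$response)
    beh_rows[[ci]] <- data.frame(condition = cond, mcg = gain$mcg,
                                 period = cohort[[ci]]$row$period)
  }
  synapses <- do.call(rbind, syn_rows)
  behavior <- do.call(rbind, beh_rows)

  # --- condition summaries and cross-level models -----------------------
  cond_sum <- do.call(rbind, lapply(split(synapses, synapses$condition),
    function(g) data.frame(condition = g$condition[1],
                           bits_per_s = mean(g$bits_per_s),
                           release_rate = mean(g$release_rate),
                           bits_per_vesicle = mean(g$bits_per_vesicle,
                                                   na.rm = TRUE),
                           fano_mean = mean(g$fano_mean))))
  cond_sum <- merge(cond_sum, behavior, by = "condition", sort = FALSE)
  cond_sum <- cond_sum[match(names(cohort), cond_sum$condition), ]
  rownames(cond_sum) <- NULL

  ref <- if ("am_control" %in% cond_sum$condition)
    which(cond_sum$condition == "am_control") else 1L
  linkage <- if (nrow(cond_sum) >= 3)
    correlate_levels(cond_sum$bits_per_s, cond_sum$mcg,
                     normalize_to = ref) else NULL
  eff_fits <- lapply(split(synapses,
                           behavior$period[match(synapses$condition,
                                                 behavior$condition)]),
    function(g) {
      ok <- is.finite(g$bits_per_vesicle) & g$bits_per_vesicle > 0 &
        g$release_rate > 0
      if (sum(ok) >= 5)
        fit_power_law(g$bits_per_vesicle[ok], g$release_rate[ok])
      else NULL
    })

  report <- structure(
    list(synapses = synapses, conditions = cond_sum,
         behavior = behavior, linkage = linkage, efficiency = eff_fits,
         render_check = if (length(render_rows))
           do.call(rbind, render_rows) else NULL,
         seed = seed),
    class = "cohort_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort pipeline report (seed ", x$seed, ")\n", sep = "")
  print(x$conditions, digits = 4)
  span <- max(x$conditions$bits_per_s) / min(x$conditions$bits_per_s)
  mcg_span <- max(x$conditions$mcg) / min(x$conditions$mcg)
  cat(sprintf("information-rate span %.2f-fold; MCG span %.2f-fold\n",
              span, mcg_span))
  if (!is.null(x$linkage))
    cat(sprintf("Pearson r (info rate vs MCG) = %.3f (p = %.2g)\n",
                x$linkage$pearson_r, x$linkage$pearson_p))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$synapses,
                   file.path(out_dir, "synapse_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$conditions,
                   file.path(out_dir, "condition_summary.csv"),
                   row.names = FALSE)
  metrics <- list(
    seed = report$seed,
    info_rate_span = max(report$conditions$bits_per_s) /
      min(report$conditions$bits_per_s),
    mcg_span = max(report$conditions$mcg) / min(report$conditions$mcg),
    pearson_r = if (!is.null(report$linkage))
      report$linkage$pearson_r else NA,
    spearman_rho = if (!is.null(report$linkage))
      report$linkage$spearman_rho else NA,
    efficiency_exponents = lapply(report$efficiency, function(f)
      if (!is.null(f)) f$b else NA))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
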