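#' Write a linescan recording to disk
#'
#' The pixel matrix goes to a 32-bit float TIFF (values scaled to 0-1 by a
#' stored factor) and the acquisition metadata (dt, dx, kernel constants)
#' plus the ground-truth train, when present, to a JSON sidecar named
#' \code{<file>.json}.
#'
#' @param recording a \code{"linescan"}.
#' @param file output TIFF path.
#' @export
write_linescan <- function(recording, file) {
  offset <- min(recording)
  scale <- max(max(recording) - offset, 1e-12) * 1.0001
  tiff::writeTIFF((unclass(recording) - offset) / scale, file,
                  bits.per.sample = 32L)
  gt <- attr(recording, "ground_truth")
  meta <- list(dt = attr(recording, "dt"), dx = attr(recording, "dx"),
               scale = scale, offset = offset,
               tau_r = attr(recording, "tau_r"),
               tau_f = attr(recording, "tau_f"),
               ground_truth = if (!is.null(gt))
                 list(time = gt$time, quanta = gt$quanta) else NULL)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a linescan recording written by [write_linescan()]
#'
#' @param file TIFF path (expects the JSON sidecar alongside).
#' @return a \code{"linescan"} matrix with metadata attributes.
#' @export
read_linescan <- function(file) {
  img <- tiff::readTIFF(file)
  meta <- jsonlite::fromJSON(paste0(file, ".json"))
  out <- img * meta$scale + meta$offset
  gt <- NULL
  if (!is.null(meta$ground_truth))
    gt <- data.frame(time = meta$ground_truth$time,
                     quanta = as.integer(meta$ground_truth$quanta))
  structure(out, dt = meta$dt, dx = meta$dx, tau_r = meta$tau_r,
            tau_f = meta$tau_f, ground_truth = gt,
            class = c("linescan", "matrix", "array"))
}

#' Write trajectories to CSV
#'
#' One CSV for a list of fish recordings, columns \code{fish},
#' \code{time_s}, \code{x_mm}, \code{y_mm}, \code{heading_rad},
#' \code{trial_id}, \code{contrast_pct}, \code{drift_sign}.
#'
#' @param cohort list of \code{"trajectory"} data frames.
#' @param file output CSV path.
#' @export
write_trajectories <- function(cohort, file) {
  rows <- do.call(rbind, lapply(cohort, function(rec) {
    cbind(fish = attr(rec, "fish"), as.data.frame(rec))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read trajectories written by [write_trajectories()]
#'
#' @param file CSV path.
#' @param frame_rate sampling rate, Hz.
#' @return list of \code{"trajectory"} data frames, one per fish.
#' @export
read_trajectories <- function(file, frame_rate = 150) {
  rows <- utils::read.csv(file)
  lapply(split(rows, rows$fish), function(g) {
    trials <- unique(g[, c("trial_id", "contrast_pct", "drift_sign")])
    starts <- vapply(trials$trial_id, function(id)
      min(g$time_s[g$trial_id == id]), 0)
    durs <- vapply(trials$trial_id, function(id) {
      tt <- g$time_s[g$trial_id == id]
      diff(range(tt)) + 1 / frame_rate
    }, 0)
    sched <- data.frame(contrast = trials$contrast_pct,
                        duration = durs, start = starts,
                        trial = trials$trial_id,
                        drift_sign = trials$drift_sign)
    structure(g[, setdiff(names(g), "fish")],
              class = c("trajectory", "data.frame"),
              frame_rate = frame_rate, trials = sched,
              fish = g$fish[1])
  })
}

#' Write a quantal series to CSV
#'
#' Columns \code{time_s}, \code{quanta}; the quantal size and duration in a
#' JSON sidecar.
#'
#' @param series a \code{"quantal_series"}.
#' @param file output CSV path.
#' @export
write_quantal_series <- function(series, file) {
  utils::write.csv(data.frame(time_s = series$time,
                              quanta = series$quanta),
                   file, row.names = FALSE)
  jsonlite::write_json(list(quantal_size = attr(series, "quantal_size"),
                            duration = attr(series, "duration")),
                       paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a quantal series written by [write_quantal_series()]
#'
#' @param file CSV path.
#' @return a \code{"quantal_series"}.
#' @export
read_quantal_series <- function(file) {
  d <- utils::read.csv(file)
  meta <- jsonlite::fromJSON(paste0(file, ".json"))
  structure(data.frame(time = d$time_s, quanta = as.integer(d$quanta)),
            class = c("quantal_series", "data.frame"),
            quantal_size = meta$quantal_size, duration = meta$duration)
}
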