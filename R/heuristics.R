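#' Configuration for the heuristic baselines
#'
#' @param angle_threshold maximum absolute change between successive 5-s
#'   z-angle cells within a still run, in degrees.
#' @param min_still_duration minimum still-run duration labelled sleep, in
#'   minutes.
#' @param count_epoch_length epoch length for activity counts, in seconds.
#' @return an object of class `heuristic_config`.
#' @export
heuristic_config <- function(angle_threshold = 5, min_still_duration = 5,
                             count_epoch_length = 30) {
  if (angle_threshold <= 0 || min_still_duration <= 0 || count_epoch_length <= 0) {
    stop_config("heuristic thresholds must be positive")
  }
  structure(list(angle_threshold = angle_threshold,
                 min_still_duration = min_still_duration,
                 count_epoch_length = count_epoch_length),
            class = "heuristic_config")
}

#' van Hees posture-angle sleep detection
#'
#' Successive differences of the 5-s z-angle series are computed; maximal runs
#' in which every absolute difference is at most the angle threshold and whose
#' total span is at least the minimum still duration are labelled sleep, all
#' other cells wake. The 5-s labels are reduced to 30-s epochs by majority
#' vote, ties going to sleep. Slow drift is tolerated: only step-wise changes
#' count, not cumulative drift from the run start.
#'
#' @param z_angle per-5-s angle series from [compute_z_angle()].
#' @param config a [heuristic_config()].
#' @return factor with levels `sleep`, `wake`, one per 30-s epoch.
#' @export
vanhees_classify <- function(z_angle, config = heuristic_config()) {
  n_cells <- length(z_angle)
  cells_per_epoch <- 6L
  n_ep <- n_cells %/% cells_per_epoch
  min_cells <- as.integer(config$min_still_duration * 60 / 5)
  cell_sleep <- rep(FALSE, n_cells)
  if (n_cells >= min_cells) {
    ok <- abs(diff(z_angle)) <= config$angle_threshold
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (r$values[j] && (r$lengths[j] + 1L) >= min_cells) {
        cell_sleep[starts[j]:(ends[j] + 1L)] <- TRUE
      }
    }
  }
  votes <- colSums(matrix(cell_sleep[seq_len(n_ep * cells_per_epoch)],
                          cells_per_epoch, n_ep))
  factor(ifelse(votes >= cells_per_epoch / 2, "sleep", "wake"),
         levels = c("sleep", "wake"))
}

#' Zero-crossing activity counts from raw acceleration
#'
#' The z axis is band-pass filtered (0.25-3 Hz, 4th-order Butterworth applied
#' forward and backward for zero phase) and positive-going crossings of a
#' 0.01 g dead-band are counted per epoch. The derivation of counts from raw
#' data is this package's own (historical devices computed counts onboard);
#' the filter band and dead-band are pinned here.
#'
#' @param recording a [raw_recording()] sampled at >= 10 Hz.
#' @param epoch_length count epoch length in seconds.
#' @return integer vector of per-epoch counts (>= 0).
#' @export
counts_from_raw <- function(recording, epoch_length = 30) {
  stopifnot(inherits(recording, "raw_recording"))
  sr <- recording$sample_rate
  if (sr < 10) stop_config("sample rate must be >= 10 Hz for counts")
  bf <- signal::butter(2, c(0.25, 3) / (sr / 2), type = "pass")
  # demean first: the band-pass removes DC anyway, and subtracting the mean
  # keeps the zero-phase filter's edge transients negligible
  z <- signal::filtfilt(bf, recording$az - mean(recording$az))
  dead <- 0.01
  up <- which(z[-1] >= dead & z[-length(z)] < dead) + 1L
  spe <- as.integer(sr * epoch_length)
  n_ep <- length(z) %/% spe
  counts <- tabulate((up - 1L) %/% spe + 1L, nbins = n_ep)
  as.integer(counts)
}

# Cole-Kripke (1992) 7-epoch weights over activity A[-4..+2], scaled 1e-5;
# weighted score < 1 scores the epoch sleep.
cole_kripke_weights <- c(404, 598, 326, 441, 408, 508, 350) * 1e-5

#' Cole-Kripke sleep-wake classification from activity counts
#'
#' Weighted sum of the four previous, current, and two following epoch counts
#' with the published weights; a score below 1 is sleep. Epochs beyond the
#' series boundaries contribute zero activity.
#'
#' @param counts per-epoch activity counts.
#' @param scores if `TRUE`, return the numeric scores instead of labels.
#' @return factor with levels `sleep`, `wake` (or scores).
#' @export
cole_kripke_classify <- function(counts, scores = FALSE) {
  n <- length(counts)
  if (n < 7) return(factor(rep("wake", n), levels = c("sleep", "wake")))
  padded <- c(rep(0, 4), counts, rep(0, 2))
  score <- vapply(seq_len(n), function(i) {
    sum(cole_kripke_weights * padded[i:(i + 6)])
  }, numeric(1))
  if (scores) return(score)
  factor(ifelse(score < 1, "sleep", "wake"), levels = c("sleep", "wake"))
}

#' Sadeh sleep-wake classification from activity counts
#'
#' The published linear score over an 11-epoch window centred on the current
#' epoch: `PS = 7.601 - 0.065 * AVG - 1.08 * NATS - 0.056 * SD - 0.703 * LG`,
#' where AVG is the window mean, NATS the number of window epochs with counts
#' in \[50, 100), SD the standard deviation of the current and five preceding
#' epochs, and LG the natural log of the current count plus one. `PS >= 0` is
#' sleep. Epochs beyond the series boundaries contribute zero activity.
#'
#' @param counts per-epoch activity counts.
#' @param scores if `TRUE`, return the numeric scores instead of labels.
#' @return factor with levels `sleep`, `wake` (or scores).
#' @export
sadeh_classify <- function(counts, scores = FALSE) {
  n <- length(counts)
  if (n < 11) return(factor(rep("wake", n), levels = c("sleep", "wake")))
  padded <- c(rep(0, 5), counts, rep(0, 5))
  score <- vapply(seq_len(n), function(i) {
    win <- padded[i:(i + 10)]            # epochs i-5 .. i+5
    sd6 <- sd(padded[i:(i + 5)])         # current + 5 preceding
    7.601 - 0.065 * mean(win) - 1.08 * sum(win >= 50 & win < 100) -
      0.056 * sd6 - 0.703 * log(counts[i] + 1)
  }, numeric(1))
  if (scores) return(score)
  factor(ifelse(score >= 0, "sleep", "wake"), levels = c("sleep", "wake"))
}
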