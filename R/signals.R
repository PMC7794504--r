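#' ENMO: Euclidean norm minus one, floored at zero
#'
#' Per-sample `max(0, sqrt(ax^2 + ay^2 + az^2) - 1)` in g; a gravity-removed
#' proxy for movement magnitude. A stationary sensor (vector norm 1 g) has
#' ENMO exactly 0.
#'
#' @param recording a [raw_recording()] with axes in g.
#' @return numeric vector, one value per sample, all `>= 0`.
#' @export
compute_enmo <- function(recording) {
  stopifnot(inherits(recording, "raw_recording"))
  pmax(0, sqrt(recording$ax^2 + recording$ay^2 + recording$az^2) - 1)
}

#' z-angle: posture angle from rolling 5-s axis medians
#'
#' Per sample, the three axes are replaced by their rolling 5-s medians and
#' the angle of the z axis against the horizontal plane is
#' `atan(az / sqrt(ax^2 + ay^2)) * 180 / pi`; the per-sample angles are then
#' averaged into consecutive 5-s cells. The angle depends only on orientation:
#' gravity along +z gives +90 deg, gravity in the horizontal plane 0 deg,
#' inverted -90 deg.
#'
#' A window in which all three medians are zero (impossible for a working
#' sensor) yields 0 deg with a warning.
#'
#' @param recording a [raw_recording()] of at least 5 s.
#' @return numeric vector of 5-s cell angles in degrees, in `[-90, 90]`.
#' @export
compute_z_angle <- function(recording) {
  stopifnot(inherits(recording, "raw_recording"))
  sr <- recording$sample_rate
  n <- length(recording$time)
  if (n < 5 * sr) stop_format("recording shorter than one 5-s window")
  k <- as.integer(round(5 * sr))
  if (k %% 2L == 0L) k <- k + 1L
  mx <- stats::runmed(recording$ax, k, endrule = "median")
  my <- stats::runmed(recording$ay, k, endrule = "median")
  mz <- stats::runmed(recording$az, k, endrule = "median")
  horiz <- sqrt(mx^2 + my^2)
  ang <- atan2(mz, horiz) * 180 / pi
  degen <- horiz == 0 & mz == 0
  if (any(degen)) {
    warning("all-zero axis medians in ", sum(degen),
            " sample(s); z-angle set to 0 there")
    ang[degen] <- 0
  }
  cell <- as.integer(5 * sr)
  n_cells <- n %/% cell
  colMeans(matrix(ang[seq_len(n_cells * cell)], cell, n_cells))
}

#' LIDS: locomotor inactivity during sleep
#'
#' ENMO is thresholded at 0.02 g (`max(0, ENMO - 0.02)`), aggregated to 30-s
#' epoch means, and summed over a centred 10-min (20-epoch) moving window to
#' give the activity count; `LIDS = 100 / (activity count + 1)` is then
#' smoothed with a centred 30-min (60-epoch) moving average. Edge epochs use
#' shrinking windows. A recording with no supra-threshold movement has LIDS
#' exactly 100 at every epoch.
#'
#' @param enmo per-sample ENMO series (g), from [compute_enmo()].
#' @param sample_rate sampling frequency in Hz.
#' @param epoch_length epoch length in seconds.
#' @return list with per-epoch numeric vectors `lids` (in `(0, 100]`),
#'   `lids_raw` (unsmoothed) and `activity_count` (`>= 0`).
#' @export
compute_lids <- function(enmo, sample_rate, epoch_length = 30) {
  spe <- as.integer(sample_rate * epoch_length)
  n_ep <- length(enmo) %/% spe
  if (n_ep < 1) stop_format("recording shorter than one epoch")
  if (n_ep < 20) {
    warning("recording shorter than 10 min; LIDS uses partial moving windows")
  }
  thr <- pmax(0, enmo - 0.02)
  ep_mean <- colMeans(matrix(thr[seq_len(n_ep * spe)], spe, n_ep))
  activity_count <- roll_center(ep_mean, 20L, op = "sum")
  lids_raw <- 100 / (activity_count + 1)
  lids <- roll_center(lids_raw, 60L, op = "mean")
  list(lids = lids, lids_raw = lids_raw, activity_count = activity_count)
}

#' Compute all derived signals for a recording
#'
#' @param recording a [raw_recording()].
#' @param epoch_length epoch length in seconds.
#' @return an object of class `derived_signals`: per-sample `enmo`, per-5-s
#'   `z_angle`, per-epoch `lids` and `activity_count`, plus grid metadata
#'   (`sample_rate`, `epoch_length`, `n_epochs`).
#' @export
compute_derived_signals <- function(recording, epoch_length = 30) {
  enmo <- compute_enmo(recording)
  zang <- compute_z_angle(recording)
  n_ep <- n_epochs_of(length(enmo), recording$sample_rate, epoch_length)
  lids <- compute_lids(enmo, recording$sample_rate, epoch_length)
  structure(
    list(enmo = enmo, z_angle = zang, lids = lids$lids,
         activity_count = lids$activity_count,
         sample_rate = recording$sample_rate, epoch_length = epoch_length,
         n_epochs = n_ep, participant_id = recording$participant_id),
    class = "derived_signals"
  )
}

#' @export
print.derived_signals <- function(x, ...) {
  cat(sprintf("<derived_signals> %s: %d epochs at %g Hz\n",
              x$participant_id, x$n_epochs, x$sample_rate))
  invisible(x)
}
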