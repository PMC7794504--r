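#' Raw tri-axial recording container
#'
#' @param participant_id opaque identifier.
#' @param start_time POSIXct time of the first sample.
#' @param time numeric seconds since `start_time`, strictly increasing.
#' @param ax,ay,az per-axis acceleration in g.
#' @param sample_rate nominal sampling frequency in Hz.
#' @param allow_gaps if `FALSE` (default) a gap between consecutive samples
#'   larger than twice the sample interval is a format error.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(participant_id, start_time, time, ax, ay, az,
                          sample_rate, allow_gaps = FALSE) {
  n <- length(time)
  if (!all(lengths(list(ax, ay, az)) == n)) {
    stop_format("axis arrays and timestamps must have equal length")
  }
  if (n < 2) stop_format("recording needs at least two samples")
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop_format("timestamps must be strictly increasing (duplicate or reversed timestamp)")
  }
  if (!allow_gaps && any(dt > 2 / sample_rate + 1e-9)) {
    stop_format("timestamp gap exceeds twice the sample interval")
  }
  structure(
    list(participant_id = as.character(participant_id),
         start_time = start_time, time = as.numeric(time),
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         sample_rate = sample_rate),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d samples at %g Hz (%.2f h), start %s\n",
              x$participant_id, length(x$time), x$sample_rate,
              length(x$time) / x$sample_rate / 3600,
              format(x$start_time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")))
  invisible(x)
}

#' Write a raw recording as delimited text
#'
#' Dialect: `#`-prefixed header lines declaring participant id, units and
#' sample rate, then comma-separated rows `timestamp,x,y,z` with ISO-8601
#' timestamps (UTC, millisecond precision) and axes in g.
#'
#' @param rec a [raw_recording()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_raw <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  header <- c(
    sprintf("# participant_id: %s", rec$participant_id),
    "# units: g",
    sprintf("# sample_rate: %s", format(rec$sample_rate))
  )
  # %OS3 truncates fractional seconds, so nudge by half a millisecond to
  # round to the nearest millisecond instead
  ts <- format(rec$start_time + rec$time + 5e-4, "%Y-%m-%dT%H:%M:%OS3Z",
               tz = "UTC")
  writeLines(header, path)
  data.table::fwrite(
    data.frame(timestamp = ts, x = rec$ax, y = rec$ay, z = rec$az),
    path, append = TRUE, col.names = TRUE
  )
  invisible(path)
}

read_header <- function(path, max_lines = 20L) {
  lines <- readLines(path, n = max_lines)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

#' Read a raw recording from delimited text
#'
#' Expects the dialect written by [write_raw()]: a `#` header declaring
#' `units` (g or m/s2) and `sample_rate`, then `timestamp,x,y,z` rows.
#' Accelerations declared in m/s2 are converted to g (9.81 m/s2 per g).
#'
#' @param path input file.
#' @param allow_gaps passed to [raw_recording()].
#' @return a [raw_recording()].
#' @export
read_raw <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  hdr <- read_header(path)
  if (is.null(hdr$units) || is.null(hdr$sample_rate)) {
    stop_format("header must declare units and sample_rate")
  }
  units <- tolower(hdr$units)
  if (!units %in% c("g", "m/s2", "m/s^2", "ms2")) {
    stop_format("unknown units: ", hdr$units)
  }
  sr <- as.numeric(hdr$sample_rate)
  dt <- data.table::fread(path, skip = length(grep("^#", readLines(path, 20L))),
                          header = TRUE)
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(dt))) {
    stop_format("missing column(s): ", paste(setdiff(need, names(dt)), collapse = ", "))
  }
  ts <- as.POSIXct(dt$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(ts)) stop_format("unparseable ISO-8601 timestamp")
  time <- round(as.numeric(ts) - as.numeric(ts[1]), 6)
  scale <- if (units == "g") 1 else 1 / 9.81
  raw_recording(
    participant_id = hdr$participant_id %||% "unknown",
    start_time = ts[1], time = time,
    ax = dt$x * scale, ay = dt$y * scale, az = dt$z * scale,
    sample_rate = sr, allow_gaps = allow_gaps
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a hypnogram sidecar
#'
#' Two-column delimited text: 1-based `epoch` index and `stage` code in
#' `W, N1, N2, N3, REM` (plus `unscored`).
#'
#' @param hyp data.frame with columns `epoch` and `stage`.
#' @param path file path.
#' @return `write_hypnogram`: invisibly `path`; `read_hypnogram`: data.frame.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(all(c("epoch", "stage") %in% names(hyp)))
  data.table::fwrite(hyp[, c("epoch", "stage")], path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("epoch", "stage") %in% names(dt))) {
    stop_format("hypnogram needs columns epoch, stage")
  }
  ok <- c("W", "N1", "N2", "N3", "REM", "unscored")
  if (!all(dt$stage %in% ok)) {
    stop_format("unknown stage code(s): ",
                paste(unique(setdiff(dt$stage, ok)), collapse = ", "))
  }
  as.data.frame(dt)
}

#' Align a PSG hypnogram to a recording's 30-s epoch grid
#'
#' The recording's epoch grid is anchored at its first sample, with half-open
#' epochs `[start, start + epoch_length)`. If the hypnogram start is offset
#' from that grid by less than 15 s the labels snap to the nearest epoch
#' boundary (the offset is messaged); a larger offset shifts the grid to the
#' hypnogram start. Epochs outside the scored interval are `"unscored"`.
#'
#' @param recording a [raw_recording()].
#' @param hypnogram data.frame with columns `epoch` (1-based) and `stage`.
#' @param epoch_length epoch length in seconds.
#' @param hypnogram_start POSIXct start of hypnogram epoch 1; defaults to the
#'   recording start.
#' @return data.frame with columns `epoch`, `start_s` and `stage`
#'   (stage in `Wake, N1, N2, N3, REM` or `"unscored"`).
#' @export
align_hypnogram <- function(recording, hypnogram, epoch_length = 30,
                            hypnogram_start = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  n_ep <- n_epochs_of(length(recording$time), recording$sample_rate, epoch_length)
  offset <- if (is.null(hypnogram_start)) 0 else {
    as.numeric(hypnogram_start) - as.numeric(recording$start_time)
  }
  grid_start <- 0
  frac <- offset %% epoch_length
  snap <- min(frac, epoch_length - frac)
  if (snap >= 1e-9 && snap < 15) {
    message(sprintf("hypnogram offset %.1f s snapped to the epoch grid", snap))
    offset <- round(offset / epoch_length) * epoch_length
  } else if (snap >= 15) {
    message(sprintf("hypnogram offset %.1f s: shifting epoch grid to hypnogram start", frac))
    grid_start <- frac
    offset <- round((offset - frac) / epoch_length) * epoch_length + frac
  }
  starts <- grid_start + (seq_len(n_ep) - 1L) * epoch_length
  if (grid_start > 0) {
    n_ep <- sum(starts + epoch_length <= max(recording$time) + 1 / recording$sample_rate)
    starts <- starts[seq_len(n_ep)]
  }
  stage <- rep("unscored", n_ep)
  # recording epoch whose start matches hypnogram epoch j
  j0 <- round((offset - grid_start) / epoch_length)
  tgt <- j0 + hypnogram$epoch
  keep <- tgt >= 1 & tgt <= n_ep
  if (!any(keep)) stop("alignment error: hypnogram lies entirely outside the recording",
                       call. = FALSE)
  stage[tgt[keep]] <- stage_from_psg(hypnogram$stage[keep])
  data.frame(epoch = seq_len(n_ep), start_s = starts, stage = stage,
             stringsAsFactors = FALSE)
}

#' Ground-truth wear labels from the protocol interval plus a stillness rule
#'
#' Epochs inside the PSG interval are labelled wear (the device is worn during
#' the supervised recording). Outside it, non-overlapping 15-min blocks —
#' anchored at the first sample outside the interval on each side — are
#' labelled wear iff the acceleration SD of the block exceeds 13.0 mg, else
#' nonwear; every epoch in a block inherits the block label. The block SD is
#' the mean of the three per-axis sample SDs. A trailing partial block uses
#' its own SD if it spans at least 5 min, otherwise it inherits the label of
#' its neighbouring block (the PSG side counts as wear).
#'
#' @param recording a [raw_recording()].
#' @param psg_interval numeric `c(start, end)` in seconds from recording
#'   start, or POSIXct pair.
#' @param epoch_length epoch length in seconds.
#' @param sd_threshold_mg wear threshold on the block SD, in mg.
#' @return character vector `"wear"`/`"nonwear"`, one per epoch.
#' @export
label_ground_truth_wear <- function(recording, psg_interval, epoch_length = 30,
                                    sd_threshold_mg = 13.0) {
  stopifnot(inherits(recording, "raw_recording"))
  if (inherits(psg_interval, "POSIXct")) {
    psg_interval <- as.numeric(psg_interval) - as.numeric(recording$start_time)
  }
  psg <- as.numeric(psg_interval)
  if (length(psg) != 2 || psg[2] <= psg[1]) stop_config("psg_interval must be c(start, end)")
  sr <- recording$sample_rate
  n_ep <- n_epochs_of(length(recording$time), sr, epoch_length)
  ep_start <- (seq_len(n_ep) - 1L) * epoch_length
  label <- rep(NA_character_, n_ep)
  inside <- ep_start >= psg[1] & ep_start < psg[2]
  label[inside] <- "wear"

  block_sd_mg <- function(lo_s, hi_s) {
    idx <- which(recording$time >= lo_s & recording$time < hi_s)
    if (length(idx) < 2) return(NA_real_)
    1000 * mean(c(sd(recording$ax[idx]), sd(recording$ay[idx]),
                  sd(recording$az[idx])))
  }
  label_region <- function(lo_s, hi_s, anchor_at_lo) {
    # blocks anchored at the first sample outside the PSG interval
    if (hi_s - lo_s < 1e-9) return()
    bounds <- if (anchor_at_lo) seq(lo_s, hi_s, by = 900) else rev(seq(hi_s, lo_s, by = -900))
    if (bounds[length(bounds)] < hi_s - 1e-9) bounds <- c(bounds, hi_s)
    if (bounds[1] > lo_s + 1e-9) bounds <- c(lo_s, bounds)
    labs <- character(length(bounds) - 1)
    for (b in seq_along(labs)) {
      span <- bounds[b + 1] - bounds[b]
      if (span >= 300 - 1e-9) {
        s <- block_sd_mg(bounds[b], bounds[b + 1])
        labs[b] <- if (!is.na(s) && s > sd_threshold_mg) "wear" else "nonwear"
      } else {
        labs[b] <- NA_character_  # partial < 5 min: inherit neighbour
      }
    }
    for (b in seq_along(labs)) {
      if (is.na(labs[b])) {
        nb <- if (anchor_at_lo) {
          if (b > 1) labs[b - 1] else "wear"   # neighbour toward the PSG side
        } else {
          if (b < length(labs)) labs[b + 1] else "wear"
        }
        labs[b] <- nb
      }
    }
    for (b in seq_along(labs)) {
      sel <- ep_start >= bounds[b] - 1e-9 & ep_start < bounds[b + 1] - 1e-9
      label[sel] <<- labs[b]
    }
  }
  label_region(max(0, psg[2]), n_ep * epoch_length, anchor_at_lo = TRUE)
  label_region(0, min(psg[1], n_ep * epoch_length), anchor_at_lo = FALSE)
  label[is.na(label)] <- "wear"
  label
}

#' Write / read an epoch table with full numeric precision
#'
#' Numeric columns are serialized with 17 significant digits so the
#' write/read round trip is bit-exact for finite doubles. A JSON provenance
#' sidecar (`<path>.json`) can be attached via `provenance`.
#'
#' @param epochs data.frame.
#' @param path file path.
#' @param provenance optional list written as `<path>.json`.
#' @return `write_epochs`: invisibly `path`; `read_epochs`: data.frame.
#' @export
write_epochs <- function(epochs, path, provenance = NULL) {
  out <- epochs
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  data.table::fwrite(out, path, quote = TRUE)
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}

#' Read a sleep log of per-night sleep-period windows
#'
#' Delimited text with columns `onset` and `offset` (ISO-8601 date-times);
#' each row is one night's sleep-period time window. Offsets may cross
#' midnight (offset simply follows onset).
#'
#' @param path file path.
#' @return data.frame with POSIXct columns `onset`, `offset`.
#' @export
read_sleep_log <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("onset", "offset") %in% names(dt))) {
    stop_format("sleep log needs columns onset, offset")
  }
  onset <- as.POSIXct(dt$onset, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  offset <- as.POSIXct(dt$offset, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(onset) || anyNA(offset)) stop_format("unparseable sleep-log timestamp")
  if (any(offset <= onset)) stop_format("sleep-log offset must follow onset")
  data.frame(onset = onset, offset = offset)
}
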