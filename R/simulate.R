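#' Simulation configuration for synthetic wrist recordings
#'
#' Describes a labelled synthetic recording: a 30-s Markov chain over the six
#' states Wake, N1, N2, N3, REM and Nonwear, a per-state movement model
#' (Poisson-style movement bursts, posture changes re-orienting the gravity
#' vector), and additive sensor noise. The defaults emulate the structure
#' wrist-worn classifiers exploit: wakefulness shows frequent movement and
#' re-orientation, sleep stages show progressively less movement from N1 to
#' N3, REM shows occasional twitch-like bursts despite atonia, and nonwear is
#' a fixed orientation plus low sensor noise (its 15-min acceleration SD stays
#' well below the 13 mg wear threshold so ground-truth labelling is
#' self-consistent).
#'
#' @param duration_hours recording length in hours (> 0).
#' @param sample_rate sampling frequency in Hz (>= 10).
#' @param stage_transition_matrix 6x6 row-stochastic matrix over
#'   `c("Wake","N1","N2","N3","REM","Nonwear")` at 30-s resolution. Rows must
#'   sum to 1 within 1e-9. The default is heavily diagonal: transitions
#'   between sleep states are rare compared to remaining in the same state.
#' @param movement_params data.frame with one row per state and columns
#'   `burst_prob` (probability an epoch contains a movement burst),
#'   `burst_amp` (burst amplitude in g) and `posture_prob` (probability the
#'   gravity orientation is redrawn at the epoch start).
#' @param noise_sd per-axis sensor noise SD in g for worn states.
#' @param nonwear_noise_sd per-axis noise SD in g during nonwear; must keep
#'   the per-15-min acceleration SD below 13 mg (validated).
#' @param initial_state state of the first epoch.
#' @param start_time POSIXct start of the recording.
#' @param seed integer seed; the same seed gives a bit-identical recording.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration_hours = 8,
                       sample_rate = 25,
                       stage_transition_matrix = default_transition_matrix(),
                       movement_params = default_movement_params(),
                       noise_sd = 0.010,
                       nonwear_noise_sd = 0.002,
                       initial_state = "Wake",
                       start_time = as.POSIXct("2024-03-01 21:00:00", tz = "UTC"),
                       seed = 1L) {
  if (!is.numeric(duration_hours) || duration_hours <= 0) {
    stop_config("duration_hours must be > 0")
  }
  if (sample_rate < 10) stop_config("sample_rate must be >= 10 Hz")
  P <- as.matrix(stage_transition_matrix)
  if (!all(dim(P) == c(6L, 6L))) stop_config("transition matrix must be 6x6")
  if (is.null(rownames(P))) rownames(P) <- colnames(P) <- sim_states()
  if (!identical(rownames(P), sim_states())) {
    P <- P[sim_states(), sim_states()]
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop_config("transition matrix rows must be non-negative and sum to 1")
  }
  mp <- as.data.frame(movement_params)
  need <- c("burst_prob", "burst_amp", "posture_prob")
  if (!all(need %in% names(mp)) || !all(sim_states() %in% rownames(mp))) {
    stop_config("movement_params needs rows for all six states and columns ",
                paste(need, collapse = ", "))
  }
  if (nonwear_noise_sd >= 0.013) {
    stop_config("nonwear_noise_sd must keep the 15-min acceleration SD below 13 mg")
  }
  if (!initial_state %in% sim_states()) stop_config("unknown initial_state")
  structure(
    list(duration_hours = duration_hours, sample_rate = sample_rate,
         stage_transition_matrix = P, movement_params = mp[sim_states(), need],
         noise_sd = noise_sd, nonwear_noise_sd = nonwear_noise_sd,
         initial_state = initial_state, start_time = start_time,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Canonical simulation state order
#' @return character vector of the six states.
#' @export
sim_states <- function() c("Wake", "N1", "N2", "N3", "REM", "Nonwear")

#' Default 30-s stage transition matrix
#'
#' Heavily diagonal (all self-transitions >= 0.8; nonwear 0.98 so removal
#' episodes form contiguous blocks with a mean dwell of 25 min).
#' @return 6x6 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  s <- sim_states()
  P <- matrix(0, 6, 6, dimnames = list(s, s))
  P["Wake", ]    <- c(0.90, 0.06, 0.02, 0.00, 0.00, 0.02)
  P["N1", ]      <- c(0.05, 0.80, 0.14, 0.00, 0.01, 0.00)
  P["N2", ]      <- c(0.02, 0.03, 0.87, 0.05, 0.03, 0.00)
  P["N3", ]      <- c(0.01, 0.00, 0.09, 0.89, 0.01, 0.00)
  P["REM", ]     <- c(0.03, 0.02, 0.05, 0.00, 0.90, 0.00)
  P["Nonwear", ] <- c(0.02, 0.00, 0.00, 0.00, 0.00, 0.98)
  P
}

#' Default per-state movement parameters
#'
#' Burst probability and amplitude decrease from Wake to N3; REM sits between
#' the light-sleep stages and wake (twitches). Posture-change rates decrease
#' in the same order. Nonwear has no movement at all.
#' @return data.frame with rows in [sim_states()] order.
#' @export
default_movement_params <- function() {
  data.frame(
    burst_prob   = c(0.90, 0.15, 0.10, 0.02, 0.25, 0.00),
    burst_amp    = c(0.15, 0.04, 0.03, 0.015, 0.05, 0.00),
    posture_prob = c(0.30, 0.05, 0.03, 0.01, 0.02, 0.00),
    row.names = sim_states()
  )
}

#' Simulate a stage sequence from the 30-s Markov chain
#'
#' @param n_epochs number of 30-s epochs.
#' @param transition_matrix 6x6 row-stochastic matrix in [sim_states()] order.
#' @param initial_state starting state.
#' @param seed integer seed.
#' @return character vector of states, length `n_epochs`.
#' @export
simulate_stage_sequence <- function(n_epochs, transition_matrix,
                                    initial_state = "Wake", seed = 1L) {
  P <- as.matrix(transition_matrix)
  if (any(abs(rowSums(P) - 1) > 1e-9) || any(P < 0)) {
    stop_config("transition matrix rows must be non-negative and sum to 1")
  }
  s <- sim_states()
  out <- character(n_epochs)
  with_seed(seed, {
    cur <- match(initial_state, s)
    u <- runif(n_epochs)
    cp <- t(apply(P, 1, cumsum))
    for (i in seq_len(n_epochs)) {
      out[i] <- s[cur]
      cur <- which(u[i] <= cp[cur, ])[1]
    }
  })
  out
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate one labelled wrist-accelerometer recording
#'
#' Draws a stage sequence from the configured Markov chain, then renders raw
#' tri-axial acceleration per 30-s epoch: a (piecewise-constant) gravity unit
#' vector, redrawn at posture changes; an optional within-epoch movement burst
#' (band-limited sinusoid, 0.5-2.5 Hz, independent phase per axis); and white
#' sensor noise. During stillness the vector norm is approximately 1 g, and
#' nonwear epochs are near-still by construction.
#'
#' @param config a [sim_config()].
#' @param participant_id identifier stored on the recording.
#' @return an object of class `sim_recording`: a list with elements `raw`
#'   (a [raw_recording()]), `stages` (true stage per epoch),
#'   `wear` (`"wear"`/`"nonwear"` per epoch), and `spt` (start/end of the
#'   sleep period window, in seconds from recording start; `NA` if no sleep).
#' @export
simulate_recording <- function(config, participant_id = "P01") {
  stopifnot(inherits(config, "sim_config"))
  sr <- config$sample_rate
  n_ep <- floor(config$duration_hours * 120)
  if (n_ep < 1) stop_config("duration too short for a single 30-s epoch")
  spe <- sr * 30L                       # samples per epoch
  n <- n_ep * spe
  mp <- config$movement_params

  stages <- simulate_stage_sequence(n_ep, config$stage_transition_matrix,
                                    config$initial_state, seed = config$seed)
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  tt <- seq(0, 30, length.out = spe + 1L)[-(spe + 1L)]  # within-epoch seconds

  with_seed(derive_seed(config$seed, 1L), {
    grav <- c(0, 0, 1)
    wear_grav <- random_unit_vector()
    grav <- wear_grav
    for (i in seq_len(n_ep)) {
      st <- stages[i]
      p <- mp[st, ]
      if (runif(1) < p$posture_prob) grav <- random_unit_vector()
      sig <- matrix(rep(grav, each = spe), spe, 3)
      if (p$burst_prob > 0 && runif(1) < p$burst_prob) {
        f <- runif(1, 0.5, 2.5)
        ph <- runif(3, 0, 2 * pi)
        for (axis in 1:3) {
          sig[, axis] <- sig[, axis] + p$burst_amp * sin(2 * pi * f * tt + ph[axis])
        }
      }
      nsd <- if (st == "Nonwear") config$nonwear_noise_sd else config$noise_sd
      sig <- sig + matrix(rnorm(spe * 3, sd = nsd), spe, 3)
      idx <- ((i - 1L) * spe + 1L):(i * spe)
      ax[idx] <- sig[, 1]; ay[idx] <- sig[, 2]; az[idx] <- sig[, 3]
    }
  })

  raw <- raw_recording(participant_id = participant_id,
                       start_time = config$start_time,
                       time = (seq_len(n) - 1L) / sr,
                       ax = ax, ay = ay, az = az, sample_rate = sr)
  sleep_ep <- which(stages %in% c("N1", "N2", "N3", "REM"))
  spt <- if (length(sleep_ep)) {
    c(start = (min(sleep_ep) - 1) * 30, end = max(sleep_ep) * 30)
  } else {
    c(start = NA_real_, end = NA_real_)
  }
  structure(
    list(raw = raw, stages = stages,
         wear = ifelse(stages == "Nonwear", "nonwear", "wear"),
         spt = spt, config = config),
    class = "sim_recording"
  )
}

#' Simulate a cohort of labelled recordings
#'
#' Participant seeds are derived deterministically from the master seed, so a
#' fixed master seed reproduces the whole cohort.
#'
#' @param n_participants number of recordings (>= 2; grouped cross-validation
#'   needs at least two participants).
#' @param config template [sim_config()]; each participant gets a derived seed.
#' @param seed master integer seed.
#' @return list of `sim_recording`, named by participant id.
#' @export
simulate_cohort <- function(n_participants, config = sim_config(), seed = 1L) {
  if (n_participants < 2) {
    stop_config("need at least 2 participants for grouped cross-validation")
  }
  ids <- sprintf("P%02d", seq_len(n_participants))
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 100L + i)
    out[[i]] <- simulate_recording(cfg, participant_id = ids[i])
  }
  names(out) <- ids
  out
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf("<sim_recording> %s: %d epochs (%.1f h) at %g Hz\n",
              x$raw$participant_id, length(x$stages),
              length(x$stages) / 120, x$raw$sample_rate))
  print(table(stage = x$stages))
  invisible(x)
}

#' Write a simulated recording to a directory
#'
#' Writes the raw delimited-text recording plus hypnogram and wear sidecars
#' and a provenance JSON (configuration, seed, package version).
#'
#' @param sim a `sim_recording`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_recording <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sim$raw$participant_id
  paths <- c(
    raw = file.path(dir, paste0(id, "_raw.csv")),
    hypnogram = file.path(dir, paste0(id, "_hypnogram.csv")),
    wear = file.path(dir, paste0(id, "_wear.csv")),
    provenance = file.path(dir, paste0(id, "_provenance.json"))
  )
  write_raw(sim$raw, paths["raw"])
  write_hypnogram(data.frame(epoch = seq_along(sim$stages),
                             stage = psg_code(sim$stages)),
                  paths["hypnogram"])
  data.table::fwrite(data.frame(epoch = seq_along(sim$wear), wear = sim$wear),
                     paths["wear"])
  cfg <- sim$config
  prov <- list(
    participant_id = id,
    seed = cfg$seed,
    duration_hours = cfg$duration_hours,
    sample_rate = cfg$sample_rate,
    noise_sd = cfg$noise_sd,
    nonwear_noise_sd = cfg$nonwear_noise_sd,
    stage_transition_matrix = cfg$stage_transition_matrix,
    movement_params = cfg$movement_params,
    spt = as.list(sim$spt),
    package_version = as.character(utils::packageVersion("actisleep"))
  )
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# Simulation states use AASM-style codes already, except Wake which is "W"
# in hypnogram files.
psg_code <- function(stages) ifelse(stages == "Wake", "W", stages)
stage_from_psg <- function(codes) ifelse(codes == "W", "Wake", codes)
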