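# Shared fixtures, memoised so the expensive cohort/training steps run once
# per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# constant-orientation recording with optional noise; seconds long at sr Hz
constant_recording <- function(gx, gy, gz, seconds = 60, sr = 25,
                               noise_sd = 0, seed = 1, id = "C01") {
  n <- seconds * sr
  set.seed(seed)
  raw_recording(
    participant_id = id,
    start_time = as.POSIXct("2024-03-01 12:00:00", tz = "UTC"),
    time = (seq_len(n) - 1) / sr,
    ax = gx + rnorm(n, sd = noise_sd),
    ay = gy + rnorm(n, sd = noise_sd),
    az = gz + rnorm(n, sd = noise_sd),
    sample_rate = sr
  )
}

# a perfectly still recording: zero-noise gravity orientation -> ENMO == 0
still_recording <- function(seconds = 1800, sr = 25) {
  constant_recording(0, 0, 1, seconds = seconds, sr = sr)
}

# a fake derived_signals object with controlled per-sample / per-epoch series
fake_signals <- function(enmo, sr = 25, epoch_length = 30,
                         z_angle = NULL, lids = NULL) {
  n_ep <- floor(length(enmo) / (sr * epoch_length))
  if (is.null(z_angle)) z_angle <- rep(0, n_ep * epoch_length / 5)
  if (is.null(lids)) lids <- rep(100, n_ep)
  structure(
    list(enmo = enmo, z_angle = z_angle, lids = lids,
         activity_count = rep(0, n_ep), sample_rate = sr,
         epoch_length = epoch_length, n_epochs = n_ep, participant_id = "F01"),
    class = "derived_signals"
  )
}

# --- the study-condition cohort: 10 participants x 2 h at 25 Hz ------------

test_cohort <- function() {
  memo("cohort", simulate_cohort(10, sim_config(duration_hours = 2), seed = 42))
}

test_epoch_data <- function() {
  memo("epoch_data", cohort_epoch_data(test_cohort()))
}

test_train_config <- function() {
  training_config(search_draws = 4, inner_folds = 3, seed = 5)
}

sleepwake_fit <- function() {
  memo("sleepwake_fit", {
    ed <- test_epoch_data()
    x <- epoch_features_matrix(ed)
    w <- !is.na(ed$sleepwake)
    nested_cv_train(x[w, , drop = FALSE], ed$sleepwake[w], ed$participant[w],
                    test_train_config(), task = "sleepwake")
  })
}

nonwear_fit <- function() {
  memo("nonwear_fit", {
    ed <- test_epoch_data()
    nested_cv_train(epoch_features_matrix(ed), ed$wear, ed$participant,
                    test_train_config(), task = "nonwear")
  })
}

# per-epoch vanHees labels for the wear rows of the cohort, pooled in the
# same row order as the sleep-wake task
vanhees_on_cohort <- function() {
  memo("vanhees_labels", {
    ed <- test_epoch_data()
    labs <- unlist(lapply(test_cohort(), function(sim) {
      as.character(vanhees_classify(compute_z_angle(sim$raw)))
    }), use.names = FALSE)
    labs[!is.na(ed$sleepwake)]
  })
}

hierarchy_fit <- function() {
  memo("hierarchy_fit", {
    ed <- test_epoch_data()
    train_hierarchy(epoch_features_matrix(ed), ed$stage, ed$participant,
                    config = training_config(search_draws = 2, inner_folds = 2,
                                             outer_folds = 3, seed = 9))
  })
}

# an unseen cohort for held-out hierarchy evaluation
heldout_epoch_data <- function() {
  memo("heldout_epoch_data", {
    cohort_epoch_data(simulate_cohort(4, sim_config(duration_hours = 2),
                                      seed = 777))
  })
}
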