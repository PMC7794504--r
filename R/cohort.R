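#' Feature matrix for a single recording
#'
#' Convenience wrapper: derived signals then [extract_features()].
#'
#' @param recording a [raw_recording()].
#' @param spec a [feature_spec()].
#' @return data.frame with `epoch` plus the feature columns.
#' @export
recording_features <- function(recording, spec = feature_spec()) {
  extract_features(compute_derived_signals(recording), spec)
}

#' Assemble the epoch table for a simulated cohort
#'
#' Stacks per-participant feature matrices with the true stage, sleep-wake
#' and wear labels, ordered by participant then epoch — the layout
#' [nested_cv_train()] expects.
#'
#' @param cohort list of `sim_recording` from [simulate_cohort()].
#' @param spec a [feature_spec()].
#' @return data.frame with columns `participant`, `epoch`, `stage`,
#'   `sleepwake` (`sleep`/`wake`, `NA` for nonwear epochs), `wear`
#'   (`wear`/`nonwear`) and the feature columns.
#' @export
cohort_epoch_data <- function(cohort, spec = feature_spec()) {
  parts <- lapply(cohort, function(sim) {
    feats <- recording_features(sim$raw, spec)
    n <- nrow(feats)
    stage <- sim$stages[seq_len(n)]
    data.frame(
      participant = sim$raw$participant_id,
      epoch = feats$epoch,
      stage = stage,
      sleepwake = ifelse(stage == "Nonwear", NA_character_,
                         ifelse(stage == "Wake", "wake", "sleep")),
      wear = sim$wear[seq_len(n)],
      feats[, setdiff(names(feats), "epoch"), drop = FALSE],
      check.names = FALSE
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Split an epoch table into features and metadata
#' @param epoch_data a [cohort_epoch_data()] result.
#' @param spec the [feature_spec()] used to build it.
#' @return list with `x` (feature matrix), and the metadata columns.
#' @export
epoch_features_matrix <- function(epoch_data, spec = feature_spec()) {
  cols <- feature_columns(spec)
  missing <- setdiff(cols, names(epoch_data))
  if (length(missing)) {
    stop("epoch table lacks feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(epoch_data[, cols])
}
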