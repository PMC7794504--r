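#' Combine sleep-wake and wear-nonwear ensembles on free-living data
#'
#' An epoch is Nonwear whenever the nonwear ensemble says so (a removed
#' device cannot witness sleep, so nonwear takes precedence); otherwise the
#' sleep-wake ensemble's label is used. Both ensembles must share the feature
#' spec.
#'
#' @param sleepwake_ensemble,nonwear_ensemble [nested_cv_train()] results.
#'   The nonwear ensemble's classes must include `"nonwear"`; the sleep-wake
#'   ensemble's `"sleep"`/`"wake"`.
#' @param features feature matrix with the common training columns.
#' @param participants optional participant id per row.
#' @return factor per epoch with levels `Nonwear`, `Sleep`, `Wake`.
#' @export
classify_free_living <- function(sleepwake_ensemble, nonwear_ensemble,
                                 features, participants = NULL) {
  if (!identical(sleepwake_ensemble$feature_columns,
                 nonwear_ensemble$feature_columns)) {
    stop("ensembles were trained on different feature specs", call. = FALSE)
  }
  nw <- ensemble_predict(nonwear_ensemble, features, participants)$labels
  sw <- ensemble_predict(sleepwake_ensemble, features, participants)$labels
  out <- ifelse(nw == "nonwear", "Nonwear",
                ifelse(sw == "sleep", "Sleep", "Wake"))
  factor(out, levels = c("Nonwear", "Sleep", "Wake"))
}

#' Detect daytime nap episodes
#'
#' Maximal runs of Sleep epochs lying wholly outside every sleep-period time
#' window and lasting at least `min_duration_min` minutes are nap episodes.
#' A run interrupted by a single non-sleep epoch is split (no gap merging).
#' Total weekly nap minutes are normalized to a 7-day equivalent when the
#' recording does not span exactly 7 days.
#'
#' @param labels per-epoch labels containing `"Sleep"` (e.g. from
#'   [classify_free_living()]).
#' @param spt_windows data.frame with numeric columns `start`, `end` — the
#'   sleep-period time windows in seconds from recording start (one row per
#'   night). An empty data.frame means no SPT exclusion.
#' @param min_duration_min minimum episode duration in minutes.
#' @param epoch_length epoch length in seconds.
#' @return object of class `nap_report`: `episodes` (start_s, end_s,
#'   duration_min), `total_min`, `weekly_min`, `recorded_days`.
#' @export
detect_naps <- function(labels, spt_windows = data.frame(start = numeric(0),
                                                         end = numeric(0)),
                        min_duration_min = 15, epoch_length = 30) {
  labels <- as.character(labels)
  n <- length(labels)
  if (nrow(spt_windows) && any(spt_windows$end <= spt_windows$start)) {
    stop_config("SPT window end must follow start")
  }
  ep_start <- (seq_len(n) - 1) * epoch_length
  ep_end <- ep_start + epoch_length
  in_spt <- rep(FALSE, n)
  for (w in seq_len(nrow(spt_windows))) {
    in_spt <- in_spt | (ep_start < spt_windows$end[w] &
                          ep_end > spt_windows$start[w])
  }
  r <- rle(labels == "Sleep")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  eps <- list()
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    idx <- starts[j]:ends[j]
    dur_min <- length(idx) * epoch_length / 60
    if (any(in_spt[idx])) next      # must lie wholly outside the SPT window
    if (dur_min < min_duration_min) next
    eps[[length(eps) + 1L]] <- data.frame(
      start_s = ep_start[idx[1]], end_s = ep_end[idx[length(idx)]],
      duration_min = dur_min
    )
  }
  episodes <- if (length(eps)) do.call(rbind, eps) else {
    data.frame(start_s = numeric(0), end_s = numeric(0),
               duration_min = numeric(0))
  }
  recorded_days <- n * epoch_length / 86400
  total_min <- sum(episodes$duration_min)
  structure(
    list(episodes = episodes, total_min = total_min,
         weekly_min = if (recorded_days > 0) total_min * 7 / recorded_days else 0,
         recorded_days = recorded_days),
    class = "nap_report"
  )
}

#' @export
print.nap_report <- function(x, ...) {
  cat(sprintf("<nap_report> %d nap episode(s), %.1f min total (%.1f min/week over %.2f days)\n",
              nrow(x$episodes), x$total_min, x$weekly_min, x$recorded_days))
  if (nrow(x$episodes)) print(x$episodes, row.names = FALSE)
  invisible(x)
}

#' Compare accelerometer nap estimates with self-report
#'
#' Paired t-test on the differences plus Pearson correlation between the
#' weekly accelerometer-based nap minutes and diary minutes. With zero
#' variance in either array the correlation is reported as `NA`.
#'
#' @param estimate weekly nap minutes from the classifier, one per
#'   participant.
#' @param diary self-reported weekly nap minutes, paired with `estimate`.
#' @return list with `mean_difference` (diary minus estimate), `t`, `p`, `r`,
#'   `r_p`, `n`, and the paired `data` for plotting.
#' @export
compare_self_report <- function(estimate, diary) {
  if (length(estimate) != length(diary)) stop("paired arrays required", call. = FALSE)
  n <- length(estimate)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- diary - estimate
  if (sd(d) == 0) {
    # constant differences: the t statistic is undefined (0/0 when all zero)
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- t.test(diary, estimate, paired = TRUE)
  }
  if (sd(estimate) == 0 || sd(diary) == 0) {
    r <- NA_real_; r_p <- NA_real_
    warning("zero variance; correlation undefined")
  } else {
    ct <- cor.test(estimate, diary, method = "pearson")
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  list(mean_difference = mean(d), t = unname(tt$statistic),
       p = tt$p.value, r = r, r_p = r_p, n = n,
       data = data.frame(estimate = estimate, diary = diary))
}
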