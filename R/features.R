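#' Feature specification: statistical measures x derived signals
#'
#' The full set is 13 measures applied to each of the three derived signals
#' (39 columns): mean, std, min, max, median absolute deviation, Shannon
#' entropy of the 20- and 200-bin within-epoch histogram, and the
#' previous/next mean-difference features at 30, 60 and 120 s. The
#' `"paper36"` preset drops `next120diff`, giving 12 measures x 3 signals =
#' 36 columns.
#'
#' @param preset `"full39"` (default) or `"paper36"`.
#' @param measures,signals optional explicit subsets (override the preset).
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(preset = c("full39", "paper36"),
                         measures = NULL, signals = NULL) {
  preset <- match.arg(preset)
  all_measures <- c("mean", "std", "min", "max", "mad", "entropy20",
                    "entropy200", "prev30diff", "next30diff", "prev60diff",
                    "next60diff", "prev120diff", "next120diff")
  if (is.null(measures)) {
    measures <- if (preset == "paper36") setdiff(all_measures, "next120diff")
                else all_measures
  }
  if (is.null(signals)) signals <- c("enmo", "z_angle", "lids")
  if (anyDuplicated(measures) || anyDuplicated(signals)) {
    stop_config("measures and signals must be unique")
  }
  if (!all(measures %in% all_measures)) {
    stop_config("unknown measure(s): ",
                paste(setdiff(measures, all_measures), collapse = ", "))
  }
  if (!all(signals %in% c("enmo", "z_angle", "lids"))) {
    stop_config("unknown signal(s)")
  }
  structure(list(preset = preset, measures = measures, signals = signals),
            class = "feature_spec")
}

# Within-epoch value matrix (values x epochs) for one signal.
# enmo: raw samples; z_angle: the six 5-s cells; lids: the five consecutive
# smoothed per-epoch values centred on the target epoch (edges shrink), so
# its spread measures capture the local trend.
epoch_values <- function(signals, signal) {
  n_ep <- signals$n_epochs
  switch(signal,
    enmo = {
      spe <- as.integer(signals$sample_rate * signals$epoch_length)
      matrix(signals$enmo[seq_len(n_ep * spe)], spe, n_ep)
    },
    z_angle = {
      cpe <- as.integer(signals$epoch_length / 5)
      matrix(signals$z_angle[seq_len(n_ep * cpe)], cpe, n_ep)
    },
    lids = {
      idx <- vapply(seq_len(n_ep), function(i) {
        w <- max(1L, i - 2L):min(n_ep, i + 2L)
        c(w, rep(NA_integer_, 5L - length(w)))
      }, integer(5))
      m <- matrix(signals$lids[idx], 5L, n_ep)
      m
    }
  )
}

col_stat <- function(m, fun) {
  if (anyNA(m)) {
    apply(m, 2, function(v) fun(v[!is.na(v)]))
  } else {
    apply(m, 2, fun)
  }
}

diff_features <- function(ep_mean, k, n_ep) {
  prev <- numeric(n_ep)
  nxt <- numeric(n_ep)
  for (i in seq_len(n_ep)) {
    if (i - k >= 1) prev[i] <- ep_mean[i] - mean(ep_mean[(i - k):(i - 1)])
    if (i + k <= n_ep) nxt[i] <- mean(ep_mean[(i + 1):(i + k)]) - ep_mean[i]
  }
  list(prev = prev, nxt = nxt)
}

#' Extract the per-epoch feature matrix
#'
#' For each epoch and signal the within-epoch distribution (raw samples for
#' ENMO, the six 5-s cells for z-angle, the five surrounding smoothed values
#' for LIDS) is summarized by the measures in the spec. Difference features
#' compare the epoch mean with the mean over the preceding/following K
#' seconds: `prevKdiff = mean(current) - mean(previous K s)` and
#' `nextKdiff = mean(next K s) - mean(current)`. Edge epochs lacking the full
#' K-second context get 0 (no change), keeping the matrix dense.
#'
#' @param signals a [compute_derived_signals()] result.
#' @param spec a [feature_spec()].
#' @return data.frame with column `epoch` plus one `<signal>_<measure>`
#'   column per spec entry; no missing values.
#' @export
extract_features <- function(signals, spec = feature_spec()) {
  stopifnot(inherits(signals, "derived_signals"), inherits(spec, "feature_spec"))
  n_ep <- signals$n_epochs
  if (n_ep < 1) stop("epoch grid is empty: recording shorter than one epoch",
                     call. = FALSE)
  out <- list(epoch = seq_len(n_ep))
  for (sig in spec$signals) {
    m <- epoch_values(signals, sig)
    if (any(colSums(!is.na(m)) == 0)) {
      stop("epoch with zero samples: epoch grid construction bug", call. = FALSE)
    }
    ep_mean <- col_stat(m, mean)
    basics <- list(
      mean = ep_mean,
      std = col_stat(m, sd),
      min = col_stat(m, min),
      max = col_stat(m, max),
      mad = col_stat(m, function(v) mad(v, constant = 1)),
      entropy20 = col_stat(m, function(v) bin_entropy(v, 20L)),
      entropy200 = col_stat(m, function(v) bin_entropy(v, 200L))
    )
    for (K in c(30, 60, 120)) {
      k <- as.integer(K / signals$epoch_length)
      d <- diff_features(ep_mean, k, n_ep)
      basics[[sprintf("prev%ddiff", K)]] <- d$prev
      basics[[sprintf("next%ddiff", K)]] <- d$nxt
    }
    for (meas in spec$measures) {
      out[[paste(sig, meas, sep = "_")]] <- basics[[meas]]
    }
  }
  df <- as.data.frame(out)
  # single-value distributions have sd NA under the sample convention
  df[is.na(df)] <- 0
  df
}

#' Column names of the feature matrix for a spec
#' @param spec a [feature_spec()].
#' @return character vector of `<signal>_<measure>` names.
#' @export
feature_columns <- function(spec = feature_spec()) {
  as.vector(t(outer(spec$signals, spec$measures, paste, sep = "_")))
}

#' Zero-mean / unit-SD normalization fitted on training rows
#'
#' Uses the population SD convention (denominator n). Constant columns get
#' scale 1 and so map to zero. When `stats` is supplied the stored statistics
#' are applied to new rows (column sets must match exactly).
#'
#' @param x numeric matrix or data.frame of feature columns.
#' @param stats optional statistics from a previous fit.
#' @return list with `x` (normalized matrix), `center`, `scale`; class
#'   `feature_normalizer`.
#' @export
normalize_features <- function(x, stats = NULL) {
  xm <- as.matrix(x)
  if (is.null(stats)) {
    center <- colMeans(xm)
    centered <- sweep(xm, 2, center)
    scale <- sqrt(colMeans(centered^2))
    scale[scale == 0] <- 1
  } else {
    if (!identical(colnames(xm), names(stats$center))) {
      stop("normalization statistics do not match the feature columns",
           call. = FALSE)
    }
    center <- stats$center
    scale <- stats$scale
    centered <- sweep(xm, 2, center)
  }
  structure(list(x = sweep(centered, 2, scale, "/"),
                 center = center, scale = scale),
            class = "feature_normalizer")
}

#' Invert a normalization
#' @param norm a `feature_normalizer`.
#' @param x normalized matrix (defaults to `norm$x`).
#' @return matrix on the original scale.
#' @export
denormalize_features <- function(norm, x = norm$x) {
  sweep(sweep(as.matrix(x), 2, norm$scale, "*"), 2, norm$center, "+")
}
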