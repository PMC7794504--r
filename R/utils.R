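#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so package functions are deterministic without
#' clobbering the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic, collision-poor mapping kept strictly below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param index positive integer stream index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %%
    (.Machine$integer.max - 1)) + 1L
}

#' Centred rolling sum or mean with shrinking edge windows
#'
#' For window width `w` the window at position i covers
#' `[i - floor(w/2), i + w - 1 - floor(w/2)]`, clipped to the series; edges
#' therefore use the available (shrunken) window rather than padding.
#'
#' @param x numeric vector.
#' @param width window width in elements.
#' @param op `"sum"` or `"mean"`.
#' @return numeric vector of `length(x)`.
#' @keywords internal
roll_center <- function(x, width, op = c("sum", "mean")) {
  op <- match.arg(op)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  width <- as.integer(width)
  left <- width %/% 2L
  right <- width - 1L - left
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  cs <- cumsum(c(0, x))
  s <- cs[hi + 1L] - cs[lo]
  if (op == "mean") s / (hi - lo + 1L) else s
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)
stop_format <- function(...) stop("format error: ", ..., call. = FALSE)

#' Number of whole 30-s epochs in a sample series
#' @keywords internal
n_epochs_of <- function(n_samples, sample_rate, epoch_length = 30) {
  floor(n_samples / (sample_rate * epoch_length))
}

#' Shannon entropy of an equal-width histogram over the vector's own range
#'
#' Natural-log entropy; a constant vector (degenerate range) has entropy 0.
#' @keywords internal
bin_entropy <- function(x, bins) {
  mn <- min(x)
  mx <- max(x)
  if (mx <= mn) return(0)
  idx <- pmin(bins, 1L + floor((x - mn) / (mx - mn) * bins))
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}
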