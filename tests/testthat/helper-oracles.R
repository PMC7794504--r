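# Independent naive recomputations used as oracles. These deliberately share
# no code with the package implementation: plain loops and textbook formulas.

# within-epoch values for one signal, recomputed by direct indexing
oracle_epoch_values <- function(signals, signal, i) {
  if (signal == "enmo") {
    spe <- signals$sample_rate * signals$epoch_length
    signals$enmo[((i - 1) * spe + 1):(i * spe)]
  } else if (signal == "z_angle") {
    cpe <- signals$epoch_length / 5
    signals$z_angle[((i - 1) * cpe + 1):(i * cpe)]
  } else {
    w <- max(1, i - 2):min(signals$n_epochs, i + 2)
    signals$lids[w]
  }
}

oracle_entropy <- function(v, bins) {
  if (max(v) == min(v)) return(0)
  breaks <- seq(min(v), max(v), length.out = bins + 1)
  h <- numeric(bins)
  for (val in v) {
    b <- findInterval(val, breaks, rightmost.closed = TRUE)
    h[b] <- h[b] + 1
  }
  p <- h[h > 0] / length(v)
  -sum(p * log(p))
}

oracle_feature <- function(signals, signal, measure, i) {
  v <- oracle_epoch_values(signals, signal, i)
  ep_mean <- function(j) mean(oracle_epoch_values(signals, signal, j))
  if (measure %in% c("mean", "std", "min", "max", "mad", "entropy20",
                     "entropy200")) {
    return(switch(measure,
      mean = mean(v), std = sd(v), min = min(v), max = max(v),
      mad = median(abs(v - median(v))),
      entropy20 = oracle_entropy(v, 20),
      entropy200 = oracle_entropy(v, 200)
    ))
  }
  K <- as.integer(sub("^(prev|next)([0-9]+)diff$", "\\2", measure))
  k <- K / signals$epoch_length
  if (startsWith(measure, "prev")) {
    if (i - k < 1) return(0)
    mean(sapply((i - k):(i - 1), ep_mean)) * -1 + ep_mean(i)
  } else {
    if (i + k > signals$n_epochs) return(0)
    mean(sapply((i + 1):(i + k), ep_mean)) - ep_mean(i)
  }
}

# brute-force average precision: iterate explicit thresholds
oracle_average_precision <- function(truth, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    sel <- scores >= t
    precision <- sum(truth & sel) / sum(sel)
    recall <- sum(truth & sel) / sum(truth)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# ancestor closure by explicit tree walk on the default hierarchy
oracle_closure <- function(label) {
  parent <- c(Nonwear = "Root", Wear = "Root", Wake = "Wear", Sleep = "Wear",
              NREM = "Sleep", REM = "Sleep", "N1+N2" = "NREM", N3 = "NREM",
              N1 = "N1+N2", N2 = "N1+N2")
  out <- character(0)
  cur <- label
  while (cur != "Root") {
    out <- c(out, cur)
    cur <- parent[[cur]]
  }
  out
}
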