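#' Per-class and macro-averaged F1
#'
#' One-vs-rest precision, recall and F1 per class; the macro score is the
#' unweighted mean over classes so all classes count equally regardless of
#' prevalence. Classes absent from both truth and prediction are excluded.
#' A class with an undefined precision or recall (zero denominator) gets
#' F1 = 0 with a warning.
#'
#' @param truth,predicted vectors of class labels, equal length.
#' @return list with `per_class` (data.frame class/precision/recall/f1/
#'   support) and `macro_f1`.
#' @export
macro_f1 <- function(truth, predicted) {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted)) stop("length mismatch", call. = FALSE)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- sort(unique(c(truth, predicted)))
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (is.na(p) || is.na(r) || p + r == 0) {
      warning("zero precision/recall denominator for class '", cl,
              "'; F1 set to 0")
      0
    } else 2 * p * r / (p + r)
    data.frame(class = cl, precision = p, recall = r, f1 = f1,
               support = tp + fn, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, macro_f1 = mean(per_class$f1))
}

#' Average precision: area under the precision-recall curve
#'
#' Step-wise `AP = sum_k (R_k - R_{k-1}) * P_k` over the score-sorted sweep,
#' with tied scores grouped into a single operating point.
#'
#' @param truth binary labels (logical, or values matched against `positive`).
#' @param scores numeric scores, higher meaning more positive.
#' @param positive the label counted as positive when `truth` is not logical.
#' @return the average precision in `[0, 1]`.
#' @export
average_precision <- function(truth, scores, positive = NULL) {
  if (!is.logical(truth)) {
    if (is.null(positive)) stop("supply `positive` for non-logical truth",
                                call. = FALSE)
    truth <- truth == positive
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(truth)
  if (n_pos == 0 || n_pos == length(truth)) {
    stop("average precision undefined for single-class truth", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  np <- grp_end
  precision <- tp / np
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Macro average precision over one-vs-rest sweeps
#'
#' @param truth class labels.
#' @param probs matrix of class probabilities with named columns.
#' @return unweighted mean of per-class one-vs-rest APs (classes present in
#'   truth only).
#' @export
macro_average_precision <- function(truth, probs) {
  classes <- intersect(colnames(probs), unique(as.character(truth)))
  aps <- vapply(classes, function(cl) {
    y <- as.character(truth) == cl
    if (all(y) || !any(y)) return(NA_real_)
    average_precision(y, probs[, cl])
  }, numeric(1))
  mean(aps, na.rm = TRUE)
}

#' Cohen's kappa with optional disagreement weights
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' distributions. `weights = "none"` gives the unweighted coefficient (for a
#' binary task weighted and unweighted coincide); `"linear"` and
#' `"quadratic"` weight disagreements by their distance in the supplied class
#' order.
#'
#' @param truth,predicted label vectors over a common label space.
#' @param weights `"none"`, `"linear"` or `"quadratic"`.
#' @param classes optional ordered class vector (defaults to sorted union).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(truth, predicted, weights = c("none", "linear", "quadratic"),
                         classes = NULL) {
  weights <- match.arg(weights)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  k <- length(classes)
  if (k == 1) {
    if (all(truth == predicted)) return(1)
    stop("degenerate single-label input with disagreement", call. = FALSE)
  }
  tab <- table(factor(truth, classes), factor(predicted, classes))
  n <- sum(tab)
  p <- tab / n
  i <- matrix(seq_len(k), k, k)
  j <- t(i)
  w <- switch(weights,
    none = 1 - diag(k),
    linear = abs(i - j) / (k - 1),
    quadratic = ((i - j) / (k - 1))^2
  )
  expected <- outer(rowSums(p), colSums(p))
  denom <- sum(w * expected)
  if (denom == 0) {
    if (all(truth == predicted)) return(1)
    stop("kappa undefined: no chance disagreement mass", call. = FALSE)
  }
  1 - sum(w * p) / denom
}

#' Row-normalized confusion matrix in percent
#'
#' Rows are true classes, columns predicted classes; each row with support
#' sums to 100.
#'
#' @param truth,predicted label vectors.
#' @param classes fixed class order (defaults to sorted union).
#' @return numeric matrix of row percentages.
#' @export
confusion_percentages <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  tab <- table(factor(truth, classes), factor(predicted, classes))
  rs <- rowSums(tab)
  pct <- 100 * sweep(unclass(tab), 1, pmax(rs, 1), "/")
  dimnames(pct) <- list(true = classes, predicted = classes)
  pct
}

#' Full flat-classification evaluation report
#'
#' @param truth,predicted label vectors.
#' @param probs optional class-probability matrix (named columns) for AP.
#' @param kappa_weights passed to [cohens_kappa()].
#' @return list with per-class F1 table, macro F1, per-class and macro AP,
#'   kappa, the row-percentage confusion matrix, and per-class epoch counts.
#' @export
evaluation_report <- function(truth, predicted, probs = NULL,
                              kappa_weights = "none") {
  f1 <- macro_f1(truth, predicted)
  ap <- NULL
  macro_ap <- NA_real_
  if (!is.null(probs)) {
    classes <- intersect(colnames(probs), unique(as.character(truth)))
    ap <- vapply(classes, function(cl) {
      y <- as.character(truth) == cl
      if (all(y) || !any(y)) return(NA_real_)
      average_precision(y, probs[, cl])
    }, numeric(1))
    macro_ap <- mean(ap, na.rm = TRUE)
  }
  list(
    per_class_f1 = f1$per_class,
    macro_f1 = f1$macro_f1,
    per_class_ap = ap,
    macro_ap = macro_ap,
    kappa = cohens_kappa(truth, predicted, weights = kappa_weights),
    confusion_pct = confusion_percentages(truth, predicted),
    support = table(as.character(truth))
  )
}
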