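#' Training configuration for the nested-CV random-forest protocol
#'
#' The hyperparameter search space is the number of trees in
#' `(100, 150, 200, 300, 400, 500)` crossed with the maximum tree depth in
#' `(5, 10, 15, 20, Full)`; `0` encodes Full (unbounded depth). Per outer
#' fold a randomized search draws `search_draws` grid cells without
#' replacement and scores each by inner k-fold cross-validation on macro
#' average precision; the winner is refit on the whole outer-training split.
#' All other forest parameters keep the implementation defaults.
#'
#' @param n_trees_grid candidate tree counts.
#' @param depth_grid candidate maximum depths; 0 means unbounded ("Full").
#' @param outer_folds,inner_folds participant-grouped fold counts (>= 2).
#' @param search_draws randomized-search draws per outer fold (capped at the
#'   grid size).
#' @param smoothing_window_min probability-smoothing window in minutes.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param seed master seed; every stochastic step derives its own seed.
#' @return an object of class `training_config`.
#' @export
training_config <- function(n_trees_grid = c(100, 150, 200, 300, 400, 500),
                            depth_grid = c(5, 10, 15, 20, 0),
                            outer_folds = 5, inner_folds = 5,
                            search_draws = 10, smoothing_window_min = 5,
                            smote_k = 5, seed = 1L) {
  if (!length(n_trees_grid) || !length(depth_grid)) {
    stop_config("hyperparameter grids must be non-empty")
  }
  if (outer_folds < 2 || inner_folds < 2) stop_config("folds must be >= 2")
  structure(list(n_trees_grid = n_trees_grid, depth_grid = depth_grid,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 search_draws = search_draws,
                 smoothing_window_min = smoothing_window_min,
                 smote_k = smote_k, seed = as.integer(seed)),
            class = "training_config")
}

#' Participant-grouped fold assignment
#'
#' Each participant lands in exactly one fold so no participant's epochs ever
#' straddle a train/validation split; fold sizes differ by at most one
#' participant. Deterministic given the seed.
#'
#' @param participant_ids vector of participant identifiers (unique values
#'   are folded).
#' @param k number of folds.
#' @param seed integer seed.
#' @return named integer vector: fold per participant.
#' @export
make_grouped_folds <- function(participant_ids, k, seed = 1L) {
  ids <- unique(as.character(participant_ids))
  if (length(ids) < k) {
    stop_config("fewer participants (", length(ids), ") than folds (", k, ")")
  }
  shuffled <- with_seed(seed, sample(ids))
  folds <- rep(seq_len(k), length.out = length(shuffled))
  stats::setNames(folds, shuffled)[ids]
}

#' SMOTE: synthetic minority oversampling
#'
#' Every class is resampled up to the majority count. A synthetic row is
#' `x + u * (x_nn - x)` with `u ~ U(0, 1)`, where `x` is a random row of the
#' minority class and `x_nn` one of its `k_neighbors` nearest same-class
#' neighbours (Euclidean). Intended for training rows only; validation and
#' test rows must never pass through it.
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @param seed integer seed.
#' @param k_neighbors nearest-neighbour count; reduced with a warning for
#'   classes with fewer than `k_neighbors + 1` rows.
#' @return list with augmented `x`, `y`, and `synthetic` (logical flag per
#'   row; original rows first, in input order).
#' @export
balance_with_smote <- function(x, y, seed = 1L, k_neighbors = 5) {
  x <- as.matrix(x)
  y <- as.character(y)
  counts <- table(y)
  if (length(counts) < 2) stop_config("SMOTE needs at least two classes")
  n_maj <- max(counts)
  new_x <- list()
  new_y <- character(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- n_maj - counts[[cl]]
      if (need == 0) next
      rows <- which(y == cl)
      n_c <- length(rows)
      if (n_c == 1) {
        warning("class '", cl, "' has a single row; duplicating it")
        new_x[[cl]] <- x[rep(rows, need), , drop = FALSE]
        new_y <- c(new_y, rep(cl, need))
        next
      }
      k <- k_neighbors
      if (n_c <= k) {
        k <- n_c - 1L
        warning("class '", cl, "' smaller than k_neighbors + 1; using k = ", k)
      }
      xc <- x[rows, , drop = FALSE]
      d <- as.matrix(dist(xc))
      diag(d) <- Inf
      nn <- apply(d, 1, function(v) order(v)[seq_len(k)])
      nn <- matrix(nn, nrow = k)
      base <- sample(n_c, need, replace = TRUE)
      pick <- nn[cbind(sample(k, need, replace = TRUE), base)]
      u <- runif(need)
      new_x[[cl]] <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      new_y <- c(new_y, rep(cl, need))
    }
  })
  if (length(new_x)) {
    aug <- do.call(rbind, new_x)
    list(x = rbind(x, aug), y = c(y, new_y),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(aug))))
  } else {
    list(x = x, y = y, synthetic = rep(FALSE, nrow(x)))
  }
}

#' Smooth class probabilities over a centred rolling window
#'
#' Each class column is averaged over a centred window (shrinking at the
#' edges) and rows are renormalized to the simplex. Five minutes equals ten
#' 30-s epochs.
#'
#' @param probs matrix of per-epoch class probabilities (rows sum to 1).
#' @param window_epochs window width in epochs.
#' @return smoothed matrix with rows summing to 1.
#' @export
smooth_probabilities <- function(probs, window_epochs = 10L) {
  probs <- as.matrix(probs)
  sm <- apply(probs, 2, roll_center, width = window_epochs, op = "mean")
  sm <- matrix(sm, nrow = nrow(probs), dimnames = dimnames(probs))
  sm / rowSums(sm)
}

smooth_by_participant <- function(probs, participants, window_epochs) {
  out <- probs
  for (p in unique(participants)) {
    idx <- which(participants == p)
    out[idx, ] <- smooth_probabilities(probs[idx, , drop = FALSE], window_epochs)
  }
  out
}

fit_forest <- function(x, y, trees, depth, seed) {
  ranger::ranger(x = x, y = factor(y), num.trees = trees,
                 max.depth = if (depth == 0) NULL else depth,
                 probability = TRUE, seed = seed, num.threads = 1)
}

predict_forest <- function(model, x, classes) {
  pr <- predict(model, data = as.matrix(x), num.threads = 1)$predictions
  out <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  out[, colnames(pr)] <- pr
  out
}

# fold assignment for inner CV that keeps every class in every training
# portion: re-derived-seed refolds first, then stratification by participant
# class profile, then a reduced fold count; error when even k = 2 fails
inner_folds_with_coverage <- function(ids, labels_by_id, k, seed, max_tries = 20) {
  all_classes <- unique(unlist(labels_by_id))
  covers <- function(f, kk) {
    all(vapply(seq_len(kk), function(g) {
      train_ids <- names(f)[f != g]
      length(unique(unlist(labels_by_id[train_ids]))) == length(all_classes)
    }, logical(1)))
  }
  for (kk in seq(k, 2L)) {
    for (attempt in seq_len(max_tries)) {
      f <- make_grouped_folds(ids, kk, derive_seed(seed, 100L * kk + attempt))
      if (covers(f, kk)) return(f)
    }
    # stratify: deal participants fold-wise within class-profile groups so
    # participants with rare classes spread across folds
    profile <- vapply(ids, function(id) {
      paste(sort(unique(labels_by_id[[id]])), collapse = "|")
    }, "")
    ord <- with_seed(derive_seed(seed, 999L + kk), {
      sh <- sample(ids)
      sh[order(profile[match(sh, ids)])]
    })
    f <- stats::setNames(rep(seq_len(kk), length.out = length(ord)), ord)[ids]
    if (covers(f, kk)) return(f)
  }
  stop("could not build inner folds covering every class in every training split",
       call. = FALSE)
}

#' Nested cross-validated random-forest training
#'
#' The paper-style protocol: participant-grouped outer folds estimate
#' generalisation; within each outer-training split a randomized search over
#' the tree-count x depth grid is scored by participant-grouped inner
#' cross-validation (macro average precision, after per-participant
#' probability smoothing), and the winning pair is refit on the full
#' outer-training split. Normalization statistics and SMOTE are fitted on
#' training rows only. The five outer models form the returned ensemble.
#'
#' Rows must be ordered by participant and, within participant, by epoch time
#' (the probability smoothing assumes a contiguous series per participant).
#'
#' @param features numeric feature matrix / data.frame (no label columns).
#' @param labels class label per row.
#' @param participants participant id per row.
#' @param config a [training_config()].
#' @param task tag stored on the ensemble (e.g. `"sleepwake"`, `"nonwear"`).
#' @return an object of class `trained_ensemble`: `members` (one per outer
#'   fold, each with the fitted forest, normalization statistics and chosen
#'   hyperparameters), `classes`, `outer_metrics` (macro F1, macro AP, kappa
#'   per fold), and the pooled held-out `predictions`.
#' @export
nested_cv_train <- function(features, labels, participants,
                            config = training_config(), task = "sleepwake") {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  participants <- as.character(participants)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(participants))
  classes <- sort(unique(labels))
  win <- as.integer(config$smoothing_window_min * 60 / 30)
  grid <- expand.grid(trees = config$n_trees_grid, depth = config$depth_grid)
  labels_by_id <- split(labels, participants)

  outer <- make_grouped_folds(participants, config$outer_folds,
                              derive_seed(config$seed, 1L))
  members <- vector("list", config$outer_folds)
  metrics <- vector("list", config$outer_folds)
  pred_rows <- vector("list", config$outer_folds)

  for (f in seq_len(config$outer_folds)) {
    val_ids <- names(outer)[outer == f]
    train_ids <- names(outer)[outer != f]
    tr <- participants %in% train_ids
    va <- participants %in% val_ids
    seed_f <- derive_seed(config$seed, 1000L + f)

    n_draws <- min(config$search_draws, nrow(grid))
    draws <- with_seed(derive_seed(seed_f, 2L),
                       grid[sample(nrow(grid), n_draws), , drop = FALSE])
    k_in <- min(config$inner_folds, length(train_ids))
    if (k_in < 2) stop_config("outer-training split has fewer than 2 participants")
    inner <- inner_folds_with_coverage(train_ids, labels_by_id[train_ids],
                                       k_in, derive_seed(seed_f, 3L))

    draw_scores <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      ap_g <- numeric(k_in)
      for (g in seq_len(k_in)) {
        in_tr <- tr & participants %in% names(inner)[inner != g]
        in_va <- tr & participants %in% names(inner)[inner == g]
        norm <- normalize_features(x[in_tr, , drop = FALSE])
        bal <- balance_with_smote(norm$x, labels[in_tr],
                                  seed = derive_seed(seed_f, 10L * d + g),
                                  k_neighbors = config$smote_k)
        fit <- fit_forest(bal$x, bal$y, draws$trees[d], draws$depth[d],
                          seed = derive_seed(seed_f, 100L * d + g))
        xv <- normalize_features(x[in_va, , drop = FALSE], stats = norm)$x
        pr <- predict_forest(fit, xv, classes)
        pr <- smooth_by_participant(pr, participants[in_va], win)
        ap_g[g] <- macro_average_precision(labels[in_va], pr)
      }
      draw_scores[d] <- mean(ap_g)
    }
    best <- draws[which.max(draw_scores), ]

    norm <- normalize_features(x[tr, , drop = FALSE])
    bal <- balance_with_smote(norm$x, labels[tr],
                              seed = derive_seed(seed_f, 4L),
                              k_neighbors = config$smote_k)
    fit <- fit_forest(bal$x, bal$y, best$trees, best$depth,
                      seed = derive_seed(seed_f, 5L))
    xv <- normalize_features(x[va, , drop = FALSE], stats = norm)$x
    pr <- smooth_by_participant(predict_forest(fit, xv, classes),
                                participants[va], win)
    pred <- classes[max.col(pr, ties.method = "first")]
    truth_va <- labels[va]
    metrics[[f]] <- data.frame(
      fold = f, trees = best$trees, depth = best$depth,
      macro_f1 = macro_f1(truth_va, pred)$macro_f1,
      macro_ap = macro_average_precision(truth_va, pr),
      kappa = cohens_kappa(truth_va, pred),
      n_val = sum(va)
    )
    members[[f]] <- list(model = fit, center = norm$center, scale = norm$scale,
                         trees = best$trees, depth = best$depth, fold = f)
    pred_rows[[f]] <- data.frame(row = which(va), fold = f,
                                 participant = participants[va],
                                 truth = truth_va, predicted = pred, pr,
                                 check.names = FALSE)
  }
  structure(
    list(members = members, classes = classes, task = task, config = config,
         feature_columns = colnames(x),
         outer_metrics = do.call(rbind, metrics),
         predictions = do.call(rbind, pred_rows)),
    class = "trained_ensemble"
  )
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("<trained_ensemble> task %s: %d members over classes {%s}\n",
              x$task, length(x$members), paste(x$classes, collapse = ", ")))
  print(x$outer_metrics, row.names = FALSE)
  invisible(x)
}

#' Predict with an outer-fold ensemble
#'
#' Each member applies its own normalization statistics and forest, its
#' probabilities are smoothed per participant over the training smoothing
#' window, and the member outputs are averaged with equal weights. Labels are
#' the probability argmax; ties go to the class earlier in the ensemble's
#' canonical (sorted) class order.
#'
#' @param ensemble a [nested_cv_train()] result.
#' @param features feature matrix with exactly the training columns.
#' @param participants optional participant id per row (one contiguous series
#'   assumed when omitted).
#' @return list with `probabilities` (rows on the simplex) and `labels`.
#' @export
ensemble_predict <- function(ensemble, features, participants = NULL) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  x <- as.matrix(features)
  if (!identical(colnames(x), ensemble$feature_columns)) {
    stop("feature columns do not match the ensemble's training spec",
         call. = FALSE)
  }
  if (is.null(participants)) participants <- rep("all", nrow(x))
  win <- as.integer(ensemble$config$smoothing_window_min * 60 / 30)
  acc <- 0
  for (m in ensemble$members) {
    xn <- normalize_features(x, stats = list(center = m$center, scale = m$scale))$x
    pr <- predict_forest(m$model, xn, ensemble$classes)
    acc <- acc + smooth_by_participant(pr, participants, win)
  }
  probs <- acc / length(ensemble$members)
  labels <- factor(ensemble$classes[max.col(probs, ties.method = "first")],
                   levels = ensemble$classes)
  list(probabilities = probs, labels = labels)
}
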