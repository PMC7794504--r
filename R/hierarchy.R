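#' Sleep-stage class hierarchy
#'
#' The default tree organizes the classification vocabulary as
#' Root -> \{Nonwear, Wear\}; Wear -> \{Wake, Sleep\};
#' Sleep -> \{NREM, REM\}; NREM -> \{N1+N2, N3\}; N1+N2 -> \{N1, N2\}.
#' N1 and N2 are grouped because they are more alike than N2 and N3.
#' Leaves are \{Nonwear, Wake, REM, N3, N1, N2\}.
#'
#' @param edges data.frame with columns `node`, `parent` (one row per
#'   non-root node); defaults to the tree above.
#' @return object of class `class_hierarchy` with the edge list, `leaves`,
#'   `internal` nodes and an ancestor map.
#' @export
class_hierarchy <- function(edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(
      node   = c("Nonwear", "Wear", "Wake", "Sleep", "NREM", "REM",
                 "N1+N2", "N3", "N1", "N2"),
      parent = c("Root", "Root", "Wear", "Wear", "Sleep", "Sleep",
                 "NREM", "NREM", "N1+N2", "N1+N2"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("node", "parent") %in% names(edges)))
  if (anyDuplicated(edges$node)) stop_config("each node must have exactly one parent")
  parents <- stats::setNames(edges$parent, edges$node)
  nodes <- edges$node
  leaves <- setdiff(nodes, edges$parent)
  internal <- unique(edges$parent)
  ancestors <- lapply(stats::setNames(nodes, nodes), function(nd) {
    path <- character(0)
    cur <- nd
    steps <- 0
    while (cur != "Root") {
      path <- c(path, cur)
      cur <- parents[[cur]]
      if (is.null(cur)) stop_config("node without path to Root: ", nd)
      steps <- steps + 1
      if (steps > length(nodes)) stop_config("cycle in hierarchy")
    }
    path
  })
  structure(list(edges = edges, parents = parents, leaves = leaves,
                 internal = setdiff(internal, character(0)),
                 ancestors = ancestors),
            class = "class_hierarchy")
}

#' Children of a hierarchy node
#' @param hierarchy a [class_hierarchy()].
#' @param node node name (`"Root"` allowed).
#' @return character vector of child nodes.
#' @export
hierarchy_children <- function(hierarchy, node) {
  hierarchy$edges$node[hierarchy$edges$parent == node]
}

#' Ancestor closure of a label (itself plus all ancestors, Root excluded)
#' @param hierarchy a [class_hierarchy()].
#' @param label node name.
#' @return character vector.
#' @export
ancestor_closure <- function(hierarchy, label) {
  cl <- hierarchy$ancestors[[label]]
  if (is.null(cl)) stop("unknown label: ", label, call. = FALSE)
  cl
}

# leaves descending from `node` (node itself if a leaf)
descendant_leaves <- function(hierarchy, node) {
  if (node %in% hierarchy$leaves) return(node)
  unlist(lapply(hierarchy_children(hierarchy, node),
                descendant_leaves, hierarchy = hierarchy))
}

# which child branch of `node` a leaf belongs to
branch_of <- function(hierarchy, node, leaves) {
  kids <- hierarchy_children(hierarchy, node)
  out <- rep(NA_character_, length(leaves))
  for (k in kids) {
    out[leaves %in% descendant_leaves(hierarchy, k)] <- k
  }
  out
}

#' Train a local classifier per parent node
#'
#' For every non-leaf node a random-forest ensemble is trained on the epochs
#' whose true leaf descends from that node, with the node's child branch as
#' the target, under the same SMOTE-balanced participant-grouped nested-CV
#' protocol as the flat tasks. Epochs never reach classifiers below a branch
#' they do not belong to (e.g. nonwear epochs train only the root model).
#' A node with fewer than two represented children degenerates to a constant
#' predictor with a warning.
#'
#' @param features feature matrix (rows ordered by participant, then time).
#' @param leaf_labels true leaf label per row.
#' @param participants participant id per row.
#' @param hierarchy a [class_hierarchy()].
#' @param config a [training_config()].
#' @return object of class `hierarchical_model`: per-node ensembles plus the
#'   hierarchy.
#' @export
train_hierarchy <- function(features, leaf_labels, participants,
                            hierarchy = class_hierarchy(),
                            config = training_config()) {
  leaf_labels <- as.character(leaf_labels)
  if (!all(leaf_labels %in% hierarchy$leaves)) {
    stop("training labels must be leaves of the hierarchy", call. = FALSE)
  }
  x <- as.matrix(features)
  nodes <- hierarchy$internal
  models <- vector("list", length(nodes))
  names(models) <- nodes
  for (nd in nodes) {
    in_node <- leaf_labels %in% descendant_leaves(hierarchy, nd)
    target <- branch_of(hierarchy, nd, leaf_labels[in_node])
    present <- unique(target)
    if (length(present) < 2) {
      warning("node '", nd, "' has fewer than 2 represented children; ",
              "using a constant predictor")
      models[[nd]] <- list(constant = present[1],
                           classes = sort(hierarchy_children(hierarchy, nd)))
      next
    }
    models[[nd]] <- nested_cv_train(
      x[in_node, , drop = FALSE], target, participants[in_node],
      config = config, task = paste0("node:", nd)
    )
  }
  structure(list(models = models, hierarchy = hierarchy,
                 feature_columns = colnames(x)),
            class = "hierarchical_model")
}

#' Greedy top-down hierarchical prediction
#'
#' Each epoch descends from the root, taking the argmax child at every node;
#' sibling probabilities at every visited node are retained. Predicted paths
#' are root-consistent by construction.
#'
#' @param model a [train_hierarchy()] result.
#' @param features feature matrix with the training columns.
#' @param participants optional participant id per row.
#' @return list with `leaf` (predicted leaf per row) and `node_probabilities`
#'   (per internal node, a matrix of sibling probabilities for the rows
#'   routed through it, `NA` elsewhere).
#' @export
predict_hierarchy <- function(model, features, participants = NULL) {
  stopifnot(inherits(model, "hierarchical_model"))
  x <- as.matrix(features)
  n <- nrow(x)
  if (is.null(participants)) participants <- rep("all", n)
  hier <- model$hierarchy
  at <- rep("Root", n)
  node_probs <- list()
  repeat {
    open <- intersect(unique(at), hier$internal)
    if (!length(open)) break
    for (nd in open) {
      rows <- which(at == nd)
      kids <- sort(hierarchy_children(hier, nd))
      mdl <- model$models[[nd]]
      pm <- matrix(NA_real_, n, length(kids), dimnames = list(NULL, kids))
      if (!is.null(mdl$constant)) {
        pm[rows, ] <- 0
        pm[rows, mdl$constant] <- 1
      } else {
        pr <- ensemble_predict(mdl, x[rows, , drop = FALSE],
                               participants[rows])$probabilities
        pm[rows, colnames(pr)] <- pr
      }
      node_probs[[nd]] <- pm
      at[rows] <- kids[max.col(pm[rows, , drop = FALSE], ties.method = "first")]
    }
  }
  list(leaf = at, node_probabilities = node_probs)
}

#' Hierarchical precision, recall and F1
#'
#' Per epoch the predicted and true labels are expanded to their ancestor
#' closures (Root excluded); hierarchical precision is the micro-averaged
#' `|intersection| / |predicted closure|`, recall
#' `|intersection| / |true closure|`, and hF1 their harmonic mean. Per-class
#' values restrict the micro-average to the epochs whose true leaf descends
#' from (or equals) that class.
#'
#' Per-class scores decompose the same counts by node membership: for a class
#' `c`, precision is the fraction of epochs predicted into `c`'s branch
#' (`c` in the predicted closure) whose true closure also contains `c`, and
#' recall the fraction of epochs truly under `c` (the sub-population whose
#' true leaf descends from it) predicted into its branch. Summing the
#' per-class counts over all nodes reproduces the overall micro scores.
#'
#' @param true_leaves true leaf label per epoch.
#' @param predicted_leaves predicted leaf (or internal node) per epoch.
#' @param hierarchy a [class_hierarchy()].
#' @return list with `overall` (hP, hR, hF1) and `per_class` (one row per
#'   hierarchy node with true support).
#' @export
hierarchical_f1 <- function(true_leaves, predicted_leaves,
                            hierarchy = class_hierarchy()) {
  true_leaves <- as.character(true_leaves)
  predicted_leaves <- as.character(predicted_leaves)
  known <- names(hierarchy$ancestors)
  if (!all(true_leaves %in% known) || !all(predicted_leaves %in% known)) {
    stop("unknown label", call. = FALSE)
  }
  tc <- hierarchy$ancestors[true_leaves]
  pc <- hierarchy$ancestors[predicted_leaves]
  inter <- mapply(function(a, b) length(intersect(a, b)), tc, pc)
  hp <- sum(inter) / sum(lengths(pc))
  hr <- sum(inter) / sum(lengths(tc))
  overall <- c(hP = hp, hR = hr,
               hF1 = if (hp + hr == 0) 0 else 2 * hp * hr / (hp + hr))
  nodes <- names(hierarchy$ancestors)
  per_class <- do.call(rbind, lapply(nodes, function(nd) {
    in_true <- vapply(tc, function(s) nd %in% s, logical(1))
    in_pred <- vapply(pc, function(s) nd %in% s, logical(1))
    if (!any(in_true)) return(NULL)
    tp <- sum(in_true & in_pred)
    p <- if (any(in_pred)) tp / sum(in_pred) else 0
    r <- tp / sum(in_true)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = nd, hP = p, hR = r, hF1 = f,
               support = sum(in_true), row.names = NULL)
  }))
  list(overall = overall, per_class = per_class)
}
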