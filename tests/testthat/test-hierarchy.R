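test_that("the default tree has the expected structure", {
  h <- class_hierarchy()
  expect_setequal(h$leaves, c("Nonwear", "Wake", "REM", "N3", "N1", "N2"))
  expect_setequal(h$internal, c("Root", "Wear", "Sleep", "NREM", "N1+N2"))
  expect_setequal(hierarchy_children(h, "Root"), c("Nonwear", "Wear"))
  expect_identical(ancestor_closure(h, "N2"),
                   c("N2", "N1+N2", "NREM", "Sleep", "Wear"))
  expect_error(class_hierarchy(data.frame(node = c("A", "A"),
                                          parent = c("Root", "Root"))),
               "exactly one parent")
})

test_that("hierarchical F1 matches set arithmetic on worked examples", {
  h <- class_hierarchy()
  perfect <- hierarchical_f1(c("N2", "Wake"), c("N2", "Wake"), h)
  expect_equal(unname(perfect$overall), c(1, 1, 1))
  # true N2 predicted N3: intersection {Wear, Sleep, NREM} of sizes 4 and 5
  one <- hierarchical_f1("N2", "N3", h)
  expect_equal(one$overall[["hP"]], 3 / 4)
  expect_equal(one$overall[["hR"]], 3 / 5)
  expect_equal(one$overall[["hF1"]],
               2 * (3 / 4) * (3 / 5) / ((3 / 4) + (3 / 5)))
  # disjoint branches share nothing
  zero <- hierarchical_f1("Nonwear", "N2", h)
  expect_equal(unname(zero$overall), c(0, 0, 0))
  expect_error(hierarchical_f1("N2", "bogus", h), "unknown label")
})

test_that("hierarchical F1 agrees with a brute-force closure oracle", {
  h <- class_hierarchy()
  set.seed(43)
  leaves <- h$leaves
  truth <- sample(leaves, 200, replace = TRUE)
  pred <- sample(leaves, 200, replace = TRUE)
  res <- hierarchical_f1(truth, pred, h)
  inter <- 0; np <- 0; nt <- 0
  for (i in seq_along(truth)) {
    tc <- oracle_closure(truth[i]); pc <- oracle_closure(pred[i])
    inter <- inter + length(intersect(tc, pc))
    np <- np + length(pc); nt <- nt + length(tc)
  }
  expect_equal(res$overall[["hP"]], inter / np, tolerance = 1e-12)
  expect_equal(res$overall[["hR"]], inter / nt, tolerance = 1e-12)
})

test_that("corrupting only deep nodes preserves upper-level scores", {
  h <- class_hierarchy()
  set.seed(47)
  truth <- sample(c("N1", "N2"), 100, replace = TRUE)
  deep_wrong <- ifelse(truth == "N1", "N2", "N1")   # path correct to N1+N2
  a <- hierarchical_f1(truth, truth, h)$per_class
  b <- hierarchical_f1(truth, deep_wrong, h)$per_class
  for (cl in c("Wear", "Sleep", "NREM", "N1+N2")) {
    expect_equal(b$hR[b$class == cl], a$hR[a$class == cl])
  }
  expect_lt(b$hF1[b$class == "N1"], a$hF1[a$class == "N1"])
})

test_that("node models train on exactly their branch populations", {
  hm <- hierarchy_fit()
  ed <- test_epoch_data()
  expect_setequal(names(hm$models),
                  c("Root", "Wear", "Sleep", "NREM", "N1+N2"))
  expect_setequal(unique(hm$models[["N1+N2"]]$predictions$truth),
                  c("N1", "N2"))
  expect_identical(nrow(hm$models[["N1+N2"]]$predictions),
                   sum(ed$stage %in% c("N1", "N2")))
  # nonwear epochs never reach classifiers below the root
  expect_identical(nrow(hm$models[["Wear"]]$predictions),
                   sum(ed$stage != "Nonwear"))
  expect_identical(nrow(hm$models[["Root"]]$predictions), nrow(ed))
})

test_that("prediction descends the tree consistently and degrades downward", {
  hm <- hierarchy_fit()
  ned <- heldout_epoch_data()
  nx <- epoch_features_matrix(ned)
  ph <- predict_hierarchy(hm, nx, ned$participant)
  h <- hm$hierarchy
  expect_true(all(ph$leaf %in% h$leaves))
  # root consistency: every row was routed through each ancestor of its leaf
  set.seed(3)
  for (i in sample(length(ph$leaf), 50)) {
    for (anc in ancestor_closure(h, ph$leaf[i])) {
      expect_false(is.na(ph$node_probabilities[[h$parents[[anc]]]][i, anc]))
    }
  }
  # sibling probabilities sum to 1 at every visited node
  for (nd in names(ph$node_probabilities)) {
    pm <- ph$node_probabilities[[nd]]
    rs <- rowSums(pm)
    expect_true(all(abs(rs[!is.na(rs)] - 1) < 1e-9))
  }
  res <- hierarchical_f1(ned$stage, ph$leaf, h)
  l1 <- mean(res$per_class$hF1[res$per_class$class %in% c("Nonwear", "Wear")])
  l5 <- mean(res$per_class$hF1[res$per_class$class %in% c("N1", "N2")])
  expect_gt(l1, l5)
})

test_that("missing child branches degenerate to a constant predictor", {
  set.seed(59)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- rep(c("Wake", "N2"), n / 2)
  x[y == "N2", 1] <- x[y == "N2", 1] + 3
  parts <- rep(sprintf("Q%d", 1:4), each = n / 4)
  cfg <- training_config(outer_folds = 2, inner_folds = 2, search_draws = 1,
                         seed = 4)
  w <- capture_warnings(hm <- train_hierarchy(x, y, parts, config = cfg))
  expect_true(any(grepl("constant predictor", w)))
  ph <- predict_hierarchy(hm, x, parts)
  expect_true(all(ph$leaf %in% c("Wake", "N2")))
})
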