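test_that("the feature spec presets have the expected shapes", {
  full <- feature_spec()
  expect_length(feature_columns(full), 39)
  paper <- feature_spec("paper36")
  expect_length(feature_columns(paper), 36)
  expect_false("enmo_next120diff" %in% feature_columns(paper))
  expect_error(feature_spec(measures = c("mean", "mean")), "unique")
  expect_error(feature_spec(measures = "kurtosis"), "unknown measure")
})

test_that("a constant epoch degenerates to point statistics", {
  sig <- fake_signals(rep(1, 2 * 750))  # ENMO == 1 for 2 epochs
  f <- extract_features(sig, feature_spec(signals = "enmo"))
  expect_equal(f$enmo_mean, c(1, 1))
  expect_equal(f$enmo_min, c(1, 1))
  expect_equal(f$enmo_max, c(1, 1))
  expect_equal(f$enmo_std, c(0, 0))
  expect_equal(f$enmo_mad, c(0, 0))
  expect_equal(f$enmo_entropy20, c(0, 0))
  expect_equal(f$enmo_entropy200, c(0, 0))
})

test_that("difference features use the pinned orientation and zero edge policy", {
  sig <- fake_signals(rep(c(0.1, 0.3), each = 750))  # epoch means 0.1 then 0.3
  f <- extract_features(sig, feature_spec(signals = "enmo"))
  expect_equal(f$enmo_next30diff[1], 0.2)     # mean(next) - mean(current)
  expect_equal(f$enmo_prev30diff[2], 0.2)     # mean(current) - mean(prev)
  # edges lacking context signal "no change"
  expect_equal(f$enmo_prev30diff[1], 0)
  expect_equal(f$enmo_prev60diff[1], 0)
  expect_equal(f$enmo_prev120diff[1], 0)
  expect_equal(f$enmo_next30diff[2], 0)
})

test_that("every feature matches an independent naive recomputation", {
  sim <- simulate_recording(sim_config(duration_hours = 1, seed = 23))
  sig <- compute_derived_signals(sim$raw)
  spec <- feature_spec()
  f <- extract_features(sig, spec)
  set.seed(61)
  epochs <- sample(sig$n_epochs, 100)
  for (i in epochs) {
    for (s in spec$signals) {
      for (m in spec$measures) {
        expect_equal(f[[paste(s, m, sep = "_")]][i], oracle_feature(sig, s, m, i),
                     tolerance = 1e-9,
                     label = sprintf("%s_%s at epoch %d", s, m, i))
      }
    }
  }
})

test_that("features respond to a constant shift as expected", {
  set.seed(41)
  base <- pmax(0, rnorm(10 * 750, 0.05, 0.05))
  f0 <- extract_features(fake_signals(base), feature_spec(signals = "enmo"))
  f1 <- extract_features(fake_signals(base + 0.5), feature_spec(signals = "enmo"))
  expect_equal(f1$enmo_mean, f0$enmo_mean + 0.5)
  expect_equal(f1$enmo_min, f0$enmo_min + 0.5)
  expect_equal(f1$enmo_max, f0$enmo_max + 0.5)
  for (col in c("enmo_std", "enmo_mad", "enmo_entropy20", "enmo_entropy200",
                "enmo_prev30diff", "enmo_next60diff", "enmo_prev120diff")) {
    expect_equal(f1[[col]], f0[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("entropies respect their bin-count bounds", {
  sim <- simulate_recording(sim_config(duration_hours = 0.5, seed = 29))
  f <- extract_features(compute_derived_signals(sim$raw))
  for (s in c("enmo", "z_angle", "lids")) {
    e20 <- f[[paste0(s, "_entropy20")]]
    e200 <- f[[paste0(s, "_entropy200")]]
    expect_true(all(e20 >= 0 & e20 <= log(20) + 1e-12))
    expect_true(all(e200 >= 0 & e200 <= log(200) + 1e-12))
  }
})

test_that("normalization is zero-mean unit-SD with the population convention", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  norm <- normalize_features(x)
  expect_equal(norm$x[, "a"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(norm$x[, "b"], c(0, 0, 0))        # constant column -> zeros
  set.seed(3)
  big <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  nb <- normalize_features(big)
  expect_equal(unname(colMeans(nb$x)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(sqrt(colMeans(nb$x^2))), rep(1, 4), tolerance = 1e-9)
  # round trip and reapplication to held-out rows
  expect_equal(denormalize_features(nb), big, tolerance = 1e-9)
  held <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  hx <- normalize_features(held, stats = nb)$x
  expect_equal(denormalize_features(list(center = nb$center, scale = nb$scale),
                                    hx), held, tolerance = 1e-9)
  bad <- held
  colnames(bad) <- c("a", "b", "c", "e")
  expect_error(normalize_features(bad, stats = nb), "do not match")
})
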