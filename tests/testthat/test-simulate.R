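test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(duration_hours = 0.5, seed = 7)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$raw$ax, b$raw$ax)
  expect_identical(a$raw$ay, b$raw$ay)
  expect_identical(a$raw$az, b$raw$az)
  expect_identical(a$stages, b$stages)
})

test_that("an absorbing transition matrix pins the stage sequence", {
  P <- diag(6)
  dimnames(P) <- list(sim_states(), sim_states())
  cfg <- sim_config(duration_hours = 0.5, stage_transition_matrix = P,
                    initial_state = "N2", seed = 3)
  sim <- simulate_recording(cfg)
  expect_true(all(sim$stages == "N2"))
})

test_that("invalid configurations are rejected", {
  P <- default_transition_matrix()
  P[1, 1] <- P[1, 1] + 0.1
  expect_error(sim_config(stage_transition_matrix = P), "configuration error")
  expect_error(sim_config(duration_hours = 0), "configuration error")
  expect_error(sim_config(sample_rate = 5), "configuration error")
  expect_error(sim_config(nonwear_noise_sd = 0.02), "configuration error")
  expect_error(simulate_cohort(1), "at least 2 participants")
})

test_that("nonwear 15-min blocks stay below the 13 mg SD threshold", {
  # force long nonwear dwells so full 15-min blocks exist
  P <- default_transition_matrix()
  P["Nonwear", ] <- c(0.005, 0, 0, 0, 0, 0.995)
  cfg <- sim_config(duration_hours = 3, stage_transition_matrix = P,
                    nonwear_noise_sd = 0.002, initial_state = "Nonwear",
                    seed = 11)
  sim <- simulate_recording(cfg)
  r <- rle(sim$stages == "Nonwear")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  checked <- 0
  spe <- cfg$sample_rate * 30
  for (j in seq_along(r$lengths)) {
    if (!r$values[j] || r$lengths[j] < 30) next
    # independent pass: per-axis SD over each whole 15-min (30-epoch) block
    for (b0 in seq(starts[j], ends[j] - 29, by = 30)) {
      idx <- ((b0 - 1) * spe + 1):((b0 + 29) * spe)
      sd_mg <- 1000 * mean(c(sd(sim$raw$ax[idx]), sd(sim$raw$ay[idx]),
                             sd(sim$raw$az[idx])))
      expect_lt(sd_mg, 13.0)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})

test_that("cohorts are reproducible with unique participant ids", {
  cfg <- sim_config(duration_hours = 1)
  a <- simulate_cohort(10, cfg, seed = 2)
  b <- simulate_cohort(10, cfg, seed = 2)
  expect_length(a, 10)
  expect_length(unique(vapply(a, function(s) s$raw$participant_id, "")), 10)
  expect_identical(a[[4]]$raw$az, b[[4]]$raw$az)
  two <- simulate_cohort(2, cfg, seed = 2)
  expect_identical(sum(vapply(two, function(s) length(s$stages), 1L)), 2L * 120L)
})

test_that("empirical transition frequencies match the configured matrix", {
  P <- default_transition_matrix()
  st <- simulate_stage_sequence(10000, P, seed = 99)
  idx <- match(st, sim_states())
  from <- idx[-length(idx)]
  to <- idx[-1]
  for (s in seq_len(6)) {
    sel <- from == s
    if (sum(sel) < 50) next
    pos <- which(P[s, ] > 0)
    obs <- tabulate(to[sel], 6)
    expect_true(all(obs[P[s, ] == 0] == 0))
    gof <- suppressWarnings(chisq.test(obs[pos], p = P[s, pos]))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("state-conditional mean ENMO is ordered Wake > REM >= N1+N2 > N3", {
  sim <- simulate_recording(sim_config(duration_hours = 60, seed = 21))
  enmo <- compute_enmo(sim$raw)
  spe <- sim$raw$sample_rate * 30
  em <- colMeans(matrix(enmo, spe, length(sim$stages)))
  counts <- table(sim$stages)
  expect_true(all(counts[c("Wake", "N1", "N2", "N3", "REM")] >= 500))
  m <- tapply(em, sim$stages, mean)
  expect_gt(m[["Wake"]], m[["REM"]])
  expect_gte(m[["REM"]], mean(em[sim$stages %in% c("N1", "N2")]))
  expect_gt(mean(em[sim$stages %in% c("N1", "N2")]), m[["N3"]])
})

test_that("posture holds are still: 5-s z-angle varies by less than a degree", {
  mp <- default_movement_params()
  mp$burst_prob[] <- 0
  mp$posture_prob[] <- 0
  cfg <- sim_config(duration_hours = 0.5, movement_params = mp, seed = 13)
  sim <- simulate_recording(cfg)
  ang <- compute_z_angle(sim$raw)
  expect_lt(max(abs(diff(ang))), 1)
  # gravity consistency during stillness: vector norm stays near 1 g
  norm <- sqrt(sim$raw$ax^2 + sim$raw$ay^2 + sim$raw$az^2)
  expect_lt(abs(mean(norm) - 1), 0.01)
})

test_that("recordings round-trip through the sidecar writers", {
  sim <- simulate_recording(sim_config(duration_hours = 0.25, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_recording(sim, dir)
  expect_true(all(file.exists(paths)))
  hyp <- read_hypnogram(paths[["hypnogram"]])
  expect_identical(nrow(hyp), length(sim$stages))
  expect_identical(hyp$stage[sim$stages == "Wake"][1], "W")
})
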