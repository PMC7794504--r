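write_toy_raw <- function(path, rows, units = "g", sr = 1) {
  writeLines(c(
    "# participant_id: T01",
    paste0("# units: ", units),
    paste0("# sample_rate: ", sr),
    "timestamp,x,y,z",
    rows
  ), path)
}

test_that("a toy raw file reads back its exact values", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_raw(path, c(
    "2024-03-01T12:00:00.000Z,0.1,0.2,0.9",
    "2024-03-01T12:00:01.000Z,0.0,0.0,1.0",
    "2024-03-01T12:00:02.000Z,-0.5,0.5,0.7"
  ))
  rec <- read_raw(path)
  expect_identical(rec$participant_id, "T01")
  expect_equal(rec$ax, c(0.1, 0.0, -0.5))
  expect_equal(rec$ay, c(0.2, 0.0, 0.5))
  expect_equal(rec$az, c(0.9, 1.0, 0.7))
  expect_equal(rec$time, c(0, 1, 2))
})

test_that("duplicated timestamps and missing axes are format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_raw(path, c(
    "2024-03-01T12:00:00.000Z,0.1,0.2,0.9",
    "2024-03-01T12:00:00.000Z,0.0,0.0,1.0"
  ))
  expect_error(read_raw(path), "format error")

  writeLines(c("# units: g", "# sample_rate: 1", "timestamp,x,y",
               "2024-03-01T12:00:00.000Z,0.1,0.2"), path)
  expect_error(read_raw(path), "missing column")
  expect_error(read_raw(tempfile()), "format error")
})

test_that("m/s2 input is converted to g (9.81 m/s2 -> 1 g)", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_raw(path, c(
    "2024-03-01T12:00:00.000Z,0,0,9.81",
    "2024-03-01T12:00:01.000Z,0,0,9.81"
  ), units = "m/s2")
  rec <- read_raw(path)
  expect_equal(rec$az, c(1, 1))
})

test_that("write_raw/read_raw round-trips a simulated recording", {
  sim <- simulate_recording(sim_config(duration_hours = 1 / 60, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw(sim$raw, path)
  back <- read_raw(path)
  expect_equal(back$ax, sim$raw$ax, tolerance = 1e-9)
  expect_equal(back$az, sim$raw$az, tolerance = 1e-9)
  expect_equal(back$time, sim$raw$time, tolerance = 1e-6)
  expect_identical(back$participant_id, sim$raw$participant_id)
})

test_that("hypnogram alignment labels matching epochs and leaves the rest unscored", {
  rec <- still_recording(seconds = 600)          # 20 epochs
  hyp <- data.frame(epoch = 1:10,
                    stage = c("W", "W", "N1", "N2", "N2", "N3", "N3", "REM", "N2", "W"))
  ef <- align_hypnogram(rec, hyp)
  expect_identical(nrow(ef), 20L)
  expect_identical(ef$stage[1:10],
                   c("Wake", "Wake", "N1", "N2", "N2", "N3", "N3", "REM", "N2", "Wake"))
  expect_true(all(ef$stage[11:20] == "unscored"))
})

test_that("small hypnogram offsets snap to the epoch grid", {
  rec <- still_recording(seconds = 600)
  hyp <- data.frame(epoch = 1:5, stage = rep("N2", 5))
  expect_message(
    ef <- align_hypnogram(rec, hyp,
                          hypnogram_start = rec$start_time + 40),  # 30 + 10 s
    "snapped"
  )
  expect_identical(ef$stage[2], "N2")   # snapped to epoch 2
  expect_identical(ef$stage[1], "unscored")
  expect_error(
    align_hypnogram(rec, data.frame(epoch = 1:3, stage = rep("N2", 3)),
                    hypnogram_start = rec$start_time + 5000),
    "alignment error"
  )
})

test_that("ground-truth wear labelling follows the PSG-interval plus 13 mg rule", {
  sr <- 25
  set.seed(8)
  n <- 45 * 60 * sr   # 15 min still / 15 min PSG still / 15 min active
  seg <- rep(1:3, each = n / 3)
  noise <- function(sd) rnorm(n / 3, sd = sd)
  rec <- raw_recording("W01", as.POSIXct("2024-03-01 12:00:00", tz = "UTC"),
                       (seq_len(n) - 1) / sr,
                       ax = c(noise(0.005), noise(0.005), noise(0.02)),
                       ay = c(noise(0.005), noise(0.005), noise(0.02)),
                       az = 1 + c(noise(0.005), noise(0.005), noise(0.02)),
                       sample_rate = sr)
  wear <- label_ground_truth_wear(rec, c(900, 1800))
  ep_seg <- rep(1:3, each = 30)
  expect_true(all(wear[ep_seg == 1] == "nonwear"))  # still, SD ~5 mg < 13
  expect_true(all(wear[ep_seg == 2] == "wear"))     # inside PSG, still or not
  expect_true(all(wear[ep_seg == 3] == "wear"))     # SD ~20 mg > 13
  # idempotent and order-independent
  expect_identical(wear, label_ground_truth_wear(rec, c(900, 1800)))
})

test_that("epoch tables round-trip bit-exactly", {
  set.seed(4)
  df <- data.frame(epoch = 1:5, a = rnorm(5), b = exp(rnorm(5) * 20),
                   lab = letters[1:5])
  path <- withr::local_tempfile(fileext = ".csv")
  write_epochs(df, path, provenance = list(seed = 4))
  back <- read_epochs(path)
  expect_identical(back$a, df$a)
  expect_identical(back$b, df$b)
  expect_identical(back$lab, df$lab)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("sleep logs parse and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset,offset",
               "2024-03-01T23:00:00,2024-03-02T07:00:00"), path)
  sl <- read_sleep_log(path)
  expect_identical(nrow(sl), 1L)
  expect_true(sl$offset > sl$onset)
  writeLines(c("onset,offset",
               "2024-03-01T23:00:00,2024-03-01T22:00:00"), path)
  expect_error(read_sleep_log(path), "offset must follow onset")
})
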