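test_that("stream CSVs round-trip through write and read", {
  s <- make_stream(c(80, 82, 85), device_id = "criterion")
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s, path)
  back <- read_stream(path)
  expect_equal(back$participant_id, "P001")
  expect_equal(back$device_id, "criterion")
  expect_equal(back$readings$hr_bpm, c(80, 82, 85))
  expect_equal(as.numeric(back$readings$time),
               as.numeric(s$readings$time))
})

test_that("read_stream rejects malformed files naming the offending row", {
  base <- data.frame(participant_id = "P1", device_id = "d", phase = "lab",
                     timestamp = c("2018-04-02T08:00:00",
                                   "2018-04-02T08:00:01",
                                   "2018-04-02T08:00:02"),
                     hr_bpm = c(80, 81, 82))
  write_case <- function(mut) {
    df <- base
    df <- mut(df)
    path <- tempfile(fileext = ".csv")
    write.csv(df, path, row.names = FALSE)
    path
  }
  neg <- write_case(function(d) { d$hr_bpm[2] <- -5; d })
  expect_error(read_stream(neg), "row 2")
  bad_ts <- write_case(function(d) { d$timestamp[3] <- "not-a-time"; d })
  expect_error(read_stream(bad_ts), "malformed timestamp at row 3")
  dup <- write_case(function(d) { d$timestamp[3] <- d$timestamp[2]; d })
  expect_error(read_stream(dup), "duplicate timestamp")
  two_dev <- write_case(function(d) { d$device_id[2] <- "other"; d })
  expect_error(read_stream(two_dev), "multiple values")
})

test_that("epoch extraction keeps grid samples and never zero-fills", {
  s <- make_stream(seq(100, 159)) # 60 s at 1 Hz
  ep <- to_epochs(s)
  expect_equal(nrow(ep$epochs), 6)
  expect_true(all(as.numeric(ep$epochs$epoch_start) %% 10 == 0))
  expect_equal(ep$epochs$hr_bpm, c(100, 110, 120, 130, 140, 150))

  # 0.1 Hz streams are already on the grid: epoch count = reading count
  s10 <- make_stream(c(90, 95, 100), by = 10)
  expect_equal(nrow(to_epochs(s10)$epochs), 3)

  # constant stream: both extraction rules agree
  const <- make_stream(rep(100, 60))
  expect_equal(to_epochs(const)$epochs$hr_bpm,
               to_epochs(const, rule = "window_mean")$epochs$hr_bpm)

  # window mean averages within [start, start + 10)
  wm <- to_epochs(s, rule = "window_mean")
  expect_equal(wm$epochs$hr_bpm[1], mean(100:109))

  # a gap in the readings leaves the epoch absent
  gappy <- hr_stream("P001", "d", "lab",
                     as.POSIXct("2018-04-02 08:00:00", tz = "UTC") +
                       c(0:9, 20:29), rep(70, 20))
  expect_equal(nrow(to_epochs(gappy)$epochs), 2)
})

test_that("matching inner-joins epochs and filters zero readings", {
  crit <- to_epochs(make_stream(rep(c(100, 110), 50), by = 10,
                                device_id = "criterion"))
  trk_hr <- rep(c(100, 110), 50)
  trk_hr[1:10] <- 0
  trk <- to_epochs(make_stream(trk_hr, by = 10, device_id = "trk"))
  m <- match_pairs(crit, trk)
  expect_s3_class(m, "matched_pairs")
  expect_equal(nrow(m), 90)
  expect_true(all(m$criterion_bpm > 0 & m$tracker_bpm > 0))
  expect_false(is.unsorted(m$epoch_start))

  # zero criterion epochs are dropped too
  crit2_hr <- rep(100, 100); crit2_hr[5] <- 0
  crit2 <- to_epochs(make_stream(crit2_hr, by = 10,
                                 device_id = "criterion"))
  trk2 <- to_epochs(make_stream(rep(100, 100), by = 10, device_id = "t"))
  expect_equal(nrow(match_pairs(crit2, trk2)), 99)

  # disjoint grids give an empty result, not an error
  late <- to_epochs(make_stream(rep(100, 10), by = 10,
                                start = as.POSIXct("2018-04-02 10:00:00",
                                                   tz = "UTC")))
  expect_equal(nrow(match_pairs(crit, late)), 0)

  # participant mismatch is an error
  other <- to_epochs(make_stream(rep(100, 10), by = 10,
                                 participant_id = "P999"))
  expect_error(match_pairs(crit, other), "participant")
})

test_that("pair count never exceeds either device's nonzero epochs", {
  p <- participant("S1", 30, 60)
  truth <- true_hr_trajectory(p, lab_protocol(), seed = 4)
  crit <- apply_device_error(truth,
                             device_error_model(dropout_prob = 0.1),
                             device_id = "criterion", seed = 31)
  trk <- apply_device_error(truth,
                            device_error_model(dropout_prob = 0.2,
                                               sampling_period = 10),
                            device_id = "trk", seed = 32)
  ec <- to_epochs(crit); et <- to_epochs(trk)
  m <- match_pairs(ec, et)
  expect_lte(nrow(m), sum(ec$epochs$hr_bpm > 0))
  expect_lte(nrow(m), sum(et$epochs$hr_bpm > 0))
})

test_that("epoch grid is stable under whole-hour time shifts", {
  p <- participant("S2", 35, 65)
  truth <- true_hr_trajectory(p, lab_protocol(), seed = 8)
  model <- device_error_model(dropout_prob = 0.05, sampling_period = 10)
  n_pairs <- sapply(c(0, 3600, 8 * 3600), function(shift) {
    shifted <- hr_stream(truth$participant_id, "truth", truth$phase,
                         truth$readings$time + shift,
                         truth$readings$hr_bpm,
                         age = attr(truth, "age"),
                         resting_hr = attr(truth, "resting_hr"))
    crit <- apply_device_error(shifted,
                               device_error_model(sampling_period = 1),
                               device_id = "criterion", seed = 41)
    trk <- apply_device_error(shifted, model, device_id = "t", seed = 42)
    nrow(match_pairs(to_epochs(crit), to_epochs(trk)))
  })
  expect_equal(n_pairs[2], n_pairs[1])
  expect_equal(n_pairs[3], n_pairs[1])
})

test_that("inclusion thresholds are boundary-inclusive per phase", {
  pairs60 <- make_pairs(rep(100, 60), rep(101, 60))
  pairs59 <- pairs60[1:59, ]
  expect_true(apply_inclusion(pairs60, "lab")$included)
  excl <- apply_inclusion(pairs59, "lab")
  expect_false(excl$included)
  expect_equal(excl$reason, "insufficient_lab_data")

  pairs1080 <- make_pairs(rep(100, 1080), rep(99, 1080), phase = "free")
  expect_true(apply_inclusion(pairs1080, "free")$included)
  expect_false(apply_inclusion(pairs1080[1:1079, ], "free")$included)
  expect_error(apply_inclusion(pairs60, "swim"))
})

test_that("wear time counts nonzero epochs in hours", {
  es <- to_epochs(make_stream(rep(100, 4320), by = 10))
  expect_equal(wear_time(es), 12)
  zeros <- to_epochs(make_stream(rep(0, 100), by = 10))
  expect_equal(wear_time(zeros), 0)

  # cohort wear time ~ configured wear x (1 - dropout)
  p <- participant("S3", 28, 60)
  truth <- true_hr_trajectory(p, free_living_protocol(wear_hours = 6),
                              seed = 14)
  dev <- apply_device_error(truth,
                            device_error_model(dropout_prob = 0.1),
                            seed = 15)
  expect_equal(wear_time(to_epochs(dev)), 6 * 0.9, tolerance = 0.05)
})

test_that("complete-triplet restriction intersects the matched sets", {
  crit <- to_epochs(make_stream(rep(100, 100), by = 10,
                                device_id = "criterion"))
  a_hr <- rep(100, 100); a_hr[1:10] <- 0
  b_hr <- rep(100, 100); b_hr[91:100] <- 0
  a <- match_pairs(crit, to_epochs(make_stream(a_hr, by = 10,
                                               device_id = "a")))
  b <- match_pairs(crit, to_epochs(make_stream(b_hr, by = 10,
                                               device_id = "b")))
  both <- complete_triplets(a, b)
  expect_equal(nrow(both[[1]]), 80)
  expect_equal(nrow(both[[2]]), 80)
  expect_equal(as.numeric(both[[1]]$epoch_start),
               as.numeric(both[[2]]$epoch_start))
})
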