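test_that("ICC(2,1) matches hand-computed two-way decompositions", {
  # identical devices with varying HR agree perfectly
  same <- make_pairs(c(80, 100, 120, 140), c(80, 100, 120, 140))
  res <- icc_absolute_agreement(same)
  expect_equal(res$icc, 1)

  # constant +20 bpm offset: absolute agreement penalises the shift
  off <- make_pairs(c(80, 100, 120, 140), c(80, 100, 120, 140) + 20)
  expect_equal(icc_absolute_agreement(off)$icc, 10 / 13,
               tolerance = 1e-12)

  # alternating +/-5 deviations around an increasing ramp
  alt <- make_pairs(c(100, 110, 120, 130),
                    c(100, 110, 120, 130) + c(5, -5, 5, -5))
  expect_equal(icc_absolute_agreement(alt)$icc, 32 / 35,
               tolerance = 1e-12)

  expect_error(icc_absolute_agreement(same[1:2, ]), "at least 3")
  expect_warning(
    zero <- icc_absolute_agreement(make_pairs(rep(100, 5), rep(100, 5))),
    "no variance")
  expect_equal(zero$icc, 0)
})

test_that("ICC is invariant to shared shifts and penalised by one-sided shifts", {
  set.seed(71)
  for (rep in 1:20) {
    x <- rnorm(sample(5:30, 1), 110, 15)
    y <- x + rnorm(length(x), 0, 5)
    p0 <- make_pairs(x, y)
    base <- icc_absolute_agreement(p0)$icc
    expect_equal(base, icc_oracle(cbind(x, y)), tolerance = 1e-10)
    shared <- icc_absolute_agreement(make_pairs(x + 13, y + 13))$icc
    expect_equal(shared, base, tolerance = 1e-9)
    one_sided <- icc_absolute_agreement(make_pairs(x, y + 15))$icc
    expect_lt(one_sided, base)
  }
})

test_that("ICC confidence interval brackets the point estimate", {
  pairs <- sim_pairs(device_error_model(additive_bias = -5,
                                        noise_sd_base = 4,
                                        sampling_period = 10), seed = 6)
  res <- icc_absolute_agreement(pairs)
  expect_lt(res$ci[1], res$icc)
  expect_gt(res$ci[2], res$icc)
  expect_true(res$ci[1] > -1 && res$ci[2] <= 1)
})

test_that("error metrics follow their defining formulas", {
  res <- error_metrics(make_pairs(c(100, 100), c(90, 110)))
  expect_equal(res$mae, 10)
  expect_equal(res$mape, 10)
  expect_equal(res$mean_diff, 0)
  expect_true(res$meets_validity_cutoff)

  ident <- error_metrics(make_pairs(c(90, 120, 150), c(90, 120, 150)))
  expect_equal(ident$mae, 0)
  expect_equal(ident$mape, 0)

  # constant offset: bias recovered exactly, MAE = |bias|
  pairs <- sim_pairs(device_error_model(additive_bias = -9.7,
                                        sampling_period = 10), seed = 2)
  res <- error_metrics(pairs)
  expect_equal(res$mean_diff, -9.7)
  expect_equal(res$mae, 9.7)
  expect_equal(res$meets_validity_cutoff, res$mape <= 10)

  expect_error(error_metrics(make_pairs(c(0, 100), c(90, 110))),
               "positive")
})

test_that("MAPE equals MAE over criterion mean when criterion is constant", {
  set.seed(5)
  y <- 100 + rnorm(50, 0, 8)
  res <- error_metrics(make_pairs(rep(100, 50), y))
  expect_equal(res$mape, res$mae / 100 * 100, tolerance = 1e-12)
  expect_lte(res$mae, max(abs(y - 100)))
})

test_that("Bland-Altman limits follow mean +/- 1.96 SD of differences", {
  ba <- bland_altman(make_pairs(c(100, 100, 100), c(98, 100, 102)))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 2)
  expect_equal(unname(ba$loa), c(-3.92, 3.92))

  const <- bland_altman(make_pairs(c(90, 110), c(93.4, 113.4)))
  expect_equal(unname(const$loa), c(3.4, 3.4)) # SD = 0 collapses the band

  # Gaussian noise: LoA half-width ~ 1.96 sigma and ~95% coverage
  set.seed(9)
  x <- rnorm(10000, 110, 12)
  d <- rnorm(10000, 0, 5)
  ba <- bland_altman(make_pairs(x, x + d))
  expect_equal(unname(ba$loa[2] - ba$loa[1]) / 2, 1.96 * 5,
               tolerance = 0.03)
  inside <- mean(d >= ba$loa[1] & d <= ba$loa[2])
  expect_gte(inside, qbinom(0.005, 10000, 0.95) / 10000)
  expect_lte(inside, qbinom(0.995, 10000, 0.95) / 10000)
})

test_that("ICC labels map bands with inclusive upper boundaries", {
  expect_equal(label_icc(c(0.4999, 0.50, 0.51, 0.73, 0.7499)),
               c("weak", "moderate", "moderate", "moderate", "moderate"))
  expect_equal(label_icc(c(0.75, 0.83, 0.89, 0.90, 0.99)),
               c("strong", "strong", "strong", "very strong",
                 "very strong"))
  expect_error(label_icc(NaN), "finite")
})

test_that("outlier flagging isolates poorly correlated participants", {
  x <- seq(80, 140, length.out = 30)
  good <- make_pairs(x, x + rnorm(30, 0, 2), participant_id = "G")
  set.seed(13)
  bad <- make_pairs(x, sample(x), participant_id = "B")
  anti <- make_pairs(x, rev(x), participant_id = "A")
  tiny <- make_pairs(c(100, 110), c(100, 110), participant_id = "T")
  all_pairs <- rbind(good, bad, anti, tiny)
  flags <- flag_outliers(all_pairs)
  status <- setNames(flags$status, flags$participant_id)
  expect_equal(status[["G"]], "ok")
  expect_equal(status[["B"]], "flagged")
  expect_equal(status[["A"]], "flagged")
  expect_equal(status[["T"]], "not_evaluable")

  agr <- agreement(all_pairs, exclude_outliers = TRUE)
  expect_setequal(agr$excluded_participants, c("B", "A"))
})

test_that("agreement summary is internally consistent", {
  pairs <- sim_pairs(device_error_model(additive_bias = -3,
                                        proportional_bias = -0.05,
                                        noise_sd_base = 3,
                                        sampling_period = 10), seed = 17)
  agr <- agreement(pairs)
  expect_lt(agr$loa[1], agr$mean_diff)
  expect_gt(agr$loa[2], agr$mean_diff)
  expect_gte(agr$mape, 0)
  expect_equal(agr$icc_label, label_icc(agr$icc))
  expect_equal(agr$n_pairs, nrow(pairs))
  expect_output(print(agr), "ICC\\(2,1\\)")
})
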