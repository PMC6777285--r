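# Independent oracles and fixture builders. The ICC oracle is a literal
# two-way sum-of-squares decomposition written with explicit loops, kept
# deliberately separate from the package's ANOVA-based implementation.

icc_oracle <- function(M) {
  dimnames(M) <- NULL
  n <- nrow(M)
  k <- ncol(M)
  grand <- mean(M)
  rowm <- unname(rowMeans(M))
  colm <- unname(colMeans(M))
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (M[i, j] - rowm[i] - colm[j] + grand)^2
    }
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Matched-pairs data.frame from raw vectors, one participant unless told
# otherwise.
make_pairs <- function(criterion, tracker, participant_id = "P001",
                       phase = "lab", tracker_id = "trk",
                       epoch_start = NULL) {
  n <- length(criterion)
  if (is.null(epoch_start)) {
    epoch_start <- as.POSIXct("2018-04-02 08:00:00", tz = "UTC") +
      10 * (seq_len(n) - 1)
  }
  out <- data.frame(participant_id = rep_len(participant_id, n),
                    phase = phase, tracker = tracker_id,
                    epoch_start = epoch_start,
                    criterion_bpm = criterion, tracker_bpm = tracker)
  class(out) <- c("matched_pairs", "data.frame")
  out
}

# A 1 Hz stream with the given bpm values starting on the 10-s grid.
make_stream <- function(hr, participant_id = "P001", device_id = "dev",
                        phase = "lab",
                        start = as.POSIXct("2018-04-02 08:00:00",
                                           tz = "UTC"),
                        by = 1) {
  hr_stream(participant_id, device_id, phase,
            start + by * (seq_along(hr) - 1), hr)
}

# Simulated matched pairs: one participant through a protocol, a
# zero-error 1 Hz criterion, and a tracker with the given error model.
sim_pairs <- function(model, protocol = lab_protocol(), seed = 1,
                      age = 30, resting_hr = 60, trajectory_seed = seed) {
  p <- participant("SIM1", age, resting_hr)
  truth <- true_hr_trajectory(p, protocol, seed = trajectory_seed)
  crit <- apply_device_error(truth, device_error_model(sampling_period = 1),
                             device_id = "criterion", seed = seed + 1)
  trk <- apply_device_error(truth, model, device_id = "tracker",
                            seed = seed + 2)
  match_pairs(to_epochs(crit), to_epochs(trk))
}
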