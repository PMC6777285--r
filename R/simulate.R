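# Synthetic paired-stream generator. The trajectory is a deterministic
# protocol backbone (piecewise-constant targets approached exponentially,
# mimicking on/off heart-rate kinetics) plus a mean-reverting
# Ornstein-Uhlenbeck wander, so that ranked-decile structure downstream is
# nontrivial. Device streams are the trajectory passed through a
# device_error_model.

# Piecewise targets -> per-second backbone by segment-wise exponential
# approach with time constant tau (seconds).
protocol_backbone <- function(targets, lengths, start_level, tau) {
  n <- sum(lengths)
  out <- numeric(n)
  level <- start_level
  pos <- 0L
  for (s in seq_along(targets)) {
    t <- seq_len(lengths[s])
    seg <- targets[s] + (level - targets[s]) * exp(-t / tau)
    out[pos + t] <- seg
    level <- seg[lengths[s]]
    pos <- pos + lengths[s]
  }
  out
}

# Discrete Ornstein-Uhlenbeck wander at 1 Hz, stationary variance sd^2.
ou_wander <- function(n, sd, tau) {
  if (sd <= 0) return(numeric(n))
  phi <- exp(-1 / tau)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = 0))
}

# Per-second target profile for a protocol; returns list(targets, lengths)
# in seconds. Free-living bouts get a fixed 60 s lead-in so heart rate has
# risen above the MVPA cutoff by the declared bout start.
protocol_segments <- function(participant, protocol, seed) {
  hrmax <- hr_max(participant$age)
  if (inherits(protocol, "lab_protocol")) {
    targets_bpm <- protocol$stage_targets * hrmax
    if (any(targets_bpm > hrmax)) {
      stop("stage targets exceed the participant's HRmax", call. = FALSE)
    }
    list(
      targets = c(participant$resting_hr, targets_bpm, participant$resting_hr),
      lengths = as.integer(60 * c(protocol$rest_minutes,
                                  rep(protocol$stage_minutes,
                                      length(protocol$stage_targets)),
                                  protocol$recovery_minutes))
    )
  } else if (inherits(protocol, "free_living_protocol")) {
    n_sec <- as.integer(round(protocol$wear_hours * 3600))
    base_bpm <- protocol$baseline_hr_fraction * hrmax
    bout_bpm <- protocol$bout_hr_fraction * hrmax
    if (bout_bpm > hrmax) {
      stop("bout target exceeds the participant's HRmax", call. = FALSE)
    }
    bout_len <- as.integer(round(protocol$bout_minutes * 60))
    lead_in <- 60L
    # place bouts uniformly at random, non-overlapping, clear of the edges
    starts <- with_seed(seed, place_bouts(n_sec, protocol$mvpa_bouts,
                                          bout_len, lead_in))
    targets <- base_bpm
    lengths <- integer(0)
    prev_end <- 0L
    targets <- numeric(0)
    for (st in starts) {
      targets <- c(targets, base_bpm, bout_bpm)
      lengths <- c(lengths, (st - lead_in) - prev_end, bout_len + lead_in)
      prev_end <- st + bout_len
    }
    targets <- c(targets, base_bpm)
    lengths <- c(lengths, n_sec - prev_end)
    list(targets = targets, lengths = lengths, bout_starts = starts,
         bout_len = bout_len)
  } else {
    stop("`protocol` must be a lab_protocol or free_living_protocol",
         call. = FALSE)
  }
}

place_bouts <- function(n_sec, n_bouts, bout_len, lead_in) {
  margin <- 30L * 60L   # keep bouts out of the first/last half hour
  margin <- min(margin, max(lead_in, (n_sec - n_bouts * bout_len) %/% 4L))
  slots <- seq.int(margin + lead_in, n_sec - margin - bout_len)
  starts <- integer(0)
  for (b in seq_len(n_bouts)) {
    ok <- slots
    for (st in starts) {
      ok <- ok[ok >= st + bout_len + 2L * lead_in | ok <= st - bout_len - 2L * lead_in]
    }
    if (length(ok) == 0L) stop("cannot place non-overlapping MVPA bouts",
                               call. = FALSE)
    starts <- c(starts, ok[sample.int(length(ok), 1L)])
  }
  sort(starts)
}

#' Simulate a criterion-truth heart-rate trajectory
#'
#' Generates the 1 Hz "true" heart rate underlying all device streams for
#' one participant and one protocol phase: a deterministic backbone that
#' approaches each protocol target exponentially (time constant `tau`),
#' plus a mean-reverting stochastic wander. Laboratory trajectories visit
#' the four stage targets within the protocol's tolerance band;
#' free-living trajectories stay below the MVPA threshold outside bouts
#' and above it within bouts.
#'
#' @param participant a [participant()].
#' @param protocol a [lab_protocol()] or [free_living_protocol()].
#' @param seed integer seed; the same seed reproduces the same trajectory.
#' @param tau exponential time constant of the heart-rate response to a
#'   change in workload, seconds.
#' @param wander_sd stationary SD of the mean-reverting wander, bpm.
#' @param wander_tau correlation time of the wander, seconds.
#' @param start_time POSIXct start of the recording (10-s grid aligned).
#' @return an [hr_stream()] for device `"truth"`, whole-bpm values at 1 Hz.
#' @export
#' @examples
#' p <- participant("P01", 30, 60)
#' tr <- true_hr_trajectory(p, lab_protocol(), seed = 7)
#' nrow(tr$readings)  # 1800 seconds
true_hr_trajectory <- function(participant, protocol, seed,
                               tau = 30, wander_sd = 1.5, wander_tau = 120,
                               start_time = as.POSIXct("2018-04-02 08:00:00",
                                                       tz = "UTC")) {
  if (!inherits(participant, "participant")) {
    stop("`participant` must be created with participant()", call. = FALSE)
  }
  seg <- protocol_segments(participant, protocol, seed = seed + 1L)
  n <- sum(seg$lengths)
  backbone <- protocol_backbone(seg$targets, seg$lengths,
                                start_level = participant$resting_hr,
                                tau = tau)
  wander <- with_seed(seed, ou_wander(n, wander_sd, wander_tau))
  hrmax <- hr_max(participant$age)
  hr <- round(pmin(pmax(backbone + wander, 30), hrmax))
  phase <- if (inherits(protocol, "lab_protocol")) "lab" else "free"
  time <- start_time + seq_len(n) - 1
  stream <- hr_stream(participant$id, "truth", phase, time, hr,
                      age = participant$age,
                      resting_hr = participant$resting_hr)
  if (phase == "free") {
    attr(stream, "bout_starts") <- seg$bout_starts
    attr(stream, "bout_len") <- seg$bout_len
  }
  stream
}

#' Distort a truth trajectory through a device error model
#'
#' Resamples the 1 Hz truth stream at the device's sampling period and
#' applies the error model reading by reading: additive bias, a bias
#' proportional to heart rate above rest, heteroscedastic Gaussian noise
#' (floored at 0 bpm), and random dropout to a literal 0 bpm reading. A
#' zero-error model returns the truth values on the device grid unchanged.
#'
#' @param truth an [hr_stream()] at 1 Hz carrying `resting_hr` metadata,
#'   as produced by [true_hr_trajectory()].
#' @param model a [device_error_model()].
#' @param device_id identifier for the simulated device.
#' @param seed integer seed; defaults to the model's own seed. Identical
#'   seeds give identical output.
#' @return an [hr_stream()] for `device_id` at the model's sampling period.
#' @export
apply_device_error <- function(truth, model, device_id = "tracker",
                               seed = model$seed) {
  if (!inherits(truth, "hr_stream")) {
    stop("`truth` must be an hr_stream", call. = FALSE)
  }
  if (!inherits(model, "device_error_model")) {
    stop("`model` must be a device_error_model", call. = FALSE)
  }
  if (is.null(seed)) {
    stop("provide `seed` (or a model with a seed) for reproducible streams",
         call. = FALSE)
  }
  secs <- as.numeric(truth$readings$time)
  if (length(secs) > 1 && any(diff(secs) != 1)) {
    stop("`truth` must be sampled at 1 Hz", call. = FALSE)
  }
  rest <- attr(truth, "resting_hr")
  if (is.null(rest)) stop("`truth` lacks resting_hr metadata", call. = FALSE)

  keep <- secs %% model$sampling_period == 0
  t_dev <- truth$readings$time[keep]
  hr_true <- truth$readings$hr_bpm[keep]
  n <- length(hr_true)

  excess <- hr_true - rest
  noise_sd <- pmax(model$noise_sd_base + model$noise_sd_slope * excess, 0)
  vals <- with_seed(seed, {
    noisy <- hr_true + model$additive_bias + model$proportional_bias * excess +
      stats::rnorm(n, 0, noise_sd)
    drop <- stats::runif(n) < model$dropout_prob
    list(noisy = noisy, drop = drop)
  })
  hr_dev <- pmax(vals$noisy, 0)
  hr_dev[vals$drop] <- 0

  hr_stream(truth$participant_id, device_id, truth$phase, t_dev, hr_dev,
            age = attr(truth, "age"), resting_hr = rest)
}

default_device_models <- function() {
  list(
    # chest-strap criterion: faithful to truth, occasional contact loss
    criterion = device_error_model(dropout_prob = 0.02, sampling_period = 1),
    # consumer optical tracker at 1 Hz: small negative bias growing with HR
    tracker_1hz = device_error_model(additive_bias = -1,
                                     proportional_bias = -0.04,
                                     noise_sd_base = 2, noise_sd_slope = 0.02,
                                     dropout_prob = 0.02, sampling_period = 1),
    # low-cost optical tracker at 0.1 Hz: larger bias and noise
    tracker_01hz = device_error_model(additive_bias = -2,
                                      proportional_bias = -0.08,
                                      noise_sd_base = 3, noise_sd_slope = 0.04,
                                      dropout_prob = 0.03, sampling_period = 10)
  )
}

#' Generate a synthetic validation cohort on disk
#'
#' Draws `n` participants (ages uniform over the study range, resting
#' heart rates around 62 bpm), simulates each through the laboratory and
#' free-living protocols, passes the truth through a criterion model and
#' two tracker models (1 Hz and 0.1 Hz), and writes a roster CSV plus one
#' long-format stream CSV per participant, phase, and device. Fully
#' reproducible: the same seed yields byte-identical files.
#'
#' @param n number of participants (>= 1).
#' @param seed master integer seed.
#' @param out_dir output directory; created if missing. Streams go under
#'   `out_dir/streams/`.
#' @param lab,free protocol objects, defaulting to the study protocols.
#' @param devices named list of [device_error_model()]s; names become
#'   device ids. Must contain `criterion`. Default: see
#'   [device_error_model()] for the phenomenology; the stock models are a
#'   faithful criterion, a 1 Hz tracker with mild negative HR-proportional
#'   bias, and a 0.1 Hz tracker with stronger bias and noise.
#' @param age_range inclusive age bounds for the simulated roster.
#' @return invisibly, a data.frame manifest of the files written.
#' @export
generate_cohort <- function(n, seed, out_dir,
                            lab = lab_protocol(),
                            free = free_living_protocol(),
                            devices = default_device_models(),
                            age_range = c(21, 50)) {
  stopifnot_scalar_number(n, "n", lower = 1)
  if (!"criterion" %in% names(devices)) {
    stop("`devices` must contain a model named 'criterion'", call. = FALSE)
  }
  dir.create(file.path(out_dir, "streams"), recursive = TRUE,
             showWarnings = FALSE)

  draws <- with_seed(seed, {
    list(
      age = sample(seq(age_range[1], age_range[2]), n, replace = TRUE),
      rest = pmin(pmax(round(stats::rnorm(n, 62, 7)), 45), 80),
      # per-(participant, phase, device) sub-seeds, drawn once up front
      subseeds = matrix(sample.int(.Machine$integer.max - 1L,
                                   n * 2L * (length(devices) + 1L)),
                        nrow = n)
    )
  })
  ids <- sprintf("P%03d", seq_len(n))
  roster <- data.frame(participant_id = ids, age = draws$age,
                       resting_hr = draws$rest)
  roster_path <- file.path(out_dir, "roster.csv")
  utils::write.csv(roster, roster_path, row.names = FALSE, quote = FALSE)

  manifest <- list()
  free_start <- as.POSIXct("2018-04-03 07:00:00", tz = "UTC")
  for (i in seq_len(n)) {
    p <- participant(ids[i], draws$age[i], draws$rest[i],
                     age_range = age_range)
    for (ph in c("lab", "free")) {
      col0 <- if (ph == "lab") 0L else length(devices) + 1L
      proto <- if (ph == "lab") lab else free
      start <- if (ph == "lab") as.POSIXct("2018-04-02 08:00:00", tz = "UTC")
               else free_start
      truth <- true_hr_trajectory(p, proto, seed = draws$subseeds[i, col0 + 1L],
                                  start_time = start)
      for (d in seq_along(devices)) {
        dev_id <- names(devices)[d]
        stream <- apply_device_error(truth, devices[[d]], device_id = dev_id,
                                     seed = draws$subseeds[i, col0 + 1L + d])
        path <- file.path(out_dir, "streams",
                          sprintf("%s_%s_%s.csv", ids[i], ph, dev_id))
        write_stream_csv(stream, path)
        manifest[[length(manifest) + 1L]] <-
          data.frame(participant_id = ids[i], phase = ph, device_id = dev_id,
                     path = path)
      }
    }
  }
  invisible(do.call(rbind, manifest))
}
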