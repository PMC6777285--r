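#' Study participant descriptor
#'
#' A participant carries the two physiological anchors the pipeline needs:
#' age, from which age-predicted maximum heart rate is derived as
#' 220 - age, and resting heart rate, the baseline the error model and the
#' trajectory generator work from. HRmax is always derived from age and is
#' never stored independently.
#'
#' @param id participant identifier (coerced to character).
#' @param age age in whole years; the cohort design targets ages 21-50 and
#'   the default validation enforces that range (override with
#'   `age_range` for other designs).
#' @param resting_hr resting heart rate in bpm; must be at least 40 and
#'   strictly below the participant's HRmax.
#' @param age_range permitted age interval, default `c(21, 50)`.
#' @return an object of class `participant`.
#' @seealso [hr_max()]
#' @export
#' @examples
#' p <- participant("P01", age = 30, resting_hr = 62)
#' hr_max(p$age)
participant <- function(id, age, resting_hr, age_range = c(21, 50)) {
  id <- as.character(id)
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("`id` must be a single non-empty string", call. = FALSE)
  }
  stopifnot_scalar_number(age, "age", age_range[1], age_range[2])
  stopifnot_scalar_number(resting_hr, "resting_hr", 40, hr_max(age) - 1e-9)
  structure(
    list(id = id, age = as.integer(age), resting_hr = resting_hr),
    class = "participant"
  )
}

#' Laboratory cycling protocol
#'
#' Incremental stationary-cycling session: seated rest, four 5-minute
#' stages at increasing fractions of age-predicted HRmax (participants are
#' held within +/- `stage_tolerance_bpm` of each stage target), then
#' seated recovery. Defaults reproduce the 20-minute protocol at 45/55/65/75%
#' HRmax with a +/-10 bpm band.
#'
#' @param rest_minutes seated rest before cycling, minutes.
#' @param stage_minutes duration of each cycling stage, minutes.
#' @param stage_targets strictly increasing fractions of HRmax in (0, 1),
#'   one per stage.
#' @param stage_tolerance_bpm permitted deviation of the stage mean from
#'   its target, bpm.
#' @param recovery_minutes seated recovery after the last stage, minutes.
#' @return an object of class `lab_protocol`.
#' @export
lab_protocol <- function(rest_minutes = 5, stage_minutes = 5,
                         stage_targets = c(0.45, 0.55, 0.65, 0.75),
                         stage_tolerance_bpm = 10, recovery_minutes = 5) {
  stopifnot_scalar_number(rest_minutes, "rest_minutes", lower = 1e-9)
  stopifnot_scalar_number(stage_minutes, "stage_minutes", lower = 1e-9)
  stopifnot_scalar_number(recovery_minutes, "recovery_minutes", lower = 1e-9)
  stopifnot_scalar_number(stage_tolerance_bpm, "stage_tolerance_bpm", lower = 0)
  if (length(stage_targets) < 1L || any(stage_targets <= 0) ||
      any(stage_targets >= 1) || is.unsorted(stage_targets, strictly = TRUE)) {
    stop("`stage_targets` must be strictly increasing fractions in (0, 1)",
         call. = FALSE)
  }
  structure(
    list(rest_minutes = rest_minutes, stage_minutes = stage_minutes,
         stage_targets = stage_targets,
         stage_tolerance_bpm = stage_tolerance_bpm,
         recovery_minutes = recovery_minutes),
    class = c("lab_protocol", "hr_protocol")
  )
}

#' Free-living wear-day protocol
#'
#' A waking wear day at a light-activity baseline, containing at least one
#' sustained bout of moderate-to-vigorous physical activity (MVPA) of at
#' least 10 minutes so that the heart-rate signal spans both sides of the
#' MVPA threshold.
#'
#' @param wear_hours total wear duration, hours.
#' @param mvpa_bouts number of MVPA bouts (>= 1).
#' @param bout_minutes duration of each bout, minutes (>= 10).
#' @param baseline_hr_fraction fraction of HRmax targeted outside bouts;
#'   must sit below the MVPA cutoff fraction.
#' @param bout_hr_fraction fraction of HRmax targeted within bouts; must
#'   sit above the MVPA cutoff fraction.
#' @return an object of class `free_living_protocol`.
#' @export
free_living_protocol <- function(wear_hours = 12, mvpa_bouts = 1,
                                 bout_minutes = 10,
                                 baseline_hr_fraction = 0.45,
                                 bout_hr_fraction = 0.75) {
  stopifnot_scalar_number(wear_hours, "wear_hours", lower = 1e-9)
  stopifnot_scalar_number(mvpa_bouts, "mvpa_bouts", lower = 1)
  stopifnot_scalar_number(bout_minutes, "bout_minutes", lower = 10)
  stopifnot_scalar_number(baseline_hr_fraction, "baseline_hr_fraction",
                          lower = 1e-9, upper = 1 - 1e-9)
  stopifnot_scalar_number(bout_hr_fraction, "bout_hr_fraction",
                          lower = 1e-9, upper = 1 - 1e-9)
  if (bout_hr_fraction <= baseline_hr_fraction) {
    stop("`bout_hr_fraction` must exceed `baseline_hr_fraction`",
         call. = FALSE)
  }
  if (mvpa_bouts * bout_minutes * 60 >= wear_hours * 3600) {
    stop("total bout time must be shorter than the wear time", call. = FALSE)
  }
  structure(
    list(wear_hours = wear_hours, mvpa_bouts = as.integer(mvpa_bouts),
         bout_minutes = bout_minutes,
         baseline_hr_fraction = baseline_hr_fraction,
         bout_hr_fraction = bout_hr_fraction),
    class = c("free_living_protocol", "hr_protocol")
  )
}

#' Phenomenological tracker error model
#'
#' Describes how a wrist tracker distorts the true heart rate. Each emitted
#' reading is
#' `truth + additive_bias + proportional_bias * (truth - resting_hr)`
#' plus Gaussian noise whose standard deviation grows linearly with heart
#' rate above rest (`noise_sd_base + noise_sd_slope * (truth - resting_hr)`),
#' floored at 0 bpm. With probability
#' `dropout_prob` a reading is emitted as a literal 0 bpm, mimicking the
#' zero readings optical trackers produce when the sensor-skin interface is
#' disturbed; downstream matching must filter these. This is a
#' phenomenological stand-in for optical-sensor error, not a physical model
#' of photoplethysmography.
#'
#' @param additive_bias constant bias, bpm.
#' @param proportional_bias unitless slope applied to (truth - resting HR);
#'   negative values reproduce the characteristic pattern of trackers
#'   underestimating more at higher heart rates.
#' @param noise_sd_base noise SD at resting heart rate, bpm.
#' @param noise_sd_slope additional noise SD per bpm of heart rate above
#'   rest.
#' @param dropout_prob per-reading probability of a zero reading, in
#'   \[0, 1\].
#' @param sampling_period seconds between readings; must divide the
#'   10-second epoch (1, 2, 5, or 10).
#' @param seed optional integer; when set, [apply_device_error()] uses it
#'   by default so the same model reproduces the same stream.
#' @return an object of class `device_error_model`.
#' @export
device_error_model <- function(additive_bias = 0, proportional_bias = 0,
                               noise_sd_base = 0, noise_sd_slope = 0,
                               dropout_prob = 0, sampling_period = 1,
                               seed = NULL) {
  stopifnot_scalar_number(additive_bias, "additive_bias")
  stopifnot_scalar_number(proportional_bias, "proportional_bias")
  stopifnot_scalar_number(noise_sd_base, "noise_sd_base", lower = 0)
  stopifnot_scalar_number(noise_sd_slope, "noise_sd_slope", lower = 0)
  stopifnot_scalar_number(dropout_prob, "dropout_prob", 0, 1)
  if (!sampling_period %in% c(1, 2, 5, 10)) {
    stop("`sampling_period` must divide the 10-second epoch (1, 2, 5, or 10)",
         call. = FALSE)
  }
  if (!is.null(seed)) stopifnot_scalar_number(seed, "seed")
  structure(
    list(additive_bias = additive_bias, proportional_bias = proportional_bias,
         noise_sd_base = noise_sd_base, noise_sd_slope = noise_sd_slope,
         dropout_prob = dropout_prob, sampling_period = sampling_period,
         seed = seed),
    class = "device_error_model"
  )
}
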