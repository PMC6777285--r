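# MVPA zone classification at 64% of age-predicted maximum heart rate,
# and the 2x2 criterion-vs-tracker confusion table pooled over
# participants. Each participant is classified against their own
# age-derived threshold; the counts are then pooled.

#' Age-predicted maximum heart rate
#'
#' The common formula 220 - age (years).
#'
#' @param age age in whole years, > 0.
#' @return HRmax in bpm.
#' @export
#' @examples
#' hr_max(30) # 190
hr_max <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("`age` must be positive", call. = FALSE)
  }
  220 - age
}

#' Classify a heart rate into the MVPA zone
#'
#' An epoch is moderate-to-vigorous physical activity (MVPA) when the
#' heart rate reaches at least `cutoff_fraction` (default 64%) of the
#' participant's age-predicted HRmax; the boundary is inclusive.
#'
#' @param hr_bpm heart rate(s), bpm, >= 0.
#' @param age participant age(s), years (recycled against `hr_bpm`).
#' @param cutoff_fraction fraction of HRmax defining the zone boundary.
#' @return character vector, `"mvpa"` or `"below"`.
#' @export
#' @examples
#' classify_epoch(c(121, 121.6), age = 30) # below the cut, exactly at it
classify_epoch <- function(hr_bpm, age, cutoff_fraction = 0.64) {
  if (any(hr_bpm < 0)) stop("`hr_bpm` must be non-negative", call. = FALSE)
  # small slack so a rate exactly at the threshold (e.g. 0.64 x 190 =
  # 121.6 bpm) is classified MVPA despite floating-point representation
  ifelse(hr_bpm >= cutoff_fraction * hr_max(age) - 1e-9, "mvpa", "below")
}

#' Build a confusion table from raw epoch counts
#'
#' `tp` counts epochs both devices place in the MVPA zone, `fn` epochs
#' the criterion places in MVPA but the tracker misses, `fp` the reverse,
#' and `tn` epochs both place below. Sensitivity, specificity, and
#' overall accuracy are percentages rounded half-up to 2 decimals.
#'
#' @param tp,fp,fn,tn non-negative epoch counts.
#' @param cutoff_fraction,hrmax_formula threshold provenance, recorded in
#'   the result.
#' @return an object of class `confusion_table`.
#' @export
#' @examples
#' confusion_table(tp = 2273, fp = 118, fn = 530, tn = 4637)
confusion_table <- function(tp, fp, fn, tn, cutoff_fraction = 0.64,
                            hrmax_formula = "220 - age") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(num / den * 100, 2)
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, n = total,
         sensitivity = pct(tp, tp + fn),
         specificity = pct(tn, tn + fp),
         accuracy = pct(tp + tn, total),
         cutoff_fraction = cutoff_fraction,
         hrmax_formula = hrmax_formula),
    class = "confusion_table"
  )
}

#' MVPA confusion table for matched pairs
#'
#' Classifies every matched epoch under both devices using the owning
#' participant's age-specific threshold, then pools the 2x2 counts.
#'
#' @param pairs pooled `matched_pairs` for one phase and tracker.
#' @param roster data.frame with `participant_id` and `age` covering all
#'   participants present in `pairs`.
#' @param cutoff_fraction fraction of HRmax defining MVPA, default 0.64.
#' @return an object of class `confusion_table`.
#' @export
confusion <- function(pairs, roster, cutoff_fraction = 0.64) {
  idx <- match(pairs$participant_id, roster$participant_id)
  if (anyNA(idx) || anyNA(roster$age[idx])) {
    missing <- unique(pairs$participant_id[is.na(idx) |
                                             is.na(roster$age[idx])])
    stop(sprintf("age missing for participant(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  age <- roster$age[idx]
  crit_mvpa <- classify_epoch(pairs$criterion_bpm, age,
                              cutoff_fraction) == "mvpa"
  trk_mvpa <- classify_epoch(pairs$tracker_bpm, age,
                             cutoff_fraction) == "mvpa"
  confusion_table(tp = sum(crit_mvpa & trk_mvpa),
                  fp = sum(!crit_mvpa & trk_mvpa),
                  fn = sum(crit_mvpa & !trk_mvpa),
                  tn = sum(!crit_mvpa & !trk_mvpa),
                  cutoff_fraction = cutoff_fraction)
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("MVPA confusion (cutoff %.0f%% of HRmax = %s), %d epochs\n",
              x$cutoff_fraction * 100, x$hrmax_formula, x$n))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(criterion = c("mvpa", "below"),
                              tracker = c("mvpa", "below")))
  print(m)
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}
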