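# Method-comparison statistics on matched criterion/tracker pairs.
# Epochs are pooled as rows of a two-way (epoch x device) layout; the ICC
# is the two-way, single-measure, absolute-agreement form ICC(2,1) /
# ICC(A,1), with the F-based confidence interval of McGraw & Wong.

pairs_columns <- function(pairs) {
  need <- c("criterion_bpm", "tracker_bpm")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` must have criterion_bpm and tracker_bpm columns",
         call. = FALSE)
  }
  list(x = as.numeric(pairs$criterion_bpm),
       y = as.numeric(pairs$tracker_bpm))
}

#' Intraclass correlation, absolute agreement, single measures
#'
#' ICC(2,1): two-way layout with matched epochs as rows and the two
#' devices as columns, random epoch effects, absolute agreement so that a
#' systematic offset between devices lowers the coefficient. Mean squares
#' come from the standard two-way ANOVA decomposition,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with k = 2
#' devices, and the confidence interval uses the F-distribution method
#' with Satterthwaite degrees of freedom.
#'
#' @param pairs a `matched_pairs` data.frame (or any data.frame with
#'   `criterion_bpm` and `tracker_bpm`); at least 3 pairs.
#' @param conf_level confidence level, default 0.95.
#' @return list with `icc`, `ci` (lo, hi), `n`, and the mean squares.
#' @export
#' @examples
#' d <- data.frame(criterion_bpm = c(80, 100, 120, 140),
#'                 tracker_bpm = c(80, 100, 120, 140) + 20)
#' icc_absolute_agreement(d)$icc  # 10/13: offset penalised
icc_absolute_agreement <- function(pairs, conf_level = 0.95) {
  v <- pairs_columns(pairs)
  x <- v$x; y <- v$y
  n <- length(x)
  k <- 2
  if (n < 3) stop("at least 3 matched pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("no variance across epochs; ICC undefined, returning 0")
    return(list(icc = 0, ci = c(NA_real_, NA_real_), n = n,
                ms = c(msr = 0, msc = 0, mse = 0)))
  }
  # balanced two-way decomposition in O(n): an explicit factor(epoch)
  # model matrix would be n x n and is infeasible for pooled cohorts
  grand <- mean(c(x, y))
  rowm <- (x + y) / 2
  sst <- sum((x - grand)^2) + sum((y - grand)^2)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * ((mean(x) - grand)^2 + (mean(y) - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  if (mse <= .Machine$double.eps * msr) {
    # exact agreement (or exact affine agreement with zero residual)
    ci <- if (icc == 1) c(1, 1) else c(NA_real_, NA_real_)
    return(list(icc = icc, ci = ci, n = n,
                ms = c(msr = msr, msc = msc, mse = mse)))
  }
  alpha <- 1 - conf_level
  fj <- msc / mse
  num <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  den <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v_df <- num / den
  f_u <- stats::qf(1 - alpha / 2, n - 1, v_df)
  f_l <- stats::qf(1 - alpha / 2, v_df, n - 1)
  lo <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  list(icc = icc, ci = c(lo, hi), n = n,
       ms = c(msr = msr, msc = msc, mse = mse))
}

#' Qualitative label for an ICC
#'
#' Bands: weak below 0.50, moderate from 0.50, strong from 0.75, very
#' strong from 0.90; each boundary belongs to the upper band.
#'
#' @param icc numeric vector of finite ICC values.
#' @return character vector of labels.
#' @export
#' @examples
#' label_icc(c(0.4999, 0.51, 0.83, 0.90))
label_icc <- function(icc) {
  if (any(!is.finite(icc))) stop("`icc` must be finite", call. = FALSE)
  cut(icc, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
      labels = c("weak", "moderate", "strong", "very strong"),
      right = FALSE) |> as.character()
}

#' Epoch-level error metrics
#'
#' Differences are tracker minus criterion throughout, so a tracker that
#' underestimates gives a negative mean difference. MAE is the mean
#' absolute difference in bpm; MAPE is `mean(|diff| / criterion) * 100`;
#' 95% confidence intervals are normal approximations on the epoch-level
#' mean (`mean +/- z * SD / sqrt(n)`), which treat pooled epochs as
#' independent.
#'
#' @param pairs a `matched_pairs` data.frame; criterion values must be
#'   strictly positive (guaranteed after [match_pairs()]).
#' @param conf_level confidence level for the intervals.
#' @param mape_cutoff validity cutoff on MAPE, percent (default 10).
#' @return list with `mae`, `mae_ci`, `mape`, `mean_diff`, `mean_diff_ci`,
#'   `meets_validity_cutoff`, `n`.
#' @export
error_metrics <- function(pairs, conf_level = 0.95, mape_cutoff = 10) {
  v <- pairs_columns(pairs)
  if (any(v$x <= 0)) stop("criterion values must be positive", call. = FALSE)
  d <- v$y - v$x
  n <- length(d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- function(m, s) m + c(-1, 1) * z * s / sqrt(n)
  mae <- mean(abs(d))
  mape <- mean(abs(d) / v$x) * 100
  list(mae = mae, mae_ci = ci(mae, stats::sd(abs(d))),
       mape = mape,
       mean_diff = mean(d), mean_diff_ci = ci(mean(d), stats::sd(d)),
       meets_validity_cutoff = mape <= mape_cutoff, n = n)
}

#' Bland-Altman analysis
#'
#' Differences (tracker minus criterion) against pair means, with 95%
#' limits of agreement `mean(diff) +/- 1.96 * SD(diff)` (sample SD).
#'
#' @param pairs a `matched_pairs` data.frame with at least 2 pairs.
#' @return list with `mean_diff`, `sd_diff`, `loa` (lower, upper), `n`,
#'   and `table`, a data.frame of per-pair `(mean, diff)` for plotting.
#' @export
#' @examples
#' d <- data.frame(criterion_bpm = c(100, 100, 100),
#'                 tracker_bpm = c(98, 100, 102))
#' bland_altman(d)$loa  # -3.92, 3.92
bland_altman <- function(pairs) {
  v <- pairs_columns(pairs)
  n <- length(v$x)
  if (n < 2) stop("at least 2 pairs are required", call. = FALSE)
  d <- v$y - v$x
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
       n = n,
       table = data.frame(mean = (v$x + v$y) / 2, diff = d))
}

#' Flag participants with implausible laboratory correlation
#'
#' Sensitivity-analysis rule: a participant whose laboratory Pearson
#' correlation between tracker and criterion falls below `r_threshold`
#' (default 0.3) likely had a poorly seated device, and agreement can be
#' recomputed with them removed. Participants with fewer than 3 laboratory
#' pairs, or no variance in either device, cannot be assessed and are
#' marked not evaluable.
#'
#' @param lab_pairs pooled `matched_pairs` for the laboratory phase and a
#'   single tracker, with a `participant_id` column.
#' @param r_threshold flagging threshold on Pearson r.
#' @return data.frame with `participant_id`, `n_pairs`, `pearson_r`, and
#'   `status` in `{"ok", "flagged", "not_evaluable"}`.
#' @export
flag_outliers <- function(lab_pairs, r_threshold = 0.3) {
  split_idx <- split(seq_len(nrow(lab_pairs)), lab_pairs$participant_id)
  rows <- lapply(names(split_idx), function(pid) {
    sub <- lab_pairs[split_idx[[pid]], , drop = FALSE]
    n <- nrow(sub)
    r <- NA_real_
    if (n >= 3 && stats::sd(sub$criterion_bpm) > 0 &&
        stats::sd(sub$tracker_bpm) > 0) {
      r <- stats::cor(sub$criterion_bpm, sub$tracker_bpm)
    }
    status <- if (is.na(r)) "not_evaluable"
              else if (r < r_threshold) "flagged" else "ok"
    data.frame(participant_id = pid, n_pairs = n, pearson_r = r,
               status = status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full agreement summary for one phase and tracker
#'
#' Bundles ICC (with CI and qualitative label), MAE, MAPE, mean
#' difference, Bland-Altman limits of agreement, and the 10% MAPE validity
#' judgement into one result. Optionally excludes participants flagged by
#' [flag_outliers()] first (their laboratory pairs must be supplied for
#' the flagging).
#'
#' @param pairs pooled `matched_pairs` for one phase and tracker.
#' @param conf_level confidence level.
#' @param mape_cutoff validity cutoff on MAPE, percent.
#' @param exclude_outliers logical; drop flagged participants.
#' @param lab_pairs laboratory pairs used for flagging when
#'   `exclude_outliers = TRUE` (defaults to `pairs`, correct when `pairs`
#'   is itself the laboratory set).
#' @return an object of class `agreement_result`.
#' @export
agreement <- function(pairs, conf_level = 0.95, mape_cutoff = 10,
                      exclude_outliers = FALSE, lab_pairs = pairs) {
  excluded <- character(0)
  if (exclude_outliers) {
    flags <- flag_outliers(lab_pairs)
    excluded <- flags$participant_id[flags$status == "flagged"]
    pairs <- pairs[!pairs$participant_id %in% excluded, , drop = FALSE]
  }
  icc <- icc_absolute_agreement(pairs, conf_level)
  err <- error_metrics(pairs, conf_level, mape_cutoff)
  ba <- bland_altman(pairs)
  structure(
    list(n_pairs = nrow(pairs),
         icc = icc$icc, icc_ci = icc$ci, icc_label = label_icc(icc$icc),
         mae = err$mae, mae_ci = err$mae_ci,
         mape = err$mape,
         mean_diff = err$mean_diff, mean_diff_ci = err$mean_diff_ci,
         loa = ba$loa, sd_diff = ba$sd_diff,
         meets_validity_cutoff = err$meets_validity_cutoff,
         excluded_participants = excluded),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement over %d matched 10-s epochs\n", x$n_pairs))
  cat(sprintf("  ICC(2,1) %.2f (95%% CI %.2f to %.2f) - %s\n",
              round_half_up(x$icc, 2), x$icc_ci[1], x$icc_ci[2],
              x$icc_label))
  cat(sprintf("  MAE  %.1f bpm (95%% CI %.1f to %.1f)\n",
              round_half_up(x$mae, 1), x$mae_ci[1], x$mae_ci[2]))
  cat(sprintf("  MAPE %.1f%% - %s the 10%% validity cutoff\n",
              round_half_up(x$mape, 1),
              if (x$meets_validity_cutoff) "meets" else "exceeds"))
  cat(sprintf("  Bias %.1f bpm (tracker - criterion), LoA %.1f to %.1f bpm\n",
              round_half_up(x$mean_diff, 1), x$loa[1], x$loa[2]))
  if (length(x$excluded_participants)) {
    cat("  excluded:", paste(x$excluded_participants, collapse = ", "), "\n")
  }
  invisible(x)
}
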