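# Criterion-ranked decile comparison: epochs are ranked by the criterion
# heart rate and split into ten equal-count bins, so decile 1 holds the
# lowest 10% of criterion readings and decile 10 the highest. Tracker
# values are carried along by time match, which is what makes the
# per-decile tracker-minus-criterion difference informative about
# HR-dependent bias.

#' Assign matched epochs to criterion-ranked deciles
#'
#' Equal-count rank split: with n epochs, decile d receives the epochs
#' with ranks in `((d-1) n/10, d n/10]`, giving bin sizes that differ by
#' at most one. Ties in the criterion value are broken by `order_by`
#' (normally the epoch timestamp), making the assignment stable.
#'
#' @param values criterion heart rates over the matched epochs (>= 10).
#' @param order_by tie-breaker, same length as `values`; defaults to
#'   input order.
#' @param n_groups number of bins, default 10.
#' @return integer vector of decile indices (1..`n_groups`) aligned with
#'   `values`.
#' @export
#' @examples
#' assign_deciles(20:1)[1:2]  # the two largest values fall in decile 10
assign_deciles <- function(values, order_by = seq_along(values),
                           n_groups = 10) {
  n <- length(values)
  if (n < n_groups) {
    stop(sprintf("need at least %d epochs to form %d bins", n_groups,
                 n_groups), call. = FALSE)
  }
  ord <- order(values, order_by)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  as.integer(ceiling(rank * n_groups / n))
}

#' Per-decile summary of criterion and tracker heart rates
#'
#' For each criterion decile: five-number summaries (min, lower quartile,
#' median, upper quartile, max) and means of both devices, plus the mean
#' tracker-minus-criterion difference. This is the numeric content of the
#' by-decile box plots used to visualise HR-dependent tracker error.
#'
#' @param pairs pooled `matched_pairs` for one phase and tracker.
#' @param n_groups number of bins, default 10.
#' @return data.frame with one row per decile.
#' @export
decile_summary <- function(pairs, n_groups = 10) {
  dec <- assign_deciles(pairs$criterion_bpm,
                        order_by = as.numeric(pairs$epoch_start %||%
                                                seq_len(nrow(pairs))),
                        n_groups = n_groups)
  five <- function(v, prefix) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    out <- data.frame(mean(v), q[1], q[2], q[3], q[4], q[5])
    names(out) <- paste0(prefix, c("_mean", "_min", "_q1", "_median",
                                   "_q3", "_max"))
    out
  }
  rows <- lapply(seq_len(n_groups), function(d) {
    sub <- pairs[dec == d, , drop = FALSE]
    cbind(data.frame(decile = d, n_epochs = nrow(sub)),
          five(sub$criterion_bpm, "criterion"),
          five(sub$tracker_bpm, "tracker"),
          data.frame(mean_diff = mean(sub$tracker_bpm - sub$criterion_bpm)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
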