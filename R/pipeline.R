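# End-to-end orchestration: (optionally simulate) -> ingest -> epoch ->
# match -> inclusion -> agreement / deciles / zones, with an exclusion
# log and a reproducibility manifest. Epoch counts in and out of every
# filter are logged because the filter accounting is the analysis's
# audit trail.

#' Pipeline run configuration
#'
#' Exactly one of `streams_dir` (+ `roster`) or `simulate` must be given:
#' either point at existing long-format stream CSVs, or describe a
#' synthetic cohort (`simulate = list(n = ...)`, optionally with `lab`,
#' `free`, and `devices` entries forwarded to [generate_cohort()]).
#'
#' @param out_dir directory for all outputs (created if missing).
#' @param seed integer seed controlling simulation and any randomness.
#' @param streams_dir directory of stream CSVs (see [write_stream_csv()]).
#' @param roster path to the roster CSV (`participant_id, age,
#'   resting_hr`); required with `streams_dir`.
#' @param simulate list describing a synthetic cohort; `n` is required.
#' @param phases phases to analyse, subset of `c("lab", "free")`.
#' @param criterion_device device id of the criterion stream.
#' @param min_lab_minutes,min_free_minutes inclusion thresholds, minutes.
#' @param cutoff_fraction MVPA threshold as a fraction of HRmax.
#' @param epoch_rule 10-second extraction rule, see [to_epochs()].
#' @param exclude_outliers drop participants whose laboratory Pearson r
#'   with the criterion falls below 0.3 (see [flag_outliers()]).
#' @param complete_triplets restrict to epochs available from the
#'   criterion and both trackers (requires exactly two trackers).
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, streams_dir = NULL, roster = NULL,
                       simulate = NULL, phases = c("lab", "free"),
                       criterion_device = "criterion",
                       min_lab_minutes = 10, min_free_minutes = 180,
                       cutoff_fraction = 0.64,
                       epoch_rule = c("instantaneous", "window_mean"),
                       exclude_outliers = FALSE,
                       complete_triplets = FALSE) {
  if (is.null(streams_dir) == is.null(simulate)) {
    stop("provide exactly one of `streams_dir` or `simulate`", call. = FALSE)
  }
  if (!is.null(streams_dir) && is.null(roster)) {
    stop("`roster` is required with `streams_dir`", call. = FALSE)
  }
  if (!is.null(simulate) && is.null(simulate$n)) {
    stop("`simulate` must contain `n`", call. = FALSE)
  }
  phases <- match.arg(phases, c("lab", "free"), several.ok = TRUE)
  stopifnot_scalar_number(min_lab_minutes, "min_lab_minutes", lower = 1e-9)
  stopifnot_scalar_number(min_free_minutes, "min_free_minutes", lower = 1e-9)
  stopifnot_scalar_number(cutoff_fraction, "cutoff_fraction", 1e-9, 1)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         streams_dir = streams_dir, roster = roster, simulate = simulate,
         phases = phases, criterion_device = criterion_device,
         min_lab_minutes = min_lab_minutes,
         min_free_minutes = min_free_minutes,
         cutoff_fraction = cutoff_fraction,
         epoch_rule = match.arg(epoch_rule),
         exclude_outliers = isTRUE(exclude_outliers),
         complete_triplets = isTRUE(complete_triplets)),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML or JSON file
#'
#' @param path YAML (or JSON) file whose keys mirror [run_config()]
#'   arguments.
#' @return a validated `run_config`.
#' @export
load_run_config <- function(path) {
  args <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  if (!is.null(args$simulate)) {
    names(args$simulate)[names(args$simulate) == "FALSE"] <- "n"
  }
  do.call(run_config, args)
}

#' Run the full validation pipeline
#'
#' Simulates or loads the cohort, reduces every stream to the 10-second
#' epoch grid, time-matches each tracker to the criterion, applies the
#' minimum-data inclusion rule, and computes agreement statistics, decile
#' summaries, and MVPA confusion tables per phase and tracker, pooled
#' over included participants. Writes `agreement.csv`/`agreement.json`,
#' `deciles.csv`, `confusion.csv`, `exclusions.csv`, `wear_time.csv`, and
#' a `manifest.json` with output checksums; the run is deterministic
#' given the seed.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [load_run_config()]).
#' @return invisibly, a list with the pooled `pairs`, per-stratum
#'   `agreement`, `deciles`, `confusion`, the `exclusions` log, the
#'   `wear` summary, and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config or a path to one", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    sim_dir <- file.path(config$out_dir, "input")
    sim_args <- c(list(n = config$simulate$n, seed = config$seed,
                       out_dir = sim_dir),
                  config$simulate[intersect(names(config$simulate),
                                            c("lab", "free", "devices"))])
    do.call(generate_cohort, sim_args)
    streams_dir <- file.path(sim_dir, "streams")
    roster_path <- file.path(sim_dir, "roster.csv")
  } else {
    streams_dir <- config$streams_dir
    roster_path <- config$roster
  }
  roster <- utils::read.csv(roster_path)

  files <- list.files(streams_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("ingest: no stream CSVs under %s", streams_dir),
         call. = FALSE)
  }
  streams <- lapply(files, read_stream)
  key <- vapply(streams, function(s)
    paste(s$participant_id, s$phase, s$device_id, sep = "\r"), "")
  names(streams) <- key
  devices <- unique(vapply(streams, function(s) s$device_id, ""))
  trackers <- setdiff(devices, config$criterion_device)
  if (!config$criterion_device %in% devices) {
    stop(sprintf("ingest: no streams for criterion device '%s'",
                 config$criterion_device), call. = FALSE)
  }
  if (config$complete_triplets && length(trackers) != 2L) {
    stop("complete_triplets mode requires exactly two trackers",
         call. = FALSE)
  }
  participants <- unique(vapply(streams, function(s) s$participant_id, ""))

  # epoch, match, inclusion -- with per-filter accounting
  pooled <- list()
  exclusions <- list()
  wear_rows <- list()
  for (pid in sort(participants)) {
    for (ph in config$phases) {
      ck <- paste(pid, ph, config$criterion_device, sep = "\r")
      if (!ck %in% key) next
      crit_ep <- to_epochs(streams[[ck]], rule = config$epoch_rule)
      wear_rows[[length(wear_rows) + 1L]] <-
        data.frame(participant_id = pid, phase = ph,
                   device_id = config$criterion_device,
                   wear_hours = wear_time(crit_ep))
      for (trk in trackers) {
        tk <- paste(pid, ph, trk, sep = "\r")
        if (!tk %in% key) next
        trk_ep <- to_epochs(streams[[tk]], rule = config$epoch_rule)
        wear_rows[[length(wear_rows) + 1L]] <-
          data.frame(participant_id = pid, phase = ph, device_id = trk,
                     wear_hours = wear_time(trk_ep))
        pairs <- match_pairs(crit_ep, trk_ep)
        incl <- apply_inclusion(pairs, phase = ph,
                                min_lab_minutes = config$min_lab_minutes,
                                min_free_minutes = config$min_free_minutes)
        if (incl$included) {
          pooled[[paste(ph, trk, sep = "\r")]] <-
            rbind(pooled[[paste(ph, trk, sep = "\r")]], pairs)
        } else {
          exclusions[[length(exclusions) + 1L]] <-
            data.frame(participant_id = pid, phase = ph, tracker = trk,
                       n_pairs = incl$n_pairs, min_epochs = incl$min_epochs,
                       reason = incl$reason)
        }
      }
    }
  }
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions)
                else data.frame(participant_id = character(0),
                                phase = character(0), tracker = character(0),
                                n_pairs = integer(0), min_epochs = numeric(0),
                                reason = character(0))

  if (config$complete_triplets) {
    for (ph in config$phases) {
      ka <- paste(ph, trackers[1], sep = "\r")
      kb <- paste(ph, trackers[2], sep = "\r")
      if (!is.null(pooled[[ka]]) && !is.null(pooled[[kb]])) {
        both <- complete_triplets(pooled[[ka]], pooled[[kb]])
        pooled[[ka]] <- both[[1]]
        pooled[[kb]] <- both[[2]]
      }
    }
  }

  # outlier flagging on laboratory pairs, applied per tracker to all phases
  dropped <- list()
  if (config$exclude_outliers) {
    for (trk in trackers) {
      lab_key <- paste("lab", trk, sep = "\r")
      if (is.null(pooled[[lab_key]])) next
      flags <- flag_outliers(pooled[[lab_key]])
      bad <- flags$participant_id[flags$status == "flagged"]
      dropped[[trk]] <- bad
      if (length(bad)) {
        for (ph in config$phases) {
          k <- paste(ph, trk, sep = "\r")
          if (!is.null(pooled[[k]])) {
            pooled[[k]] <-
              pooled[[k]][!pooled[[k]]$participant_id %in% bad, ,
                          drop = FALSE]
          }
        }
      }
    }
  }

  # statistics per phase x tracker
  agree_rows <- list(); dec_rows <- list(); conf_rows <- list()
  results <- list()
  for (k in names(pooled)) {
    pairs <- pooled[[k]]
    if (is.null(pairs) || nrow(pairs) < 10) next
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    ph <- parts[1]; trk <- parts[2]
    agr <- agreement(pairs)
    dec <- decile_summary(pairs)
    cnf <- confusion(pairs, roster, cutoff_fraction = config$cutoff_fraction)
    results[[paste(ph, trk, sep = ".")]] <-
      list(agreement = agr, deciles = dec, confusion = cnf)
    agree_rows[[k]] <- data.frame(
      phase = ph, tracker = trk, n_pairs = agr$n_pairs,
      icc = round_half_up(agr$icc, 2),
      icc_lo = round_half_up(agr$icc_ci[1], 2),
      icc_hi = round_half_up(agr$icc_ci[2], 2),
      icc_label = agr$icc_label,
      mae_bpm = round_half_up(agr$mae, 1),
      mape_pct = round_half_up(agr$mape, 1),
      mean_diff_bpm = round_half_up(agr$mean_diff, 1),
      loa_lower = round_half_up(agr$loa[1], 1),
      loa_upper = round_half_up(agr$loa[2], 1),
      meets_validity_cutoff = agr$meets_validity_cutoff,
      n_excluded_outliers = length(dropped[[trk]] %||% character(0)))
    dec_rows[[k]] <- cbind(data.frame(phase = ph, tracker = trk), dec)
    conf_rows[[k]] <- data.frame(
      phase = ph, tracker = trk, tp = cnf$tp, fp = cnf$fp, fn = cnf$fn,
      tn = cnf$tn, sensitivity = cnf$sensitivity,
      specificity = cnf$specificity, accuracy = cnf$accuracy)
  }
  if (length(results) == 0L) {
    stop("statistics: no phase/tracker stratum passed inclusion",
         call. = FALSE)
  }

  wear <- do.call(rbind, wear_rows)
  wear_summary <- stats::aggregate(wear_hours ~ phase + device_id, wear,
                                   function(h) round(mean(h), 2))

  paths <- list(
    agreement_csv = file.path(config$out_dir, "agreement.csv"),
    agreement_json = file.path(config$out_dir, "agreement.json"),
    deciles_csv = file.path(config$out_dir, "deciles.csv"),
    confusion_csv = file.path(config$out_dir, "confusion.csv"),
    exclusions_csv = file.path(config$out_dir, "exclusions.csv"),
    wear_csv = file.path(config$out_dir, "wear_time.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  agree_df <- do.call(rbind, agree_rows); rownames(agree_df) <- NULL
  utils::write.csv(agree_df, paths$agreement_csv, row.names = FALSE)
  jsonlite::write_json(agree_df, paths$agreement_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  dec_df <- do.call(rbind, dec_rows); rownames(dec_df) <- NULL
  utils::write.csv(dec_df, paths$deciles_csv, row.names = FALSE)
  conf_df <- do.call(rbind, conf_rows); rownames(conf_df) <- NULL
  utils::write.csv(conf_df, paths$confusion_csv, row.names = FALSE)
  utils::write.csv(exclusions, paths$exclusions_csv, row.names = FALSE)
  utils::write.csv(wear_summary, paths$wear_csv, row.names = FALSE)

  cfg_flat <- config
  cfg_flat$simulate <- if (is.null(config$simulate)) NULL
                       else list(n = config$simulate$n)
  manifest <- list(
    package = "hrconcord",
    package_version = as.character(utils::packageVersion("hrconcord")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(cfg_flat),
    outputs = as.list(tools::md5sum(unlist(paths[names(paths) !=
                                                   "manifest"])))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(pairs = pooled, results = results, agreement = agree_df,
                 deciles = dec_df, confusion = conf_df,
                 exclusions = exclusions, wear = wear_summary,
                 paths = paths))
}
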