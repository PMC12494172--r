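#' Read a gaze stream from a tab-separated table
#'
#' Expected columns: `timestamp_ms`, `x_deg`, `y_deg`, `valid` (0/1 or
#' logical). Timestamps must be strictly increasing.
#'
#' @param path file path.
#' @return gaze stream data frame (`time_ms`, `x`, `y`, `valid`).
#' @export
read_gaze_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(utils::read.delim(path, check.names = FALSE),
                error = function(e) stop("unparseable gaze table ", path, ": ",
                                         conditionMessage(e)))
  req <- c("timestamp_ms", "x_deg", "y_deg", "valid")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("gaze table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0) stop("empty gaze table: ", path)
  bad <- which(!is.finite(d$timestamp_ms))
  if (length(bad)) stop("unparseable timestamp at row ", bad[1])
  if (nrow(d) > 1 && any(diff(d$timestamp_ms) <= 0)) {
    r <- which(diff(d$timestamp_ms) <= 0)[1] + 1L
    stop("non-monotone timestamps at row ", r)
  }
  data.frame(time_ms = d$timestamp_ms, x = d$x_deg, y = d$y_deg,
             valid = as.logical(d$valid))
}

#' Write a gaze stream as a tab-separated table
#' @param stream gaze stream data frame.
#' @param path output path.
#' @export
write_gaze_table <- function(stream, path) {
  out <- data.frame(timestamp_ms = stream$time_ms, x_deg = stream$x,
                    y_deg = stream$y, valid = as.integer(stream$valid))
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a trial event log (BIDS-events-like TSV)
#'
#' Columns: `onset` (s, CS onset), `duration` (s), `trial_type`
#' (`cs1`..`cs4`), `orientation`, plus bookkeeping columns `trial`,
#' `shaping`, `exp_index`, `cs_value`.
#'
#' @param schedule trial schedule data frame ([gen_trial_schedule()]).
#' @param path file path.
#' @return `read_events` returns a schedule data frame.
#' @export
write_events <- function(schedule, path) {
  out <- data.frame(onset = schedule$cs_onset_ms / 1000,
                    duration = (schedule$cs_offset_ms - schedule$cs_onset_ms) / 1000,
                    trial_type = paste0("cs", schedule$cs_type),
                    orientation = schedule$orientation,
                    trial = schedule$trial, shaping = as.integer(schedule$shaping),
                    exp_index = schedule$exp_index, cs_value = schedule$cs_value,
                    trial_start_ms = schedule$trial_start_ms)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, na.strings = "n/a")
  req <- c("onset", "duration", "trial_type", "orientation")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("events file missing column(s): ", paste(miss, collapse = ", "))
  cs_onset <- d$onset * 1000
  t0 <- if ("trial_start_ms" %in% names(d)) d$trial_start_ms else cs_onset - TRIAL_PHASES[["fix"]]
  data.frame(trial = d$trial %||% seq_len(nrow(d)),
             shaping = as.logical(d$shaping %||% 0),
             exp_index = d$exp_index,
             cs_type = as.integer(sub("^cs", "", d$trial_type)),
             cs_value = d$cs_value,
             orientation = d$orientation,
             trial_start_ms = t0,
             cs_onset_ms = cs_onset,
             cs_offset_ms = cs_onset + d$duration * 1000,
             ucs_onset_ms = t0 + sum(TRIAL_PHASES[c("fix", "cs", "fix2")]),
             ucs_offset_ms = t0 + sum(TRIAL_PHASES[c("fix", "cs", "fix2", "ucs")]),
             trial_end_ms = t0 + TRIAL_LEN)
}

#' Read/write numeric matrices as TSV with a header row
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  colnames(m) <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Write a simulated study to disk as plain-text tables
#'
#' Layout per participant: gaze stream TSV, events TSV, per-run timecourse
#' and confound TSVs; study-level covariate CSV and a ground-truth JSON
#' sidecar. A YAML manifest records the configuration.
#'
#' @param study a `synthetic_study` ([simulate_study()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- study$config$n_participants
  ids <- study$covariates$participant
  for (p in seq_len(n)) {
    pd <- file.path(dir, ids[p])
    dir.create(pd, showWarnings = FALSE)
    write_events(study$schedules[[p]], file.path(pd, "events.tsv"))
    if (!is.null(study$gaze))
      write_gaze_table(study$gaze[[p]], file.path(pd, "gaze.tsv"))
    for (run in names(study$runs[[p]])) {
      rd <- study$runs[[p]][[run]]
      write_matrix_tsv(rd$timecourses, file.path(pd, paste0("timecourses_", run, ".tsv")))
      utils::write.table(rd$confounds, file.path(pd, paste0("confounds_", run, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  gt <- study$ground_truth
  jsonlite::write_json(
    list(theta = gt$theta,
         true_edges = as.data.frame(gt$true_edges) |> stats::setNames(c("i", "j")),
         true_whr_slope = gt$true_whr_slope),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  cfg <- study$config
  cfg$planted_edges <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study written by [write_study()]
#' @param dir study directory.
#' @return a `synthetic_study`-shaped list (without regenerating RNG state).
#' @export
read_study <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  covars <- utils::read.csv(file.path(dir, "covariates.csv"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  ids <- covars$participant
  schedules <- list(); gaze <- list(); runs <- list()
  for (p in seq_along(ids)) {
    pd <- file.path(dir, ids[p])
    schedules[[p]] <- read_events(file.path(pd, "events.tsv"))
    gp <- file.path(pd, "gaze.tsv")
    gaze[[p]] <- if (file.exists(gp)) read_gaze_table(gp) else NULL
    runs[[p]] <- list()
    for (run in c("sweet", "savory")) {
      tp <- file.path(pd, paste0("timecourses_", run, ".tsv"))
      if (file.exists(tp)) {
        conf <- utils::read.delim(file.path(pd, paste0("confounds_", run, ".tsv")),
                                  check.names = FALSE)
        runs[[p]][[run]] <- list(timecourses = unname(read_matrix_tsv(tp)),
                                 confounds = conf,
                                 fd = conf$framewise_displacement)
      }
    }
  }
  structure(list(config = do.call(study_config, cfg[names(cfg) %in% names(formals(study_config))]),
                 layout = aoi_layout(),
                 ground_truth = list(theta = gt$theta,
                                     true_edges = as.matrix(gt$true_edges),
                                     true_whr_slope = gt$true_whr_slope),
                 schedules = schedules,
                 gaze = if (all(vapply(gaze, is.null, logical(1)))) NULL else gaze,
                 covariates = covars, runs = runs),
            class = "synthetic_study")
}
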