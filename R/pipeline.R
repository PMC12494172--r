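#' End-to-end analysis pipeline
#'
#' Runs the full chain on a study (in memory from [simulate_study()] or read
#' from disk with [read_study()]): gaze quality control and fixation
#' classification, per-trial AOI summaries with the trial-exclusion rule,
#' per-participant ST/GT coefficients and group assignment, the adjusted
#' WHR/BMI association models, per-run connectivity matrices with motion
#' scrubbing and the >25% spike exclusion, and one CPM per run condition.
#' A manifest records, for every participant, a terminal status
#' (`completed` or `excluded:<rule>`) plus per-run exclusion decisions.
#'
#' @param study a `synthetic_study` or study directory path.
#' @param gaze_quality_min participant-level minimum gaze-sample percentage
#'   (default 80).
#' @param velocity_threshold,min_duration I-VT parameters
#'   ([classify_fixations()]).
#' @param keep_per_cs_type trial-exclusion parameter ([apply_exclusions()]).
#' @param fd_threshold,max_spike_fraction motion scrubbing parameters
#'   ([process_run()]).
#' @param cpm_threshold,n_permutations,consensus_fraction CPM parameters
#'   ([cpm()]).
#' @param seed RNG seed for the permutation test.
#' @param out_dir optional directory for result files (phenotype CSV,
#'   manifest JSON, consensus edge TSVs).
#' @return list of class `pipeline_result`: `phenotypes` (per-participant
#'   slope/group), `adiposity` (WHR and BMI model fits), `connectivity`
#'   (per condition, per participant), `cpm` (per condition), `manifest`.
#' @export
run_pipeline <- function(study,
                         gaze_quality_min = 80,
                         velocity_threshold = 30, min_duration = 50,
                         keep_per_cs_type = 12,
                         fd_threshold = 0.5, max_spike_fraction = 0.25,
                         cpm_threshold = 0.3, n_permutations = 0,
                         consensus_fraction = 0.9, seed = 1L,
                         out_dir = NULL) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(study$gaze)) stop("study contains no gaze streams")
  n <- study$config$n_participants
  ids <- study$covariates$participant
  layout <- study$layout

  status <- setNames(rep("completed", n), ids)
  slopes <- rep(NA_real_, n); n_used <- rep(NA_integer_, n)
  quality <- rep(NA_real_, n)

  for (p in seq_len(n)) {
    stream <- study$gaze[[p]]
    quality[p] <- gaze_sample_quality(stream)
    if (quality[p] < gaze_quality_min) {
      status[p] <- "excluded:gaze_quality"
      next
    }
    fx <- classify_fixations(stream, velocity_threshold, min_duration)
    summ <- session_summaries(study$schedules[[p]], fx, layout)
    kept <- apply_exclusions(summ, keep_per_cs_type)
    fit <- tryCatch(stgt_coefficient(kept$cs_value, kept$gaze_index),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$usable) {
      status[p] <- "excluded:too_few_trials"
      next
    }
    slopes[p] <- fit$slope
    n_used[p] <- fit$n_trials_used
  }

  ok <- status == "completed"
  phenotypes <- data.frame(participant = ids, gaze_quality = quality,
                           stgt_slope = slopes, n_trials_used = n_used,
                           group = NA_character_)
  if (sum(ok) >= 5)
    phenotypes$group[ok] <- as.character(assign_groups(slopes[ok]))
  phenotypes$group[!ok] <- "excluded"

  covars <- cbind(study$covariates, stgt_slope = slopes)
  adiposity <- list()
  if (sum(ok) >= 8) {
    adiposity$whr <- adiposity_model(covars[ok, ], predictor = "whr")
    adiposity$bmi <- adiposity_model(covars[ok, ], predictor = "bmi")
  }

  conditions <- names(study$runs[[1]])
  connectivity <- list(); cpm_fits <- list()
  run_status <- list()
  for (cond in conditions) {
    mats <- vector("list", n)
    for (p in which(ok)) {
      rd <- study$runs[[p]][[cond]]
      cm <- process_run(rd$timecourses, rd$confounds, fd = rd$fd,
                        fd_threshold = fd_threshold,
                        max_spike_fraction = max_spike_fraction)
      mats[[p]] <- cm
      run_status[[cond]][[ids[p]]] <- if (is.null(cm)) "excluded:motion" else "kept"
    }
    use <- which(ok & !vapply(mats, is.null, logical(1)))
    connectivity[[cond]] <- mats
    if (length(use) >= 10) {
      cpm_fits[[cond]] <- cpm(
        mats[use], slopes[use],
        covariates = study$covariates[use, c("age", "sex", "run_order", "hunger", "whr", "scanner")],
        threshold = cpm_threshold, n_permutations = n_permutations,
        consensus_fraction = consensus_fraction,
        seed = derive_seed(seed, paste0("cpm-", cond)))
      attr(cpm_fits[[cond]], "participants") <- ids[use]
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("signtrack")),
    seed = seed,
    parameters = list(gaze_quality_min = gaze_quality_min,
                      velocity_threshold = velocity_threshold,
                      min_duration = min_duration,
                      keep_per_cs_type = keep_per_cs_type,
                      fd_threshold = fd_threshold,
                      max_spike_fraction = max_spike_fraction,
                      cpm_threshold = cpm_threshold,
                      n_permutations = n_permutations,
                      consensus_fraction = consensus_fraction),
    participants = as.list(status),
    runs = run_status)

  res <- structure(list(phenotypes = phenotypes, adiposity = adiposity,
                        connectivity = connectivity, cpm = cpm_fits,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  st <- unlist(x$manifest$participants)
  cat("  participants:", length(st), "(", sum(st == "completed"), "completed )\n")
  for (cond in names(x$cpm)) {
    f <- x$cpm[[cond]]
    cat(sprintf("  CPM [%s]: accuracy pos %.3f / neg %.3f%s\n", cond,
                f$accuracy["pos"], f$accuracy["neg"],
                if (!is.null(f$p_value))
                  sprintf(", perm p pos %.3g / neg %.3g",
                          f$p_value["pos"], f$p_value["neg"]) else ""))
  }
  invisible(x)
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$phenotypes, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (cond in names(res$cpm)) {
    cons <- consensus_network(res$cpm[[cond]])
    for (sign in c("pos", "neg")) {
      df <- cons[[sign]]
      if (nrow(df))
        utils::write.table(df, file.path(out_dir, sprintf("consensus_%s_%s.tsv", cond, sign)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    bundle <- list(condition = cond,
                   accuracy = as.list(res$cpm[[cond]]$accuracy),
                   p_value = as.list(res$cpm[[cond]]$p_value),
                   n_permutations = res$cpm[[cond]]$n_permutations,
                   threshold = res$cpm[[cond]]$threshold)
    jsonlite::write_json(bundle, file.path(out_dir, sprintf("cpm_%s.json", cond)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
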