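#' Configuration for a synthetic conditioning + connectivity study
#'
#' Holds every generative parameter for a simulated study: the Pavlovian task
#' structure (4 fractal CS types with reward values 2, 1, 0, 0 and 16
#' experimental trials each), the latent sign-tracking propensity theta
#' driving gaze allocation, the linear coupling of waist-to-hip ratio (WHR)
#' to theta, and a planted set of node pairs whose functional coupling scales
#' with theta.
#'
#' The defaults are the study conditions used throughout the package's tests:
#' `planted_effect` (gamma) and `whr_slope` have no empirical anchor — the
#' source task reports no effect-size scale linking gaze behavior to
#' connectivity — so they are fixed, documented free parameters.
#'
#' @param n_participants number of participants (default 47, a typical
#'   analytic sample for this design).
#' @param n_nodes parcellation nodes per timecourse matrix (default 220).
#' @param n_volumes fMRI volumes per run (default 250, ~8.4 min at TR 2.01 s).
#' @param trial_counts experimental trials per CS type (default 16).
#' @param cs_values reward value of each CS type (default `c(2, 1, 0, 0)`).
#' @param propensity_sd dispersion of the latent propensity theta.
#' @param whr_slope linear coupling of WHR on theta (WHR units per theta SD).
#' @param whr_intercept mean WHR at theta = 0.
#' @param whr_noise_sd residual WHR noise SD.
#' @param planted_edges two-column matrix/data frame of 0-based node pairs
#'   whose coupling scales with theta; `NULL` picks `n_planted` distinct
#'   cross-block pairs at random when the study is simulated.
#' @param n_planted number of planted edges when `planted_edges` is `NULL`.
#' @param planted_effect coupling magnitude gamma.
#' @param noise_sd observation noise SD for node timecourses.
#' @param fd_spike_frac expected fraction of high-motion (FD > 0.5 mm)
#'   volumes per run.
#' @param seed RNG seed for the study.
#' @return object of class `study_config` (a validated list).
#' @export
study_config <- function(n_participants = 47, n_nodes = 220, n_volumes = 250,
                         trial_counts = 16, cs_values = c(2, 1, 0, 0),
                         propensity_sd = 1, whr_slope = 0.06,
                         whr_intercept = 0.85, whr_noise_sd = 0.05,
                         planted_edges = NULL, n_planted = 30,
                         planted_effect = 0.5, noise_sd = 1,
                         fd_spike_frac = 0.02, seed = 1L) {
  stopifnot(n_participants >= 1, n_nodes >= 2, n_volumes >= 10, trial_counts >= 1,
            propensity_sd > 0, noise_sd > 0, fd_spike_frac >= 0, fd_spike_frac <= 1)
  if (!any(cs_values == 0) || !any(cs_values > 0))
    stop("cs_values must contain at least one zero and one positive value")
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (ncol(planted_edges) != 2) stop("planted_edges must have two columns")
    if (any(planted_edges < 0) || any(planted_edges >= n_nodes))
      stop("planted_edges reference nodes outside 0..n_nodes-1")
    if (any(planted_edges[, 1] == planted_edges[, 2]))
      stop("planted_edges must join distinct nodes")
  }
  structure(list(
    n_participants = as.integer(n_participants), n_nodes = as.integer(n_nodes),
    n_volumes = as.integer(n_volumes), trial_counts = as.integer(trial_counts),
    cs_values = cs_values, propensity_sd = propensity_sd,
    whr_slope = whr_slope, whr_intercept = whr_intercept,
    whr_noise_sd = whr_noise_sd, planted_edges = planted_edges,
    n_planted = as.integer(n_planted), planted_effect = planted_effect,
    noise_sd = noise_sd, fd_spike_frac = fd_spike_frac,
    seed = as.integer(seed)), class = "study_config")
}

# Task phase durations, ms (fixation, CS, double fixation, UCS, inter-trial).
TRIAL_PHASES <- c(fix = 1500, cs = 3000, fix2 = 1500, ucs = 3000, iti = 7500)
TRIAL_LEN <- sum(TRIAL_PHASES)

#' Generate the Pavlovian conditioning trial schedule
#'
#' Eight shaping trials present the four CS-UCS pairings in descending then
#' ascending reward order; the experimental phase then presents each CS type
#' `trial_counts` times in pseudorandomized blocks of four (each pairing once
#' per block before any repetition). Halfway through the experimental trials
#' the monitor/candy-machine orientation switches from CS-left to CS-right.
#' Per trial: 1.5 s fixation, 3 s CS, 1.5 s double fixation, 3 s UCS
#' delivery, 7.5 s inter-trial interval.
#'
#' @param config a [study_config()].
#' @param seed RNG seed for the block pseudorandomization (defaults to the
#'   config seed).
#' @return data frame with one row per trial: `trial`, `shaping`,
#'   `exp_index` (1..64 for experimental trials, NA for shaping), `cs_type`,
#'   `cs_value`, `orientation`, and ms timing columns `trial_start_ms`,
#'   `cs_onset_ms`, `cs_offset_ms`, `ucs_onset_ms`, `ucs_offset_ms`,
#'   `trial_end_ms`.
#' @examples
#' sched <- gen_trial_schedule(study_config())
#' nrow(sched)                      # 72 = 8 shaping + 64 experimental
#' table(sched$cs_type[!sched$shaping])
#' @export
gen_trial_schedule <- function(config = study_config(), seed = config$seed) {
  k <- length(config$cs_values)
  desc <- order(config$cs_values, decreasing = TRUE)  # stable: ties keep type order
  shaping_types <- c(desc, rev(desc))
  n_blocks <- config$trial_counts
  rng <- local({ set.seed(derive_seed(seed, "schedule"));
                 unlist(lapply(seq_len(n_blocks), function(b) sample.int(k))) })
  types <- c(shaping_types, rng)
  n_total <- length(types)
  n_exp <- k * n_blocks
  shaping <- c(rep(TRUE, 2 * k), rep(FALSE, n_exp))
  exp_index <- ifelse(shaping, NA_integer_, seq_len(n_total) - 2L * k)
  orientation <- ifelse(shaping | exp_index <= n_exp / 2, "cs_left", "cs_right")
  orientation[is.na(orientation)] <- "cs_left"
  t0 <- (seq_len(n_total) - 1) * TRIAL_LEN
  data.frame(
    trial = seq_len(n_total), shaping = shaping, exp_index = exp_index,
    cs_type = types, cs_value = config$cs_values[types],
    orientation = orientation,
    trial_start_ms = t0,
    cs_onset_ms = t0 + TRIAL_PHASES[["fix"]],
    cs_offset_ms = t0 + TRIAL_PHASES[["fix"]] + TRIAL_PHASES[["cs"]],
    ucs_onset_ms = t0 + sum(TRIAL_PHASES[c("fix", "cs", "fix2")]),
    ucs_offset_ms = t0 + sum(TRIAL_PHASES[c("fix", "cs", "fix2", "ucs")]),
    trial_end_ms = t0 + TRIAL_LEN)
}

# Random point inside a rectangle, away from the border by `pad`.
runif_rect <- function(r, pad = 0.5) {
  c(stats::runif(1, r[1] + pad, r[2] - pad), stats::runif(1, r[3] + pad, r[4] - pad))
}

# A background location outside both AOIs (near screen centre or periphery).
bg_point <- function(layout) {
  repeat {
    p <- c(stats::runif(1, -4, 4), stats::runif(1, -8, 8))
    if (assign_aoi(p, layout, "cs_left") == "BG" &&
        assign_aoi(p, layout, "cs_right") == "BG") return(p)
  }
}

#' Simulate a 50 Hz gaze recording for one participant
#'
#' The session is built as a sequence of fixation segments (300-700 ms) whose
#' targets depend on the trial phase: orienting to the CS just after onset,
#' then — in the late-CS analysis window of rewarding trials — on the CS AOI
#' with probability `plogis(theta)` and otherwise mostly the UCS location;
#' on zero-value trials late-window gaze favors the UCS/background
#' independently of theta. Segment centres are jittered sample-to-sample well
#' below the saccade velocity threshold, and segment transitions are
#' instantaneous jumps that exceed it. Blinks are injected as invalid-sample
#' runs of 60-200 ms at Poisson times. AOI coordinates honour the
#' orientation switch (mirrored scene in the CS-right half).
#'
#' @param schedule trial schedule from [gen_trial_schedule()].
#' @param theta latent sign-tracking propensity of this participant.
#' @param layout an [aoi_layout()].
#' @param seed RNG seed.
#' @param sampling_rate_hz sampling rate (default 50).
#' @param jitter_sd within-fixation positional jitter SD in degrees.
#' @param blink_rate_hz expected blinks per second (default 0.15).
#' @return gaze stream data frame (`time_ms`, `x`, `y`, `valid`).
#' @export
gen_gaze_session <- function(schedule, theta, layout = aoi_layout(), seed = 1L,
                             sampling_rate_hz = 50, jitter_sd = 0.05,
                             blink_rate_hz = 0.15) {
  stopifnot(inherits(layout, "aoi_layout"))
  set.seed(derive_seed(seed, "gaze"))
  p_cs_reward <- stats::plogis(theta)

  session_end <- max(schedule$trial_end_ms)
  dt <- 1000 / sampling_rate_hz

  # Build the segment table trial by trial, phase by phase.
  seg_start <- numeric(0); seg_cx <- numeric(0); seg_cy <- numeric(0)
  add_phase <- function(t0, t1, pick_target) {
    starts <- c(); cx <- c(); cy <- c()
    t <- t0
    while (t < t1) {
      len <- stats::runif(1, 300, 700)
      p <- pick_target()
      starts <- c(starts, t); cx <- c(cx, p[1]); cy <- c(cy, p[2])
      t <- t + len
    }
    list(starts = starts, cx = cx, cy = cy)
  }

  for (r in seq_len(nrow(schedule))) {
    tr <- schedule[r, ]
    mirrored <- tr$orientation == "cs_right"
    cs_rect <- if (mirrored) mirror_rect(layout$cs) else layout$cs
    ucs_rect <- if (mirrored) mirror_rect(layout$ucs) else layout$ucs
    rewarding <- tr$cs_value > 0

    pick_bg <- function() bg_point(layout)
    pick_cs <- function() runif_rect(cs_rect)
    pick_ucs <- function() runif_rect(ucs_rect)
    # early CS: orienting response toward the CS, phenotype-independent
    pick_early <- function() if (stats::runif(1) < 0.7) pick_cs() else pick_bg()
    pick_late <- if (rewarding) {
      function() {
        if (stats::runif(1) < p_cs_reward) pick_cs()
        else if (stats::runif(1) < 0.8) pick_ucs() else pick_bg()
      }
    } else {
      function() {
        u <- stats::runif(1)
        if (u < 0.15) pick_cs() else if (u < 0.60) pick_ucs() else pick_bg()
      }
    }

    phases <- list(
      list(tr$trial_start_ms, tr$cs_onset_ms, pick_bg),
      list(tr$cs_onset_ms, tr$cs_onset_ms + 1500, pick_early),
      list(tr$cs_onset_ms + 1500, tr$cs_offset_ms, pick_late),
      list(tr$cs_offset_ms, tr$ucs_onset_ms, pick_bg),
      list(tr$ucs_onset_ms, tr$ucs_offset_ms, pick_ucs),
      list(tr$ucs_offset_ms, tr$trial_end_ms, pick_bg))
    for (ph in phases) {
      sg <- add_phase(ph[[1]], ph[[2]], ph[[3]])
      seg_start <- c(seg_start, sg$starts)
      seg_cx <- c(seg_cx, sg$cx); seg_cy <- c(seg_cy, sg$cy)
    }
  }

  o <- order(seg_start)
  seg_start <- seg_start[o]; seg_cx <- seg_cx[o]; seg_cy <- seg_cy[o]

  time_ms <- seq(0, session_end - dt, by = dt)
  seg_id <- findInterval(time_ms, seg_start)
  seg_id[seg_id == 0] <- 1L
  n <- length(time_ms)
  x <- seg_cx[seg_id] + stats::rnorm(n, 0, jitter_sd)
  y <- seg_cy[seg_id] + stats::rnorm(n, 0, jitter_sd)

  valid <- rep(TRUE, n)
  n_blinks <- stats::rpois(1, blink_rate_hz * session_end / 1000)
  if (n_blinks > 0) {
    b_start <- stats::runif(n_blinks, 0, session_end)
    b_len <- stats::runif(n_blinks, 60, 200)
    for (b in seq_len(n_blinks))
      valid[time_ms >= b_start[b] & time_ms < b_start[b] + b_len[b]] <- FALSE
  }
  data.frame(time_ms = time_ms, x = x, y = y, valid = valid)
}

#' Simulate participant covariates
#'
#' WHR is linearly coupled to the latent propensity
#' (`whr = intercept + whr_slope * theta + noise`); age, sex, pre-task
#' hunger, scanner and run order are drawn independently with realistic
#' marginals for a healthy-adult sample.
#'
#' @param config a [study_config()].
#' @param theta latent propensities (length `n_participants`).
#' @param seed RNG seed.
#' @return data frame: `participant`, `age`, `sex` ("female"/"male"),
#'   `hunger` (0-100 visual-analogue), `whr`, `bmi`, `scanner` ("A"/"B"),
#'   `run_order` ("sweet_first"/"savory_first").
#' @export
gen_covariates <- function(config, theta, seed = config$seed) {
  set.seed(derive_seed(seed, "covariates"))
  n <- config$n_participants
  stopifnot(length(theta) == n)
  data.frame(
    participant = sprintf("sub-%03d", seq_len(n)),
    age = round(pmax(18, stats::rnorm(n, 25.3, 5.8)), 1),
    sex = ifelse(stats::runif(n) < 0.66, "female", "male"),
    hunger = round(stats::runif(n, 0, 100)),
    whr = config$whr_intercept + config$whr_slope * theta +
      stats::rnorm(n, 0, config$whr_noise_sd),
    bmi = round(pmax(17, stats::rnorm(n, 25.2, 3.6)), 1),
    scanner = sample(c("A", "B"), n, replace = TRUE),
    run_order = sample(c("sweet_first", "savory_first"), n, replace = TRUE))
}

# Block-structured factor loadings mimicking canonical-network organisation:
# nodes are split into 10 contiguous blocks, each loading mainly on its own
# latent factor.
network_loadings <- function(n_nodes, k = 10) {
  blocks <- sort(rep_len(seq_len(k), n_nodes))
  L <- matrix(0.1, n_nodes, k)
  L[cbind(seq_len(n_nodes), blocks)] <- 0.8
  L
}

#' Canonical-network labels for synthetic parcellations
#'
#' Assigns the `n_nodes` synthetic nodes to the ten canonical networks
#' (medial-frontal, fronto-parietal, default mode, motor, primary visual,
#' secondary visual, visual association, salience, subcortical, cerebellar)
#' in contiguous blocks matching the generator's factor structure.
#'
#' @param n_nodes number of nodes.
#' @return character vector of length `n_nodes` with levels
#'   MF, FP, DMN, Mot, VI, VII, VAs, SAL, SC, CBL.
#' @export
synthetic_atlas <- function(n_nodes) {
  labs <- c("MF", "FP", "DMN", "Mot", "VI", "VII", "VAs", "SAL", "SC", "CBL")
  labs[sort(rep_len(seq_along(labs), n_nodes))]
}

#' Simulate one run of node timecourses with confounds
#'
#' Timecourses follow a latent-factor model (10 factors with block loadings,
#' giving realistic network-structured connectivity). For each planted edge
#' (i, j), node j additionally receives a component of node i's series with
#' weight `planted_effect * theta_std`, so the (i, j) correlation increases
#' with the participant's standardized propensity. The confound table
#' carries 6 motion parameters, their first-order derivatives, global, CSF
#' and white-matter signals, and framewise displacement (FD) with an
#' `fd_spike_frac` fraction of FD > 0.5 mm volumes.
#'
#' @param config a [study_config()].
#' @param theta_std standardized propensity of this participant.
#' @param planted_edges two-column 0-based node-pair matrix (possibly empty).
#' @param seed RNG seed.
#' @param spike_frac override for the high-motion volume fraction.
#' @return list with `timecourses` (T x N matrix), `confounds` (T x 16 data
#'   frame, last column `framewise_displacement`), `fd` (numeric vector).
#' @export
gen_run_timecourses <- function(config, theta_std, planted_edges = config$planted_edges,
                                seed = config$seed, spike_frac = config$fd_spike_frac) {
  set.seed(derive_seed(seed, "timecourses"))
  Tn <- config$n_volumes; N <- config$n_nodes
  if (!is.null(planted_edges) && length(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (any(planted_edges >= N)) stop("planted edge references node >= n_nodes")
  }
  L <- network_loadings(N)
  Fk <- matrix(stats::rnorm(Tn * ncol(L)), Tn)
  X <- Fk %*% t(L) + matrix(stats::rnorm(Tn * N, 0, config$noise_sd), Tn)
  if (!is.null(planted_edges) && nrow(planted_edges)) {
    w <- config$planted_effect * theta_std
    for (e in seq_len(nrow(planted_edges))) {
      i <- planted_edges[e, 1] + 1L; j <- planted_edges[e, 2] + 1L
      X[, j] <- X[, j] + w * scale(X[, i])[, 1]
    }
  }

  motion <- sapply(seq_len(6), function(k) cumsum(stats::rnorm(Tn, 0, 0.02)))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  dmotion <- rbind(0, diff(motion))
  colnames(dmotion) <- paste0(colnames(motion), "_derivative1")
  fd <- rowSums(abs(dmotion))
  n_spike <- round(spike_frac * Tn)
  if (n_spike > 0) {
    idx <- sample.int(Tn, n_spike)
    fd[idx] <- stats::runif(n_spike, 0.6, 1.5)
  }
  conf <- data.frame(motion, dmotion,
                     global_signal = rowMeans(X) + stats::rnorm(Tn, 0, 0.05),
                     csf = stats::rnorm(Tn), white_matter = stats::rnorm(Tn),
                     framewise_displacement = fd, check.names = FALSE)
  list(timecourses = X, confounds = conf, fd = fd)
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Draws latent propensities theta ~ N(0, `propensity_sd`^2), builds per-
#' participant trial schedules and gaze sessions, covariates, and one
#' "sweet" and one "savory" timecourse run each. Planted theta-coupled
#' edges affect the sweet run only; the savory run is null, mirroring a
#' reward-specific brain-behavior association.
#'
#' @param config a [study_config()].
#' @param layout an [aoi_layout()].
#' @param runs character subset of `c("sweet", "savory")` to simulate.
#' @param gaze logical; simulate gaze streams (the slow part). When `FALSE`,
#'   only schedules, covariates and timecourses are generated.
#' @return list of class `synthetic_study`: `config`, `layout`,
#'   `ground_truth` (list: `theta`, `true_edges` 0-based matrix,
#'   `true_whr_slope`), `schedules`, `gaze` (per participant), `covariates`,
#'   `runs` (per participant, per condition: output of
#'   [gen_run_timecourses()]).
#' @export
simulate_study <- function(config = study_config(), layout = aoi_layout(),
                           runs = c("sweet", "savory"), gaze = TRUE) {
  set.seed(derive_seed(config$seed, "study"))
  n <- config$n_participants
  theta <- stats::rnorm(n, 0, config$propensity_sd)
  theta_std <- (theta - mean(theta)) / stats::sd(theta)

  planted <- config$planted_edges
  if (is.null(planted)) {
    # cross-block pairs so planted correlation is not confounded with the
    # factor block structure
    blocks <- sort(rep_len(seq_len(10), config$n_nodes))
    pool <- edge_pairs(config$n_nodes)
    cross <- blocks[pool$i + 1L] != blocks[pool$j + 1L]
    pick <- sample(which(cross), min(config$n_planted, sum(cross)))
    planted <- as.matrix(pool[pick, c("i", "j")])
    dimnames(planted) <- NULL
  }

  schedules <- lapply(seq_len(n), function(p)
    gen_trial_schedule(config, seed = derive_seed(config$seed, paste0("sched", p))))
  gaze_streams <- NULL
  if (gaze)
    gaze_streams <- lapply(seq_len(n), function(p)
      gen_gaze_session(schedules[[p]], theta[p], layout,
                       seed = derive_seed(config$seed, paste0("gaze", p))))
  covars <- gen_covariates(config, theta)

  run_data <- lapply(seq_len(n), function(p) {
    out <- list()
    if ("sweet" %in% runs)
      out$sweet <- gen_run_timecourses(config, theta_std[p], planted,
                                       seed = derive_seed(config$seed, paste0("sweet", p)))
    if ("savory" %in% runs)
      out$savory <- gen_run_timecourses(config, theta_std[p],
                                        planted_edges = NULL,
                                        seed = derive_seed(config$seed, paste0("savory", p)))
    out
  })

  structure(list(
    config = config, layout = layout,
    ground_truth = list(theta = theta, true_edges = planted,
                        true_whr_slope = config$whr_slope),
    schedules = schedules, gaze = gaze_streams, covariates = covars,
    runs = run_data), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic sign-/goal-tracking study\n")
  cat("  participants:", x$config$n_participants,
      " nodes:", x$config$n_nodes, " volumes/run:", x$config$n_volumes, "\n")
  cat("  planted edges:", nrow(x$ground_truth$true_edges),
      " gamma:", x$config$planted_effect,
      " whr slope:", x$config$whr_slope, "\n")
  invisible(x)
}
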