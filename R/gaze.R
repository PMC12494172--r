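#' Area-of-interest layout for the conditioning task scene
#'
#' The scene is described in a planar coordinate system measured in visual
#' degrees, centred on the fixation cross at (0, 0). Two rectangular AOIs are
#' defined — the fractal conditioned stimulus (CS) and the candy-dispenser
#' location (UCS); everything else is background (BG). In the canonical
#' ("CS-left") orientation the CS rectangle sits on the left (negative x).
#' When the apparatus orientation is switched the layout is mirrored about
#' the vertical midline (x -> -x).
#'
#' @param cs,ucs numeric length-4 vectors `c(xmin, xmax, ymin, ymax)` in
#'   visual degrees, for the CS-left orientation.
#' @return an object of class `aoi_layout`.
#' @examples
#' layout <- aoi_layout()
#' assign_aoi(c(-10, 0), layout, "cs_left")   # "CS"
#' @export
aoi_layout <- function(cs = c(-14, -6, -4, 4), ucs = c(6, 14, -4, 4)) {
  chk <- function(r, nm) {
    if (length(r) != 4 || !is.numeric(r) || r[1] >= r[2] || r[3] >= r[4])
      stop(sprintf("'%s' must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax", nm))
  }
  chk(cs, "cs"); chk(ucs, "ucs")
  overlap <- cs[1] < ucs[2] && ucs[1] < cs[2] && cs[3] < ucs[4] && ucs[3] < cs[4]
  if (overlap) stop("CS and UCS AOI rectangles must be disjoint")
  structure(list(cs = as.numeric(cs), ucs = as.numeric(ucs)), class = "aoi_layout")
}

# Mirror a rectangle about x = 0.
mirror_rect <- function(r) c(-r[2], -r[1], r[3], r[4])

in_rect <- function(x, y, r) x >= r[1] & x <= r[2] & y >= r[3] & y <= r[4]

#' Assign a fixation to an area of interest
#'
#' Membership is decided by the fixation centroid. Under the switched
#' ("CS-right") orientation the layout is mirrored about the vertical midline
#' before the point-in-rectangle test, so the same physical AOIs are tracked
#' on both halves of the task.
#'
#' @param centroid numeric length-2 `c(x, y)` in visual degrees, or a
#'   fixation row as returned by [classify_fixations()].
#' @param layout an [aoi_layout()].
#' @param orientation `"cs_left"` or `"cs_right"`.
#' @return one of `"CS"`, `"UCS"`, `"BG"`.
#' @export
assign_aoi <- function(centroid, layout, orientation = c("cs_left", "cs_right")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(layout, "aoi_layout"))
  if (is.data.frame(centroid)) centroid <- c(centroid$x[1], centroid$y[1])
  cs <- layout$cs; ucs <- layout$ucs
  if (orientation == "cs_right") {
    cs <- mirror_rect(cs); ucs <- mirror_rect(ucs)
  }
  if (in_rect(centroid[1], centroid[2], cs)) "CS"
  else if (in_rect(centroid[1], centroid[2], ucs)) "UCS"
  else "BG"
}

#' Classify raw gaze samples into fixations (I-VT filter)
#'
#' Velocity-threshold identification: point-to-point angular velocity is
#' computed between consecutive valid samples (Euclidean angular distance in
#' degrees divided by the sample interval). Samples connected by velocities
#' strictly below the threshold form candidate fixation runs; runs spanning
#' at least `min_duration` become fixations with a time-weighted centroid.
#' Invalid samples (blinks, tracking loss) terminate runs unless bridged by
#' the optional gap fill-in.
#'
#' @param stream data frame with columns `time_ms` (strictly increasing),
#'   `x`, `y` (visual degrees) and `valid` (logical).
#' @param velocity_threshold saccade velocity cut in degrees per second
#'   (default 30).
#' @param min_duration minimum fixation span in ms (default 50).
#' @param max_gap_ms fill gaps of invalid samples up to this length by linear
#'   interpolation before classification (default 0 = off).
#' @param merge_max_ms,merge_max_deg merge consecutive fixations separated by
#'   at most `merge_max_ms` and whose centroids are within `merge_max_deg`
#'   (defaults 0 = off).
#' @return data frame with one row per fixation: `start_ms`, `end_ms`,
#'   `duration_ms`, `x`, `y` (centroid). Zero rows when fewer than two valid
#'   samples are present.
#' @examples
#' s <- data.frame(time_ms = seq(0, 980, by = 20), x = 0, y = 0, valid = TRUE)
#' classify_fixations(s)  # one ~1 s fixation at (0, 0)
#' @export
classify_fixations <- function(stream, velocity_threshold = 30, min_duration = 50,
                               max_gap_ms = 0, merge_max_ms = 0, merge_max_deg = 0) {
  stopifnot(velocity_threshold > 0, min_duration > 0)
  validate_gaze_stream(stream)
  t <- stream$time_ms; x <- stream$x; y <- stream$y; v_ok <- as.logical(stream$valid)

  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      duration_ms = numeric(0), x = numeric(0), y = numeric(0))
  if (sum(v_ok) < 2L) return(empty)

  if (max_gap_ms > 0) {
    filled <- fill_gaps(t, x, y, v_ok, max_gap_ms)
    x <- filled$x; y <- filled$y; v_ok <- filled$valid
  }

  n <- length(t)
  dt <- diff(t)                                   # ms
  dist <- sqrt(diff(x)^2 + diff(y)^2)             # degrees
  vel <- dist / (dt / 1000)                       # deg/s
  link <- v_ok[-n] & v_ok[-1] & vel < velocity_threshold & !is.na(vel)

  # Chains of samples connected by sub-threshold links. A new run starts at
  # every sample whose incoming link is broken.
  run_id <- cumsum(c(TRUE, !link))
  keep <- v_ok
  fix_list <- split(which(keep), run_id[keep])
  out <- lapply(fix_list, function(idx) {
    span <- t[idx[length(idx)]] - t[idx[1]]
    if (span < min_duration) return(NULL)
    # time weights: half-interval to each neighbour within the run
    ti <- t[idx]
    w <- (c(diff(ti), 0) + c(0, diff(ti))) / 2
    if (sum(w) == 0) w <- rep(1, length(idx))
    c(start = ti[1], end = ti[length(idx)],
      x = sum(x[idx] * w) / sum(w), y = sum(y[idx] * w) / sum(w))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  fx <- data.frame(start_ms = out[, "start"], end_ms = out[, "end"],
                   duration_ms = out[, "end"] - out[, "start"],
                   x = out[, "x"], y = out[, "y"], row.names = NULL)
  fx <- fx[order(fx$start_ms), , drop = FALSE]

  if (merge_max_ms > 0 && nrow(fx) > 1) fx <- merge_fixations(fx, merge_max_ms, merge_max_deg)
  rownames(fx) <- NULL
  fx
}

# Linear interpolation across short invalid gaps (Tobii I-VT "gap fill-in").
fill_gaps <- function(t, x, y, valid, max_gap_ms) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(!r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == length(t)) next
    gap <- t[i1 + 1L] - t[i0 - 1L]
    if (gap > max_gap_ms) next
    idx <- i0:i1
    frac <- (t[idx] - t[i0 - 1L]) / gap
    x[idx] <- x[i0 - 1L] + frac * (x[i1 + 1L] - x[i0 - 1L])
    y[idx] <- y[i0 - 1L] + frac * (y[i1 + 1L] - y[i0 - 1L])
    valid[idx] <- TRUE
  }
  list(x = x, y = y, valid = valid)
}

merge_fixations <- function(fx, merge_max_ms, merge_max_deg) {
  i <- 1L
  while (i < nrow(fx)) {
    gap <- fx$start_ms[i + 1L] - fx$end_ms[i]
    d <- sqrt((fx$x[i + 1L] - fx$x[i])^2 + (fx$y[i + 1L] - fx$y[i])^2)
    if (gap <= merge_max_ms && d <= merge_max_deg) {
      w <- c(fx$duration_ms[i], fx$duration_ms[i + 1L])
      if (sum(w) == 0) w <- c(1, 1)
      fx$x[i] <- sum(fx$x[i:(i + 1L)] * w) / sum(w)
      fx$y[i] <- sum(fx$y[i:(i + 1L)] * w) / sum(w)
      fx$end_ms[i] <- fx$end_ms[i + 1L]
      fx$duration_ms[i] <- fx$end_ms[i] - fx$start_ms[i]
      fx <- fx[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  fx
}

#' Percentage of valid gaze samples over a recording
#'
#' Tracker data quality: the share of raw samples the eye-tracker identified
#' (participants blinking or looking outside the glasses frame lower it).
#' Participants below a quality threshold (default 80% elsewhere in the
#' pipeline) are excluded from analysis.
#'
#' @param stream gaze stream data frame (see [classify_fixations()]).
#' @return percentage in `[0, 100]`.
#' @export
gaze_sample_quality <- function(stream) {
  validate_gaze_stream(stream)
  if (nrow(stream) == 0) stop("empty gaze stream")
  100 * mean(as.logical(stream$valid))
}

validate_gaze_stream <- function(stream) {
  req <- c("time_ms", "x", "y", "valid")
  miss <- setdiff(req, names(stream))
  if (length(miss)) stop("gaze stream missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(stream) > 1 && any(diff(stream$time_ms) <= 0))
    stop("gaze stream timestamps must be strictly increasing")
  invisible(TRUE)
}

#' Summarize fixations within the late-CS analysis window of one trial
#'
#' Pavlovian conditioned gaze is measured over the last 1.5 s of the 3 s CS
#' presentation (the onset period reflects an orienting response common to
#' both phenotypes). Each fixation contributes its temporal overlap with the
#' window to the AOI containing its centroid; percentages are shares of the
#' total overlapped fixation time, and the gaze index is
#' `(pct_cs - pct_ucs) / 100`, ranging from -1 (all gaze at the reward
#' location) to +1 (all gaze on the CS).
#'
#' @param trial one row of a trial schedule (needs `cs_offset_ms`,
#'   `orientation`; see [gen_trial_schedule()]).
#' @param fixations fixation data frame from [classify_fixations()].
#' @param layout an [aoi_layout()].
#' @param window_ms analysis window length before CS offset (default 1500).
#' @return one-row data frame: `pct_cs`, `pct_ucs`, `pct_bg`,
#'   `valid_fix_time_ms`, `gaze_index` (NA when no fixation overlaps the
#'   window).
#' @export
window_summary <- function(trial, fixations, layout, window_ms = 1500) {
  w0 <- trial$cs_offset_ms - window_ms
  w1 <- trial$cs_offset_ms
  res <- c(CS = 0, UCS = 0, BG = 0)
  if (nrow(fixations)) {
    ov <- pmin(fixations$end_ms, w1) - pmax(fixations$start_ms, w0)
    sel <- which(ov > 0)
    for (k in sel) {
      role <- assign_aoi(c(fixations$x[k], fixations$y[k]), layout,
                         as.character(trial$orientation))
      res[role] <- res[role] + ov[k]
    }
  }
  tot <- sum(res)
  if (tot > 0) {
    pct <- 100 * res / tot
    gi <- (pct[["CS"]] - pct[["UCS"]]) / 100
  } else {
    pct <- c(CS = NA_real_, UCS = NA_real_, BG = NA_real_)
    gi <- NA_real_
  }
  data.frame(pct_cs = pct[["CS"]], pct_ucs = pct[["UCS"]], pct_bg = pct[["BG"]],
             valid_fix_time_ms = tot, gaze_index = gi)
}

#' Per-trial gaze summaries for a whole session
#'
#' Runs [window_summary()] over every trial of a schedule.
#'
#' @param schedule trial schedule data frame ([gen_trial_schedule()]).
#' @param fixations fixation data frame ([classify_fixations()]).
#' @param layout an [aoi_layout()].
#' @param window_ms analysis window length in ms.
#' @return data frame: schedule columns `trial`, `shaping`, `cs_type`,
#'   `cs_value`, `exp_index` plus the window summary columns.
#' @export
session_summaries <- function(schedule, fixations, layout, window_ms = 1500) {
  rows <- lapply(seq_len(nrow(schedule)), function(r) {
    cbind(schedule[r, c("trial", "shaping", "cs_type", "cs_value", "exp_index")],
          window_summary(schedule[r, ], fixations, layout, window_ms))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the task's trial exclusions
#'
#' Shaping trials are dropped, and for each CS type only the first
#' `keep_per_cs_type` experimental trials are retained: the last four trials
#' of each type suffer poorer data quality (fatigue, drifting calibration)
#' and are excluded, leaving 12 of 16 trials per type (48 in total) at the
#' defaults.
#'
#' @param summaries per-trial summary data frame ([session_summaries()]);
#'   needs `shaping`, `cs_type` and `exp_index` columns.
#' @param keep_per_cs_type experimental trials retained per CS type
#'   (default 12).
#' @return filtered data frame.
#' @export
apply_exclusions <- function(summaries, keep_per_cs_type = 12) {
  stopifnot(keep_per_cs_type >= 1)
  ex <- summaries[!summaries$shaping, , drop = FALSE]
  short <- FALSE
  keep <- unlist(lapply(split(seq_len(nrow(ex)), ex$cs_type), function(idx) {
    idx <- idx[order(ex$exp_index[idx])]
    if (length(idx) < keep_per_cs_type) {
      short <<- TRUE
      idx
    } else idx[seq_len(keep_per_cs_type)]
  }), use.names = FALSE)
  if (short)
    warning("fewer than ", keep_per_cs_type,
            " experimental trials for at least one CS type; keeping all")
  out <- ex[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
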