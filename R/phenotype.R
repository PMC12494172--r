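#' Sign-/goal-tracking regression coefficient for one participant
#'
#' Each CS type carries the reward value it predicts (2, 1, 0, 0 candies).
#' Regressing the per-trial gaze index on CS value gives a per-participant
#' slope: positive slopes mean gaze is drawn to reward-predictive cues
#' (sign-tracking), negative slopes mean gaze is drawn to the reward
#' location itself (goal-tracking). Trials with a missing gaze index are
#' dropped rather than imputed.
#'
#' @param cs_value per-trial CS reward values.
#' @param gaze_index per-trial gaze indices in `[-1, 1]` (NA allowed).
#' @param min_trials minimum retained trials for a usable slope
#'   (default 24, half of the standard 48).
#' @return object of class `stgt_fit`: `slope`, `intercept`,
#'   `n_trials_used`, `usable` (whether `min_trials` was met).
#' @examples
#' stgt_coefficient(c(2, 1, 0, 0), c(0.5, 0.1, -0.2, -0.4), min_trials = 4)$slope  # 0.4
#' @export
stgt_coefficient <- function(cs_value, gaze_index, min_trials = 24) {
  stopifnot(length(cs_value) == length(gaze_index))
  keep <- !is.na(gaze_index) & !is.na(cs_value)
  x <- cs_value[keep]; y <- gaze_index[keep]
  if (length(unique(x)) < 2)
    stop("slope undefined: fewer than 2 distinct CS values among retained trials")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 n_trials_used = length(x),
                 usable = length(x) >= min_trials),
            class = "stgt_fit")
}

#' @export
print.stgt_fit <- function(x, ...) {
  cat(sprintf("ST/GT coefficient: %.4f (intercept %.4f, %d trials%s)\n",
              x$slope, x$intercept, x$n_trials_used,
              if (x$usable) "" else ", below trial minimum"))
  invisible(x)
}

#' Assign sign-/goal-tracker groups from a sample of slopes
#'
#' Participants are ranked by their ST/GT coefficient; the 2/5 with the most
#' positive slopes are sign-trackers (ST), the 2/5 with the most negative
#' are goal-trackers (GT), and the middle 1/5 are intermediates. Tail sizes
#' are `round(0.4 n)` (47 participants split 19/9/19); slope ties are broken
#' by stable input order.
#'
#' @param slopes numeric vector of per-participant ST/GT coefficients.
#' @param fractions tail/middle fractions, kept for documentation; only the
#'   first (tail) fraction is used.
#' @return factor of length `n` with levels `GT`, `intermediate`, `ST`.
#' @examples
#' table(assign_groups(rnorm(47)))  # 19 GT, 9 intermediate, 19 ST
#' @export
assign_groups <- function(slopes, fractions = c(2, 1, 2) / 5) {
  n <- length(slopes)
  if (n < 5) stop("at least 5 participants required for a group split")
  if (any(!is.finite(slopes))) stop("all slopes must be finite")
  k <- round(fractions[1] * n)
  rk <- order(slopes)  # stable for ties
  g <- rep("intermediate", n)
  g[rk[seq_len(k)]] <- "GT"
  g[rk[seq.int(n - k + 1, n)]] <- "ST"
  factor(g, levels = c("GT", "intermediate", "ST"))
}

#' Adjusted association between the ST/GT coefficient and an adiposity measure
#'
#' Ordinary least squares with the ST/GT coefficient as outcome and an
#' adiposity measure (WHR or BMI) as predictor, adjusted for age, sex and
#' pre-task hunger. Reports unstandardized coefficients with classical 95%
#' CIs and p-values, plus standardized estimates from refitting with the
#' outcome and continuous predictors z-scored. Two standardization
#' conventions are computed: `std` leaves binary indicators unscaled
#' (interpretable as group shifts in outcome SDs); `std_all` scales them
#' too. The `std` convention is the one echoed in printed output.
#'
#' @param data data frame containing the outcome and model terms.
#' @param outcome name of the outcome column (default `"stgt_slope"`).
#' @param predictor name of the adiposity column (e.g. `"whr"` or `"bmi"`).
#' @param covariates names of adjustment columns
#'   (default `c("age", "sex", "hunger")`).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `adiposity_fit`: `coefficients` (data frame with
#'   estimate, CI bounds, p, standardized estimates), `r_squared`,
#'   `adj_r_squared`, `n`, `formula`, `standardization`.
#' @export
adiposity_model <- function(data, outcome = "stgt_slope", predictor = "whr",
                            covariates = c("age", "sex", "hunger"),
                            conf_level = 0.95) {
  vars <- c(outcome, predictor, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  form <- stats::reformulate(c(predictor, covariates), response = outcome)
  if (nrow(d) < length(vars) + 2) stop("too few complete cases")
  fit <- stats::lm(form, data = d)
  if (fit$rank < length(stats::coef(fit))) stop("rank-deficient design")
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)

  # standardized refits
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  is_cont <- vapply(d, function(v) is.numeric(v) && length(unique(v)) > 2, logical(1))
  dz <- d
  for (v in vars[vars %in% names(is_cont)[is_cont] | vars == outcome])
    if (is.numeric(dz[[v]])) dz[[v]] <- zscore(dz[[v]])
  fitz <- stats::lm(form, data = dz)
  # full standardization: indicator-code then scale everything
  mm <- stats::model.matrix(form, d)[, -1, drop = FALSE]
  mma <- scale(mm)
  ya <- zscore(d[[outcome]])
  fita <- stats::lm.fit(cbind(1, mma), ya)

  est <- stats::coef(fit)
  tab <- data.frame(
    term = names(est), estimate = unname(est),
    conf_low = ci[, 1], conf_high = ci[, 2],
    p_value = sm$coefficients[, 4],
    std_estimate = unname(stats::coef(fitz)),
    std_all_estimate = c(fita$coefficients[1], fita$coefficients[-1]),
    row.names = NULL)
  structure(list(coefficients = tab, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, n = nrow(d),
                 formula = form, conf_level = conf_level,
                 standardization = "outcome and continuous predictors z-scored; binary indicators unscaled (std); fully scaled variant in std_all",
                 lm_fit = fit),
            class = "adiposity_fit")
}

#' @export
print.adiposity_fit <- function(x, digits = 3, ...) {
  cat("Adjusted linear model:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, R^2 = %.3f, adjusted R^2 = %.3f\n",
              x$n, x$r_squared, x$adj_r_squared))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided; used for post-hoc ST vs GT group comparisons of adiposity.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`, and group means.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Repeated-measures ANOVA for AOI x CS-type percent fixations
#'
#' Two-way fully within-subject ANOVA on the participants x AOI x CS-type
#' table of percent fixations, reporting the AOI-by-CS-type interaction with
#' Greenhouse-Geisser (or Huynh-Feldt) corrected degrees of freedom. The
#' sphericity correction is estimated from the covariance matrix of the
#' interaction contrasts.
#'
#' @param data long data frame with columns `participant`, `aoi`, `cs_type`,
#'   `pct` — one complete, balanced cell table.
#' @param correction `"gg"` (Greenhouse-Geisser, default) or `"hf"`
#'   (Huynh-Feldt).
#' @return list: `F`, `df` (uncorrected numerator/denominator), `epsilon`,
#'   `df_corrected`, `p` (corrected), `correction`.
#' @export
rm_anova <- function(data, correction = c("gg", "hf")) {
  correction <- match.arg(correction)
  req <- c("participant", "aoi", "cs_type", "pct")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data$aoi <- factor(data$aoi); data$cs_type <- factor(data$cs_type)
  data$participant <- factor(data$participant)
  tab <- stats::xtabs(~ participant + aoi + cs_type, data)
  if (any(tab != 1)) stop("cell table must be complete and balanced (one value per cell)")

  data$cell <- interaction(data$aoi, data$cs_type, lex.order = TRUE)
  ord <- order(data$participant, data$cell)
  d <- data[ord, ]
  n_cells <- nlevels(d$cell)
  Y <- matrix(d$pct, ncol = n_cells, byrow = TRUE,
              dimnames = list(levels(d$participant), levels(d$cell)))

  if (stats::var(as.vector(Y)) < 1e-24 ||
      sum((Y - rowMeans(Y))^2) < 1e-20) {
    # degenerate: no within-subject variation at all
    a <- nlevels(d$aoi); b <- nlevels(d$cs_type)
    df1 <- (a - 1) * (b - 1); df2 <- df1 * (nrow(Y) - 1)
    return(list(F = 0, df = c(df1, df2), epsilon = NA_real_,
                df_corrected = c(df1, df2), p = 1, correction = correction))
  }

  idata <- expand.grid(cs_type = levels(d$cs_type), aoi = levels(d$aoi))
  idata <- idata[order(idata$aoi, idata$cs_type), c("aoi", "cs_type")]
  mod <- stats::lm(Y ~ 1)
  an <- car::Anova(mod, idata = idata, idesign = ~ aoi * cs_type, type = "III")
  s <- suppressWarnings(summary(an, multivariate = FALSE))  # HF eps > 1 note
  ut <- s$univariate.tests
  row <- grep("aoi:cs_type", rownames(ut))
  Fv <- ut[row, "F value"]; df1 <- ut[row, "num Df"]; df2 <- ut[row, "den Df"]

  # sphericity correction from the covariance of orthonormalized
  # interaction contrasts (columns of Y are aoi-major, cs-minor)
  orth <- function(m) stats::contr.poly(m)
  C <- kronecker(orth(nlevels(d$aoi)), orth(nlevels(d$cs_type)))
  S <- stats::cov(Y %*% C)
  dint <- ncol(C)
  eps_gg <- sum(diag(S))^2 / (dint * sum(S^2))
  eps <- if (correction == "gg") eps_gg else {
    ns <- nrow(Y)
    (ns * dint * eps_gg - 2) / (dint * (ns - 1 - dint * eps_gg))
  }
  eps <- min(eps, 1)
  p <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  list(F = unname(Fv), df = c(unname(df1), unname(df2)), epsilon = unname(eps),
       df_corrected = c(unname(eps * df1), unname(eps * df2)),
       p = unname(p), correction = correction)
}

#' Trend of a gaze measure over trials
#'
#' Simplified random-effects trend test: an OLS slope of the measure on
#' trial number is fit per participant, and the slopes are tested against
#' zero with a one-sample t-test. When every slope is identical the t
#' statistic is undefined; by convention p = 1 if the common slope is 0 and
#' p = 0 otherwise.
#'
#' @param data long data frame with columns `participant`, `trial`, `value`.
#' @return list: `mean_slope`, `t`, `df`, `p`, `slopes`.
#' @export
trend_over_trials <- function(data) {
  req <- c("participant", "trial", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  by_p <- split(data, data$participant)
  if (any(vapply(by_p, nrow, integer(1)) < 3))
    stop("each participant needs at least 3 trials")
  slopes <- vapply(by_p, function(d) {
    x <- d$trial; y <- d$value
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }, numeric(1))
  m <- mean(slopes)
  if (stats::sd(slopes) < 1e-12) {
    return(list(mean_slope = m, t = NA_real_, df = length(slopes) - 1,
                p = if (abs(m) < 1e-12) 1 else 0, slopes = slopes))
  }
  ht <- stats::t.test(slopes)
  list(mean_slope = m, t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, slopes = slopes)
}
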