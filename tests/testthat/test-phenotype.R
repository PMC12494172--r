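test_that("ST/GT slope matches closed forms and a brute-force OLS oracle", {
  # saturated pattern: +1 on 24 rewarding trials, -1 on 24 neutral trials
  cs <- rep(c(2, 1, 0, 0), each = 12)
  gi <- ifelse(cs > 0, 1, -1)
  expect_equal(stgt_coefficient(cs, gi)$slope, 12 / 11, tolerance = 1e-12)

  # 4-trial worked example
  fit4 <- stgt_coefficient(c(2, 1, 0, 0), c(0.5, 0.1, -0.2, -0.4), min_trials = 4)
  expect_equal(fit4$slope, 0.4, tolerance = 1e-12)

  # both against lm() as independent oracle
  expect_equal(stgt_coefficient(cs, gi)$slope, unname(coef(lm(gi ~ cs))[2]),
               tolerance = 1e-12)
  set.seed(10)
  csr <- sample(c(2, 1, 0, 0), 48, replace = TRUE)
  gir <- rnorm(48)
  gir[sample(48, 5)] <- NA
  fit <- stgt_coefficient(csr, gir)
  ref <- coef(lm(gir ~ csr))
  expect_equal(fit$slope, unname(ref[2]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(ref[1]), tolerance = 1e-12)
  expect_equal(fit$n_trials_used, sum(!is.na(gir)))

  expect_equal(stgt_coefficient(csr, rep(0.3, 48))$slope, 0)
  expect_error(stgt_coefficient(rep(2, 10), rnorm(10)), "distinct")
})

test_that("slope is order-invariant and affine-equivariant", {
  set.seed(11)
  cs <- rep(c(2, 1, 0, 0), each = 12)
  gi <- rnorm(48)
  s0 <- stgt_coefficient(cs, gi)$slope
  o <- sample(48)
  expect_equal(stgt_coefficient(cs[o], gi[o])$slope, s0, tolerance = 1e-12)
  expect_equal(stgt_coefficient(cs, 3 * gi + 2)$slope, 3 * s0, tolerance = 1e-12)
})

test_that("group split yields the 2/5-1/5-2/5 partition with round(0.4 n) tails", {
  for (n in c(47, 5, 10, 23)) {
    g <- assign_groups(seq_len(n) / n)
    k <- round(0.4 * n)
    expect_equal(unname(table(g)[c("GT", "intermediate", "ST")]),
                 c(k, n - 2 * k, k), ignore_attr = TRUE)
  }
  g47 <- assign_groups(rnorm(47))
  expect_equal(as.vector(table(g47)), c(19, 9, 19))
  # ranking is by slope: the largest slopes are ST
  sl <- c(5, 4, 3, 2, 1)
  expect_equal(as.character(assign_groups(sl)), c("ST", "ST", "intermediate", "GT", "GT"))
  expect_error(assign_groups(rnorm(4)), "at least 5")
  expect_error(assign_groups(c(1, 2, NA, 4, 5)), "finite")
})

test_that("adiposity model recovers noiseless generating coefficients exactly", {
  set.seed(12)
  n <- 47
  d <- data.frame(age = rnorm(n, 25, 6), sex = sample(c("female", "male"), n, TRUE),
                  hunger = runif(n, 0, 100), whr = rnorm(n, 0.85, 0.07))
  d$stgt_slope <- -1.64 + 1.48 * d$whr + 0.01 * d$age + 0.07 * (d$sex == "male")
  fit <- adiposity_model(d, predictor = "whr")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["whr"]), 1.48, tolerance = 1e-9)
  expect_equal(unname(est["age"]), 0.01, tolerance = 1e-9)
  expect_equal(unname(est["(Intercept)"]), -1.64, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # CI contains the point estimate
  expect_true(all(fit$coefficients$conf_low <= fit$coefficients$estimate &
                    fit$coefficients$estimate <= fit$coefficients$conf_high))

  # duplicated rows leave coefficients unchanged
  fit2 <- adiposity_model(rbind(d, d), predictor = "whr")
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-9)

  # null predictor: coefficient near zero at large n
  set.seed(13)
  n2 <- 2000
  d2 <- data.frame(age = rnorm(n2), sex = sample(c("f", "m"), n2, TRUE),
                   hunger = runif(n2), whr = rnorm(n2),
                   stgt_slope = rnorm(n2))
  fitn <- adiposity_model(d2, predictor = "whr")
  expect_lt(abs(fitn$coefficients$estimate[fitn$coefficients$term == "whr"]), 0.1)

  # standardized estimate equals the z-scored refit oracle
  dz <- d
  dz$stgt_slope <- scale(d$stgt_slope)[, 1]
  for (v in c("whr", "age", "hunger")) dz[[v]] <- scale(d[[v]])[, 1]
  ref <- coef(lm(stgt_slope ~ whr + age + sex + hunger, dz))
  expect_equal(setNames(fit$coefficients$std_estimate, fit$coefficients$term)[["whr"]],
               unname(ref["whr"]), tolerance = 1e-9)
})

test_that("parameter recovery: the WHR association is detected across replicates", {
  hits <- 0
  for (r in 1:20) {
    cfg <- study_config(n_participants = 200, seed = 300 + r)
    th <- rnorm(200)
    cv <- gen_covariates(cfg, th, seed = 300 + r)
    cv$stgt_slope <- 0.3 * th + rnorm(200, 0, 0.3)  # behavior monotone in theta
    fit <- adiposity_model(cv, predictor = "whr")
    row <- fit$coefficients[fit$coefficients$term == "whr", ]
    if (row$estimate > 0 && row$conf_low > 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("Welch t matches the textbook formula and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 10)
  w <- welch_t(a, b)
  o <- brute_welch(a, b)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sw <- welch_t(b, a)
  expect_equal(sw$t, -w$t, tolerance = 1e-12)
  expect_equal(sw$p, w$p, tolerance = 1e-12)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("repeated-measures ANOVA matches a brute-force oracle", {
  set.seed(14)
  d <- expand.grid(participant = paste0("p", 1:5), aoi = c("CS", "UCS", "BG"),
                   cs_type = paste0("f", 1:4))
  d$pct <- rnorm(nrow(d), 33, 6) + ifelse(d$aoi == "CS" & d$cs_type %in% c("f1", "f2"), 10, 0)
  r <- rm_anova(d)
  o <- brute_rm_anova(d)
  expect_equal(r$F, o$F, tolerance = 1e-8)
  expect_equal(r$df, o$df)
  expect_equal(r$epsilon, o$epsilon, tolerance = 1e-8)
  expect_equal(r$p, o$p, tolerance = 1e-8)

  # all cells equal: no interaction signal
  d0 <- d; d0$pct <- 50
  r0 <- rm_anova(d0)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  expect_error(rm_anova(d[-1, ]), "complete")
})

test_that("compound-symmetric data give epsilon 1 and uncorrected df", {
  # exact sphericity: independent cell effects plus a subject offset
  set.seed(15)
  n <- 300
  d <- expand.grid(participant = seq_len(n), aoi = c("CS", "UCS", "BG"),
                   cs_type = paste0("f", 1:4))
  d$pct <- rnorm(nrow(d)) + rep(rnorm(n), 12)
  r <- rm_anova(d)
  expect_gt(r$epsilon, 0.95)  # epsilon -> 1 under sphericity
  o <- brute_rm_anova(d)
  expect_equal(r$epsilon, o$epsilon, tolerance = 1e-8)
})

test_that("trend over trials recovers planted slopes and handles degeneracy", {
  # constant values: slope 0, p 1 by convention
  d0 <- expand.grid(participant = 1:6, trial = 1:10)
  d0$value <- 5
  r0 <- trend_over_trials(d0)
  expect_equal(r0$mean_slope, 0)
  expect_equal(r0$p, 1)

  # values equal to trial number: common slope 1
  d1 <- expand.grid(participant = 1:6, trial = 1:10)
  d1$value <- d1$trial
  expect_equal(trend_over_trials(d1)$mean_slope, 1)

  # power at planted slope 0.2, noise 0.1, 30 participants
  rej <- 0
  for (r in 1:40) {
    set.seed(500 + r)
    d <- expand.grid(participant = 1:30, trial = 1:12)
    d$value <- 0.2 * d$trial + rnorm(nrow(d), 0, 0.1)
    if (trend_over_trials(d)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 40, 0.95)
  expect_error(trend_over_trials(data.frame(participant = 1, trial = 1:2,
                                            value = 1:2)), "3 trials")
})
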