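test_that("partial Spearman reduces to plain Spearman and matches its oracle", {
  set.seed(30)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.5)
  expect_equal(partial_spearman(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(partial_spearman(x, exp(x)), 1)  # monotone, no covariates

  # 8-subject example against an explicit rank + lm-residual computation
  x8 <- c(3.1, -0.2, 0.5, 2.2, 1.1, -1.4, 0.7, 1.9)
  y8 <- c(0.2, -0.6, 0.1, 1.8, 0.9, -1.1, -0.3, 1.2)
  cv <- data.frame(age = c(24, 31, 28, 45, 37, 22, 29, 33))
  M <- model.matrix(~ age, cv)
  ex <- residuals(lm.fit(M, rank(x8)))
  ey <- residuals(lm.fit(M, rank(y8)))
  expect_equal(partial_spearman(x8, y8, cv), cor(ex, ey), tolerance = 1e-12)

  expect_error(partial_spearman(rep(1, 8), y8), "constant")
})

test_that("edge selection uses strict cuts by sign", {
  rho <- c(0.35, -0.31, 0.30, -0.29)
  sel <- select_edges(rho, 0.3)
  expect_equal(sel$pos, 1L)
  expect_equal(sel$neg, 2L)
  sel0 <- select_edges(c(0.1, -0.2), 0.3)
  expect_equal(lengths(sel0), c(pos = 0L, neg = 0L))
  selz <- select_edges(c(0.2, -0.1, 0), 0)
  expect_equal(selz$pos, 1L)
  expect_equal(selz$neg, 2L)
})

test_that("network strength is the additive sum of edge z values", {
  z <- c(0.2, 0.3, -0.1, 0.4)
  expect_equal(network_strength(z, integer(0)), 0)
  expect_equal(network_strength(z, c(1, 2)), 0.5)
  expect_equal(network_strength(z, 1:4),
               network_strength(z, c(1, 3)) + network_strength(z, c(2, 4)))
  expect_error(network_strength(z, 9), "outside")
})

test_that("LOOCV predictions match a naive fold-by-fold reimplementation", {
  set.seed(31)
  n <- 12; N <- 8
  Z <- matrix(rnorm(n * N * (N - 1) / 2), n)
  y <- Z[, 5] - 0.5 * Z[, 11] + rnorm(n, 0, 0.3)
  cv <- data.frame(age = rnorm(n, 30, 5), sex = sample(c("f", "m"), n, TRUE))
  fit <- suppressWarnings(cpm(Z, y, cv, threshold = 0.4))
  orc <- naive_cpm(Z, y, cv, 0.4)
  expect_equal(as.matrix(fit$predictions), orc$pred, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(fit$accuracy), unname(orc$acc), tolerance = 1e-10)
  expect_identical(fit$folds$pos, orc$folds_pos)
  expect_identical(fit$folds$neg, orc$folds_neg)

  # also without covariates
  fit0 <- suppressWarnings(cpm(Z, y, threshold = 0.4))
  orc0 <- naive_cpm(Z, y, NULL, 0.4)
  expect_equal(as.matrix(fit0$predictions), orc0$pred, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("exact linear behavior on one selectable edge is recovered perfectly", {
  set.seed(32)
  n <- 16
  Z <- matrix(rnorm(n * 30), n)
  y <- 2 + 3 * Z[, 7]
  fit <- suppressWarnings(cpm(Z, y, threshold = 0.9))
  expect_equal(fit$predictions$pos, y, tolerance = 1e-8)
  expect_equal(unname(fit$accuracy["pos"]), 1)
})

test_that("held-out data never influence training-fold selection", {
  set.seed(33)
  n <- 14
  Z <- matrix(rnorm(n * 45), n)
  y <- Z[, 3] + rnorm(n, 0, 0.5)
  fit <- suppressWarnings(cpm(Z, y, threshold = 0.4))
  f <- 5
  Zc <- Z
  Zc[f, ] <- 1e6 * rnorm(45)  # corrupt the held-out subject
  fitc <- suppressWarnings(cpm(Zc, y, threshold = 0.4))
  expect_identical(fit$folds$pos[[f]], fitc$folds$pos[[f]])
  expect_identical(fit$folds$neg[[f]], fitc$folds$neg[[f]])
})

test_that("permutation p follows the plain-proportion formula and is seeded", {
  set.seed(34)
  n <- 14
  Z <- matrix(rnorm(n * 20), n)
  y <- Z[, 2] * 2 + rnorm(n, 0, 0.2)
  f1 <- suppressWarnings(cpm(Z, y, threshold = 0.5, n_permutations = 60, seed = 9))
  f2 <- suppressWarnings(cpm(Z, y, threshold = 0.5, n_permutations = 60, seed = 9))
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$permutation_accuracy, f2$permutation_accuracy)

  # p is exactly the proportion of permuted accuracies >= observed
  expect_equal(unname(f1$p_value["pos"]),
               mean(f1$permutation_accuracy[, "pos"] >= f1$accuracy["pos"]))
  # add-one option bounds p away from zero
  f3 <- suppressWarnings(cpm(Z, y, threshold = 0.5, n_permutations = 60,
                             seed = 9, add_one = TRUE))
  expect_equal(unname(f3$p_value["pos"]),
               (1 + sum(f3$permutation_accuracy[, "pos"] >= f3$accuracy["pos"])) / 61)
  expect_gt(f3$p_value["pos"], 0)
})

test_that("consensus networks follow the fold-fraction rule", {
  folds <- c(replicate(46, list(c(1L, 7L))), list(c(7L)))  # edge 1 in 46/47
  cons <- consensus_network(folds, fraction = 0.9, n_folds = 47)
  expect_true(1L %in% cons$edge)
  expect_true(7L %in% cons$edge)
  expect_equal(cons$fold_fraction[cons$edge == 1L], 46 / 47)

  half <- c(replicate(10, list(1L)), replicate(10, list(integer(0))))
  expect_equal(nrow(consensus_network(half, fraction = 0.9, n_folds = 20)), 0)
  # fraction 1: intersection of folds
  inter <- consensus_network(list(c(1L, 2L), c(2L, 3L)), fraction = 1, n_folds = 2)
  expect_equal(inter$edge, 2L)
})

test_that("degree summaries obey the handshake lemma and proportions", {
  edges <- data.frame(i = c(0L, 0L, 1L, 2L), j = c(1L, 2L, 2L, 3L))
  atlas <- c("MF", "FP", "MF", "SAL")
  ds <- degree_summary(edges, atlas)
  expect_equal(sum(ds$degrees$degree), 2 * nrow(edges))
  expect_equal(sum(ds$pair_counts), nrow(edges))
  expect_equal(ds$degrees$proportion, ds$degrees$degree / nrow(edges))
  # the printed worked example: degree 24 of 1210 edges -> 0.020
  expect_equal(round(24 / 1210, 3), 0.020)
  expect_error(degree_summary(data.frame(i = 0L, j = 9L), atlas), "outside")
})

test_that("top-node extraction keeps 10% of nodes and includes ties", {
  deg <- data.frame(node = 0:219, network = synthetic_atlas(220),
                    degree = rev(seq_len(220)), proportion = 0)
  expect_equal(nrow(top_nodes(deg, 0.10)), 22)
  expect_equal(nrow(top_nodes(deg, 1)), 220)
  deg$degree <- rep(1L, 220)  # full tie: everything at the cut comes along
  expect_message(tn <- top_nodes(deg, 0.10), "tied")
  expect_equal(nrow(tn), 220)
})

test_that("cpm object methods are coherent", {
  set.seed(35)
  n <- 15
  Z <- matrix(rnorm(n * 28), n)
  y <- Z[, 4] + rnorm(n, 0, 0.4)
  fit <- suppressWarnings(cpm(Z, y, threshold = 0.5, n_permutations = 30, seed = 1))
  expect_s3_class(fit, "cpm")
  expect_equal(nrow(predict(fit)), n)
  expect_equal(residuals(fit, "pos"), y - fit$predictions$pos)
  co <- coef(fit)
  expect_equal(rownames(co), c("pos", "neg"))
  s <- summary(fit)
  expect_s3_class(s, "summary.cpm")
  expect_output(print(fit), "Connectome-based")
  # predict on new subjects uses the full-sample model
  pn <- predict(fit, Z[1:3, , drop = FALSE])
  expect_equal(nrow(pn), 3)
  fm <- fit$full_model
  s1 <- if (length(fm$pos_edges)) sum(Z[1, fm$pos_edges]) else 0
  expect_equal(pn$pos[1], unname(fm$pos["intercept"] + fm$pos["slope"] * s1))
  # full-sample selection agrees with partial_spearman edge by edge
  rho_check <- vapply(fm$pos_edges, function(e) partial_spearman(Z[, e], y),
                      numeric(1))
  if (length(rho_check)) expect_true(all(rho_check > 0.5))
})

test_that("matrix-list input matches edge-matrix input", {
  set.seed(36)
  n <- 12; N <- 9
  mats <- replicate(n, {
    X <- matrix(rnorm(60 * N), 60)
    connectivity_matrix(X)
  }, simplify = FALSE)
  Z <- do.call(rbind, lapply(mats, function(m) upper_vec(m$z)))
  y <- Z[, 10] + rnorm(n, 0, 0.3)
  f1 <- suppressWarnings(cpm(mats, y, threshold = 0.5))
  f2 <- suppressWarnings(cpm(Z, y, threshold = 0.5))
  expect_equal(f1$predictions, f2$predictions, tolerance = 1e-12)
  expect_equal(f1$n_nodes, N)
  # consensus carries node pairs when the node count is known
  cons <- consensus_network(f1)
  if (nrow(cons$pos)) expect_true(all(c("i", "j") %in% names(cons$pos)))
})
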