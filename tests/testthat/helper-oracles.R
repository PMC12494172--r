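# Independent oracles and fixture builders used across the suite.

# Noise-free gaze stream with planted fixation segments: constant-position
# segments on the 20 ms sample grid, joined by saccadic sweeps whose
# per-sample steps exceed the velocity threshold. Returns the stream plus
# the planted segment table.
planted_fixation_stream <- function(seed, n_segments = NULL, dt = 20) {
  set.seed(seed)
  k <- n_segments %||% sample(3:8, 1)
  pos <- matrix(NA_real_, k, 2)
  pos[1, ] <- runif(2, -10, 10)
  for (s in seq_len(k - 1)) {
    repeat {
      p <- runif(2, -12, 12)
      if (sqrt(sum((p - pos[s, ])^2)) >= 5) break
    }
    pos[s + 1, ] <- p
  }
  seg_samples <- sample(5:30, k, replace = TRUE)     # 80-580 ms spans
  gap_samples <- sample(1:3, k - 1, replace = TRUE)

  t <- c(); x <- c(); y <- c()
  seg_tab <- data.frame(start_ms = numeric(k), end_ms = numeric(k),
                        x = pos[, 1], y = pos[, 2])
  clock <- 0
  for (s in seq_len(k)) {
    ts <- seq(clock, by = dt, length.out = seg_samples[s])
    t <- c(t, ts)
    x <- c(x, rep(pos[s, 1], seg_samples[s]))
    y <- c(y, rep(pos[s, 2], seg_samples[s]))
    seg_tab$start_ms[s] <- ts[1]
    seg_tab$end_ms[s] <- ts[length(ts)]
    clock <- ts[length(ts)] + dt
    if (s < k) {
      g <- gap_samples[s]
      frac <- seq_len(g) / (g + 1)
      t <- c(t, seq(clock, by = dt, length.out = g))
      x <- c(x, pos[s, 1] + frac * (pos[s + 1, 1] - pos[s, 1]))
      y <- c(y, pos[s, 2] + frac * (pos[s + 1, 2] - pos[s, 2]))
      clock <- clock + g * dt
    }
  }
  list(stream = data.frame(time_ms = t, x = x, y = y, valid = TRUE),
       segments = seg_tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive fold-by-fold CPM reimplementation: explicit ranks, lm residuals and
# per-fold loops, sharing no code with the package engine.
naive_cpm <- function(Z, y, covariates, threshold) {
  n <- nrow(Z)
  M <- if (is.null(covariates)) NULL else stats::model.matrix(~ ., covariates)
  pred <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("pos", "neg")))
  folds_pos <- vector("list", n); folds_neg <- vector("list", n)
  for (f in seq_len(n)) {
    tr <- setdiff(seq_len(n), f)
    rho <- vapply(seq_len(ncol(Z)), function(e) {
      rx <- rank(Z[tr, e]); ry <- rank(y[tr])
      if (stats::sd(rx) == 0) return(0)
      if (is.null(M)) return(stats::cor(rx, ry))
      ex <- stats::residuals(stats::lm.fit(M[tr, , drop = FALSE], rx))
      ey <- stats::residuals(stats::lm.fit(M[tr, , drop = FALSE], ry))
      stats::cor(ex, ey)
    }, numeric(1))
    folds_pos[[f]] <- which(rho > threshold)
    folds_neg[[f]] <- which(rho < -threshold)
    for (s in c("pos", "neg")) {
      sel <- if (s == "pos") folds_pos[[f]] else folds_neg[[f]]
      st <- if (length(sel)) rowSums(Z[, sel, drop = FALSE]) else rep(0, n)
      if (length(sel) == 0 || stats::var(st[tr]) < 1e-12) {
        pred[f, s] <- mean(y[tr])
      } else {
        b <- stats::cov(st[tr], y[tr]) / stats::var(st[tr])
        pred[f, s] <- mean(y[tr]) - b * mean(st[tr]) + b * st[f]
      }
    }
  }
  acc <- c(pos = stats::cor(rank(pred[, "pos"]), rank(y)),
           neg = stats::cor(rank(pred[, "neg"]), rank(y)))
  list(pred = pred, acc = acc, folds_pos = folds_pos, folds_neg = folds_neg)
}

# Brute-force two-way within-subject ANOVA oracle: raw sums of squares for
# the AxB interaction and its subject interaction error, plus the
# Greenhouse-Geisser epsilon from the covariance of orthonormalized
# interaction contrasts.
brute_rm_anova <- function(data) {
  data$aoi <- factor(data$aoi); data$cs_type <- factor(data$cs_type)
  data$participant <- factor(data$participant)
  a <- nlevels(data$aoi); b <- nlevels(data$cs_type)
  n <- nlevels(data$participant)
  Y <- array(NA_real_, c(n, a, b))
  for (r in seq_len(nrow(data)))
    Y[as.integer(data$participant[r]), as.integer(data$aoi[r]),
      as.integer(data$cs_type[r])] <- data$pct[r]
  m_jk <- apply(Y, c(2, 3), mean)
  m_ij <- apply(Y, c(1, 2), mean)
  m_ik <- apply(Y, c(1, 3), mean)
  m_i <- apply(Y, 1, mean); m_j <- apply(Y, 2, mean); m_k <- apply(Y, 3, mean)
  g <- mean(Y)
  ss_ab <- n * sum((sweep(sweep(m_jk, 1, m_j, "-"), 2, m_k, "-") + g)^2)
  resid <- Y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    resid[i, j, k] <- Y[i, j, k] - m_jk[j, k] - m_ij[i, j] - m_ik[i, k] +
      m_j[j] + m_k[k] + m_i[i] - g
  ss_abs <- sum(resid^2)
  df1 <- (a - 1) * (b - 1); df2 <- df1 * (n - 1)
  Fv <- (ss_ab / df1) / (ss_abs / df2)

  # orthonormal basis of the interaction contrast subspace; epsilon depends
  # only on the subspace, not the particular basis. Cell columns of W are in
  # the array's natural order (aoi fastest, cs slowest), so the slow factor
  # comes first in the kronecker product.
  on_contr <- function(m) qr.Q(qr(stats::contr.helmert(m)))
  C <- kronecker(on_contr(b), on_contr(a))
  W <- matrix(Y, n, a * b)
  S <- stats::cov(W %*% C)
  eps <- sum(diag(S))^2 / (ncol(C) * sum(S^2))
  list(F = Fv, df = c(df1, df2), epsilon = eps,
       p = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE))
}

# Textbook Welch statistic.
brute_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Small in-memory study for smoke tests.
tiny_study <- function(seed = 99, n = 12, nodes = 20, gaze = TRUE) {
  simulate_study(study_config(n_participants = n, n_nodes = nodes,
                              n_volumes = 120, n_planted = 6, seed = seed),
                 gaze = gaze)
}

# Map 0-based planted node pairs to edge indices for a given node count.
planted_edge_index <- function(true_edges, n_nodes) {
  ep <- edge_pairs(n_nodes)
  match(paste(true_edges[, 1], true_edges[, 2]), paste(ep$i, ep$j))
}
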