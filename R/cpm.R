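#' Partial Spearman rank correlation
#'
#' Both variables are rank-transformed (average ranks for ties), each is
#' residualized on the covariate design (categorical covariates
#' indicator-coded, continuous covariates entered unranked), and the
#' residuals are Pearson-correlated. With no covariates this reduces to the
#' plain Spearman rho.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional data frame of covariates (same rows).
#' @return partial Spearman rho.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(stats::cor(rx, ry))
  M <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(M) != length(x)) stop("covariate rows must match x/y length")
  if (length(x) < ncol(M) + 2) stop("too few observations for the covariate design")
  q <- qr(M)
  stats::cor(qr.resid(q, rx), qr.resid(q, ry))
}

#' Threshold edge correlations into positive and negative networks
#'
#' Strict cut: edges with `rho > threshold` form the positive network,
#' `rho < -threshold` the negative network.
#'
#' @param rho per-edge correlation vector.
#' @param threshold absolute-rho selection threshold (default 0.3).
#' @return list with integer index vectors `pos` and `neg`.
#' @export
select_edges <- function(rho, threshold = 0.3) {
  list(pos = which(rho > threshold), neg = which(rho < -threshold))
}

#' Summed network strength
#'
#' The connectivity strength of a subject in an edge set: the sum of
#' Fisher-z values over those edges.
#'
#' @param z either a subject's edge vector (length E) or a `conn_matrix`.
#' @param edges integer edge indices into the [edge_pairs()] enumeration.
#' @return numeric scalar (0 for an empty edge set).
#' @export
network_strength <- function(z, edges) {
  v <- if (inherits(z, "conn_matrix")) upper_vec(z$z) else as.numeric(z)
  if (length(edges) == 0) return(0)
  if (any(edges < 1 | edges > length(v))) stop("edge index outside the edge vector")
  sum(v[edges])
}

# Convert accepted connectivity inputs to an n x E edge matrix.
as_edge_matrix <- function(x) {
  if (is.matrix(x) && !inherits(x, "conn_matrix")) {
    return(list(Z = x, n_nodes = NULL))
  }
  if (is.list(x)) {
    mats <- lapply(x, function(m) if (inherits(m, "conn_matrix")) m$z else as.matrix(m))
    N <- unique(vapply(mats, nrow, integer(1)))
    if (length(N) != 1) stop("all connectivity matrices must share dimensions")
    Z <- do.call(rbind, lapply(mats, upper_vec))
    return(list(Z = Z, n_nodes = N))
  }
  stop("x must be an n x E edge matrix or a list of connectivity matrices")
}

# Vectorized LOOCV engine shared by the observed fit and the permutation
# null: Ymat holds one behavior vector per column (column 1 = observed).
# Per fold, edge ranks and covariate residualization are computed once and
# reused across all columns through BLAS products; this is algebraically
# identical to rerunning the whole pipeline per permutation because fold
# membership does not depend on the behavior values.
cpm_engine <- function(Z, Ymat, M, threshold, track_edges = TRUE) {
  n <- nrow(Z); E <- ncol(Z); B <- ncol(Ymat)
  pred_pos <- matrix(NA_real_, n, B)
  pred_neg <- matrix(NA_real_, n, B)
  fold_pos <- if (track_edges) vector("list", n) else NULL
  fold_neg <- if (track_edges) vector("list", n) else NULL
  empty_folds <- c(pos = 0L, neg = 0L)

  for (f in seq_len(n)) {
    train <- setdiff(seq_len(n), f)
    m <- length(train)
    Q <- qr(cbind(rep(1, m), if (!is.null(M)) M[train, , drop = FALSE]))

    ZR <- apply(Z[train, , drop = FALSE], 2, rank)
    ER <- qr.resid(Q, ZR)
    en <- sqrt(colSums(ER^2))
    en[en == 0] <- Inf                      # constant edges: rho -> 0
    ER <- ER / rep(en, each = m)

    YR <- apply(Ymat[train, , drop = FALSE], 2, rank)
    YRr <- qr.resid(Q, YR)
    yn <- sqrt(colSums(YRr^2))
    if (any(yn == 0)) stop("behavior constant (after covariate residualization) in a training fold")
    YRr <- YRr / rep(yn, each = m)

    RHO <- crossprod(ER, YRr)               # E x B
    POS <- RHO > threshold
    NEG <- RHO < -threshold
    if (track_edges) {
      fold_pos[[f]] <- which(POS[, 1])
      fold_neg[[f]] <- which(NEG[, 1])
      if (length(fold_pos[[f]]) == 0) empty_folds["pos"] <- empty_folds["pos"] + 1L
      if (length(fold_neg[[f]]) == 0) empty_folds["neg"] <- empty_folds["neg"] + 1L
    }

    Yt <- Ymat[train, , drop = FALSE]
    sy <- colSums(Yt)
    for (sign in c("pos", "neg")) {
      SEL <- if (sign == "pos") POS else NEG
      S <- Z %*% SEL                        # n x B strengths
      St <- S[train, , drop = FALSE]
      sx <- colSums(St); sxx <- colSums(St^2); sxy <- colSums(St * Yt)
      denom <- sxx - sx^2 / m
      slope <- ifelse(denom > 1e-12, (sxy - sx * sy / m) / denom, 0)
      intercept <- ifelse(denom > 1e-12, (sy - slope * sx) / m, sy / m)
      pred <- intercept + slope * S[f, ]
      if (sign == "pos") pred_pos[f, ] <- pred else pred_neg[f, ] <- pred
    }
  }

  spearman_cols <- function(P) {
    vapply(seq_len(B), function(b) {
      p <- P[, b]; y <- Ymat[, b]
      if (stats::sd(p) == 0) return(0)
      stats::cor(rank(p), rank(y))
    }, numeric(1))
  }
  list(pred_pos = pred_pos, pred_neg = pred_neg,
       acc_pos = spearman_cols(pred_pos), acc_neg = spearman_cols(pred_neg),
       fold_pos = fold_pos, fold_neg = fold_neg, empty_folds = empty_folds)
}

#' Connectome-based predictive modeling (CPM)
#'
#' Fits the CPM estimator with leave-one-out cross-validation (LOOCV). For
#' each held-out subject, every edge of the training subjects' Fisher-z
#' connectivity is correlated with the behavioral target by partial Spearman
#' correlation (controlling for the supplied covariates); edges with
#' `|rho| > threshold` form a positive and a negative network; a univariate
#' least-squares line of behavior on summed network strength is fit per
#' network, and the held-out subject's strength over the training-selected
#' edges yields their predicted score. Prediction accuracy is the Spearman
#' correlation of predicted versus observed scores; significance comes from
#' permutation testing (behavior shuffled against the matrices, covariates
#' kept aligned with the matrices, the full LOOCV pipeline rerun each time):
#' `p = #(permuted accuracy >= observed) / B`.
#'
#' Folds with an empty selected edge set predict the training mean (a
#' conservative fallback that keeps the LOOCV sample intact); a warning
#' reports how many folds were affected.
#'
#' @param x connectivity input: an `n x E` matrix of edge vectors (rows =
#'   subjects, columns in [edge_pairs()] order) or a list of `conn_matrix` /
#'   symmetric matrices.
#' @param behavior numeric behavioral target, length n (e.g. the ST/GT
#'   regression coefficient).
#' @param covariates optional data frame of per-subject covariates (age,
#'   sex, run order, hunger, WHR, scanner, ...); categoricals are
#'   indicator-coded.
#' @param threshold absolute partial-rho edge selection cut (default 0.3).
#' @param n_permutations permutations for the null distribution (default 0 =
#'   no inference; the reference analysis used 10,000).
#' @param consensus_fraction fraction of folds an edge must be selected in
#'   to enter the consensus network (default 0.9).
#' @param seed RNG seed for the permutations.
#' @param add_one use the add-one-smoothed permutation p
#'   `(1 + #) / (B + 1)` instead of the plain proportion (default FALSE).
#' @return object of class `cpm`; see [summary.cpm()]. Key fields:
#'   `predictions` (per-subject LOOCV predicted scores per network),
#'   `accuracy`, `p_value`, `folds` (per-fold selected edge indices),
#'   `full_model` (selection and line fit on the full sample, used by
#'   [predict.cpm()] for new subjects).
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(20 * 45), 20)
#' y <- Z[, 3] + rnorm(20, 0, 0.1)
#' fit <- cpm(Z, y, threshold = 0.5)
#' fit$accuracy
#' @export
cpm <- function(x, behavior, covariates = NULL, threshold = 0.3,
                n_permutations = 0, consensus_fraction = 0.9, seed = 1L,
                add_one = FALSE) {
  em <- as_edge_matrix(x)
  Z <- em$Z
  n <- nrow(Z)
  if (n < 10) stop("CPM requires at least 10 subjects")
  stopifnot(length(behavior) == n, threshold > 0, threshold < 1,
            consensus_fraction > 0, consensus_fraction <= 1)
  M <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    M <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }

  obs <- cpm_engine(Z, matrix(behavior, ncol = 1), M, threshold, track_edges = TRUE)
  if (any(obs$empty_folds > 0))
    warning(sprintf("empty edge selection in %d (positive) / %d (negative) folds; training-mean prediction used",
                    obs$empty_folds["pos"], obs$empty_folds["neg"]))

  p_value <- NULL
  perm_acc <- NULL
  if (n_permutations >= 1) {
    set.seed(derive_seed(seed, "cpm-perm"))
    perms <- replicate(n_permutations, sample.int(n))
    Ymat <- matrix(behavior[perms], n, n_permutations)
    pe <- cpm_engine(Z, Ymat, M, threshold, track_edges = FALSE)
    perm_acc <- cbind(pos = pe$acc_pos, neg = pe$acc_neg)
    pfun <- function(perm, ob) {
      if (add_one) (1 + sum(perm >= ob)) / (n_permutations + 1)
      else mean(perm >= ob)
    }
    p_value <- c(pos = pfun(pe$acc_pos, obs$acc_pos[1]),
                 neg = pfun(pe$acc_neg, obs$acc_neg[1]))
  }

  # full-sample model for predicting new subjects (vectorized partial
  # Spearman; equivalent to partial_spearman() per edge)
  rho_full <- {
    Qf <- qr(cbind(rep(1, n), M))
    ZRf <- apply(Z, 2, rank)
    ERf <- qr.resid(Qf, ZRf)
    enf <- sqrt(colSums(ERf^2)); enf[enf == 0] <- Inf
    yrf <- qr.resid(Qf, rank(behavior))
    ynf <- sqrt(sum(yrf^2))
    if (ynf == 0) stop("behavior constant after covariate residualization")
    as.numeric(crossprod(ERf / rep(enf, each = n), yrf / ynf))
  }
  sel_full <- select_edges(rho_full, threshold)
  line_fit <- function(edges) {
    s <- if (length(edges)) rowSums(Z[, edges, drop = FALSE]) else rep(0, n)
    if (stats::var(s) < 1e-12) return(c(intercept = mean(behavior), slope = 0))
    b <- stats::cov(s, behavior) / stats::var(s)
    c(intercept = mean(behavior) - b * mean(s), slope = b)
  }
  full_model <- list(pos_edges = sel_full$pos, neg_edges = sel_full$neg,
                     pos = line_fit(sel_full$pos), neg = line_fit(sel_full$neg))

  structure(list(
    call = match.call(), n = n, n_edges = ncol(Z), n_nodes = em$n_nodes,
    threshold = threshold, consensus_fraction = consensus_fraction,
    behavior = behavior,
    covariate_names = if (is.null(covariates)) character(0) else names(covariates),
    predictions = data.frame(pos = obs$pred_pos[, 1], neg = obs$pred_neg[, 1]),
    accuracy = c(pos = obs$acc_pos[1], neg = obs$acc_neg[1]),
    folds = list(pos = obs$fold_pos, neg = obs$fold_neg),
    empty_folds = obs$empty_folds,
    n_permutations = n_permutations, p_value = p_value,
    permutation_accuracy = perm_acc, seed = seed, add_one = add_one,
    full_model = full_model), class = "cpm")
}

#' @export
print.cpm <- function(x, ...) {
  cat("Connectome-based predictive model (LOOCV)\n")
  cat(sprintf("  n = %d subjects, %d edges, |rho| threshold %.2f\n",
              x$n, x$n_edges, x$threshold))
  if (length(x$covariate_names))
    cat("  partial correlation covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  cat(sprintf("  accuracy (Spearman rho): positive %.3f, negative %.3f\n",
              x$accuracy["pos"], x$accuracy["neg"]))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p (B = %d): positive %.4g, negative %.4g\n",
                x$n_permutations, x$p_value["pos"], x$p_value["neg"]))
  invisible(x)
}

#' Summarize a fitted CPM
#'
#' @param object a `cpm` fit.
#' @param ... unused.
#' @return list of class `summary.cpm` with accuracy, permutation p,
#'   consensus edge counts and per-fold selection size statistics.
#' @export
summary.cpm <- function(object, ...) {
  cons <- consensus_network(object)
  sel_sizes <- list(pos = lengths(object$folds$pos), neg = lengths(object$folds$neg))
  out <- list(n = object$n, n_edges = object$n_edges,
              threshold = object$threshold,
              accuracy = object$accuracy, p_value = object$p_value,
              n_permutations = object$n_permutations,
              consensus_fraction = object$consensus_fraction,
              consensus_sizes = c(pos = nrow(cons$pos), neg = nrow(cons$neg)),
              selection_size_range = lapply(sel_sizes, range),
              empty_folds = object$empty_folds)
  class(out) <- "summary.cpm"
  out
}

#' @export
print.summary.cpm <- function(x, ...) {
  cat("CPM summary\n")
  cat(sprintf("  n = %d subjects, %d edges, threshold %.2f\n", x$n, x$n_edges, x$threshold))
  cat(sprintf("  accuracy: pos %.3f, neg %.3f\n", x$accuracy["pos"], x$accuracy["neg"]))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p (B = %d): pos %.4g, neg %.4g\n",
                x$n_permutations, x$p_value["pos"], x$p_value["neg"]))
  cat(sprintf("  consensus network (>= %.0f%% of folds): %d positive, %d negative edges\n",
              100 * x$consensus_fraction, x$consensus_sizes["pos"], x$consensus_sizes["neg"]))
  cat(sprintf("  per-fold selection sizes: pos %d-%d, neg %d-%d\n",
              x$selection_size_range$pos[1], x$selection_size_range$pos[2],
              x$selection_size_range$neg[1], x$selection_size_range$neg[2]))
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) {
  rbind(pos = object$full_model$pos, neg = object$full_model$neg)
}

#' Predict behavior for new subjects from a fitted CPM
#'
#' Without `newdata`, returns the LOOCV (out-of-fold) predictions stored in
#' the fit. With `newdata`, applies the full-sample model: network strength
#' over the full-sample selected edges, fed through the full-sample line
#' fit. Full-sample predictions for training subjects are in-sample and must
#' not be used to assess accuracy.
#'
#' @param object a `cpm` fit.
#' @param newdata optional connectivity input (same forms as in [cpm()]).
#' @param ... unused.
#' @return data frame with columns `pos` and `neg`.
#' @export
predict.cpm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  Z <- as_edge_matrix(newdata)$Z
  if (ncol(Z) != object$n_edges) stop("newdata edge count mismatch")
  fm <- object$full_model
  s_pos <- if (length(fm$pos_edges)) rowSums(Z[, fm$pos_edges, drop = FALSE]) else rep(0, nrow(Z))
  s_neg <- if (length(fm$neg_edges)) rowSums(Z[, fm$neg_edges, drop = FALSE]) else rep(0, nrow(Z))
  data.frame(pos = fm$pos["intercept"] + fm$pos["slope"] * s_pos,
             neg = fm$neg["intercept"] + fm$neg["slope"] * s_neg,
             row.names = NULL)
}

#' @export
residuals.cpm <- function(object, network = c("pos", "neg"), ...) {
  network <- match.arg(network)
  object$behavior - object$predictions[[network]]
}

#' Observed-versus-predicted plot for a fitted CPM
#'
#' @param x a `cpm` fit.
#' @param network `"pos"` or `"neg"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cpm <- function(x, network = c("pos", "neg"), ...) {
  network <- match.arg(network)
  pred <- x$predictions[[network]]
  graphics::plot(pred, x$behavior,
                 xlab = "predicted score (LOOCV)", ylab = "observed score",
                 main = sprintf("%s network: rho = %.3f%s",
                                if (network == "pos") "Positive" else "Negative",
                                x$accuracy[network],
                                if (!is.null(x$p_value))
                                  sprintf(", perm p = %.3g", x$p_value[network]) else ""),
                 ...)
  graphics::abline(stats::lm(x$behavior ~ pred), lty = 2)
  invisible(x)
}

#' Consensus network across LOOCV folds
#'
#' Edges selected in at least `fraction` of all folds (selection count
#' `>= fraction * n_folds`) form the consensus network used for reporting
#' and anatomy summaries.
#'
#' @param object a `cpm` fit, or a list of per-fold integer edge-index
#'   vectors.
#' @param fraction consensus fraction (defaults to the fit's setting).
#' @param n_folds number of folds (required when `object` is a plain list).
#' @return for a `cpm` fit, a list of data frames `pos` and `neg` with
#'   columns `edge` (index), `fold_fraction`, and — when the node count is
#'   known — `i`, `j` (0-based node pairs); for a plain list, one such data
#'   frame.
#' @export
consensus_network <- function(object, fraction = NULL, n_folds = NULL) {
  if (inherits(object, "cpm")) {
    fraction <- fraction %||% object$consensus_fraction
    build <- function(fold_list) {
      df <- consensus_from_folds(fold_list, fraction, length(fold_list))
      if (!is.null(object$n_nodes) && nrow(df)) {
        ep <- edge_pairs(object$n_nodes)
        df$i <- ep$i[df$edge]; df$j <- ep$j[df$edge]
      }
      df
    }
    return(list(pos = build(object$folds$pos), neg = build(object$folds$neg)))
  }
  if (is.null(fraction) || is.null(n_folds))
    stop("fraction and n_folds are required for a plain fold list")
  consensus_from_folds(object, fraction, n_folds)
}

consensus_from_folds <- function(fold_list, fraction, n_folds) {
  all_edges <- unlist(fold_list)
  if (length(all_edges) == 0)
    return(data.frame(edge = integer(0), fold_fraction = numeric(0)))
  counts <- table(all_edges)
  keep <- counts >= fraction * n_folds
  data.frame(edge = as.integer(names(counts)[keep]),
             fold_fraction = as.numeric(counts[keep]) / n_folds,
             row.names = NULL)
}

#' Node-degree and canonical-network summaries of a consensus network
#'
#' Degree is the number of incident consensus edges per node; the degree
#' proportion expresses it relative to the consensus network size (e.g. a
#' degree of 24 in a 1210-edge network is 0.020). The pair-count matrix
#' accumulates each edge into the unordered canonical-network pair of its
#' endpoints (the numeric counterpart of a chord diagram).
#'
#' @param edges data frame with 0-based node columns `i`, `j` (e.g. from
#'   [consensus_network()]).
#' @param atlas character vector of canonical-network labels, one per node
#'   (e.g. [synthetic_atlas()]).
#' @return list: `degrees` (data frame `node` 0-based, `network`, `degree`,
#'   `proportion`, sorted by decreasing degree), `pair_counts` (K x K
#'   symmetric-by-construction upper matrix of edge counts),
#'   `n_edges`.
#' @export
degree_summary <- function(edges, atlas) {
  n_nodes <- length(atlas)
  if (nrow(edges) && max(edges$i, edges$j) >= n_nodes)
    stop("edge references node outside the atlas")
  deg <- tabulate(c(edges$i, edges$j) + 1L, nbins = n_nodes)
  n_edges <- nrow(edges)
  labs <- unique(atlas)
  pc <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  if (n_edges) {
    a <- atlas[edges$i + 1L]; b <- atlas[edges$j + 1L]
    ia <- match(a, labs); ib <- match(b, labs)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    for (k in seq_len(n_edges)) pc[lo[k], hi[k]] <- pc[lo[k], hi[k]] + 1L
  }
  deg_df <- data.frame(node = seq_len(n_nodes) - 1L, network = atlas,
                       degree = deg,
                       proportion = if (n_edges) deg / n_edges else 0)
  deg_df <- deg_df[order(-deg_df$degree, deg_df$node), ]
  rownames(deg_df) <- NULL
  list(degrees = deg_df, pair_counts = pc, n_edges = n_edges)
}

#' Highest-degree nodes of a consensus network
#'
#' Ranks nodes by consensus degree and returns the top fraction
#' (`round(top_fraction * N)` nodes; 10% of 220 nodes is 22). Nodes tied
#' with the last included degree are all included, so the returned count can
#' exceed the nominal cut; a message notes when that happens.
#'
#' @param degrees degree data frame from [degree_summary()].
#' @param top_fraction fraction of nodes to keep (default 0.10).
#' @return the top rows of `degrees`.
#' @export
top_nodes <- function(degrees, top_fraction = 0.10) {
  n <- nrow(degrees)
  k <- max(1L, round(top_fraction * n))
  d <- degrees[order(-degrees$degree, degrees$node), ]
  cut_deg <- d$degree[k]
  keep <- which(d$degree >= cut_deg)
  if (length(keep) > k)
    message(length(keep) - k, " node(s) tied at the degree cut; all included")
  out <- d[keep, ]
  rownames(out) <- NULL
  out
}
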