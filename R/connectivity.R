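#' Flag high-motion volumes by framewise displacement
#'
#' Volumes whose framewise displacement (FD) strictly exceeds the threshold
#' (default 0.5 mm) are flagged as motion spikes and later regressed out of
#' the node timecourses.
#'
#' @param fd per-volume FD values in mm (non-negative).
#' @param threshold spike threshold in mm (default 0.5).
#' @return logical vector of spike flags.
#' @examples
#' flag_spikes(c(0.1, 0.6, 0.5))  # FALSE TRUE FALSE
#' @export
flag_spikes <- function(fd, threshold = 0.5) {
  if (any(fd < 0)) stop("framewise displacement must be non-negative")
  fd > threshold
}

#' Decide whether a run is excluded for excessive motion
#'
#' A run is excluded when the flagged fraction of volumes strictly exceeds
#' `max_fraction` (default 25%).
#'
#' @param spike_flags logical spike flags ([flag_spikes()]).
#' @param max_fraction maximum tolerated spike fraction (default 0.25).
#' @return `TRUE` if the run is excluded, `FALSE` if kept.
#' @export
exclude_run <- function(spike_flags, max_fraction = 0.25) {
  mean(spike_flags) > max_fraction
}

#' Detrend, standardize and confound-regress node timecourses
#'
#' Per node: remove the linear trend, z-score, then jointly regress out the
#' 16 nuisance columns (6 motion parameters, their derivatives, global, CSF
#' and white-matter signals, FD) together with one indicator column per
#' flagged volume. The indicators exactly annihilate the flagged rows
#' (censoring by regression), so spikes cannot propagate into correlations.
#' Collinear nuisance columns are dropped with a warning. Residuals are not
#' re-standardized.
#'
#' @param timecourses T x N numeric matrix (volumes x nodes).
#' @param confounds T-row data frame or matrix of nuisance regressors.
#' @param spike_flags logical length-T spike flags (default: none).
#' @return T x N residual matrix with attribute `n_volumes_used` (unflagged
#'   volume count).
#' @export
clean_timecourses <- function(timecourses, confounds = NULL, spike_flags = NULL) {
  X <- as.matrix(timecourses)
  Tn <- nrow(X)
  if (is.null(spike_flags)) spike_flags <- rep(FALSE, Tn)
  stopifnot(length(spike_flags) == Tn)
  if (!is.null(confounds) && nrow(as.matrix(confounds)) != Tn)
    stop("confounds and timecourses must have equal row counts")
  if (anyNA(X) || (!is.null(confounds) && anyNA(confounds)))
    stop("missing values are not allowed")

  tt <- seq_len(Tn)
  # detrend: residual of regression on (1, t)
  Qt <- qr(cbind(1, tt))
  X <- qr.resid(Qt, X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  X <- sweep(X, 2, sds, "/")

  D <- cbind(rep(1, Tn), if (!is.null(confounds)) as.matrix(confounds))
  if (any(spike_flags)) {
    ind <- matrix(0, Tn, sum(spike_flags))
    ind[cbind(which(spike_flags), seq_len(sum(spike_flags)))] <- 1
    D <- cbind(D, ind)
  }
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    warning("dropping ", ncol(D) - qd$rank, " collinear nuisance column(s)")
    D <- D[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
    qd <- qr(D)
  }
  res <- qr.resid(qd, X)
  attr(res, "n_volumes_used") <- sum(!spike_flags)
  res
}

#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between every pair of retained node timecourses,
#' Fisher-transformed (`z = atanh(r)` with `|r|` clipped at `1 - 1e-7` so
#' degenerate pairs stay finite while preserving ordering).
#'
#' @param clean cleaned T x N matrix ([clean_timecourses()]).
#' @param drop_nodes integer node indices (1-based columns) to remove before
#'   correlation — e.g. cerebellar nodes with inadequate coverage.
#' @param node_ids optional node labels (length N before dropping).
#' @return object of class `conn_matrix`: `z` (symmetric matrix, zero
#'   diagonal), `node_ids`, `n_volumes_used`, `clipped` (count of clipped
#'   pairs).
#' @examples
#' x <- matrix(rnorm(300), 100)
#' cm <- connectivity_matrix(x)
#' dim(cm$z)
#' @export
connectivity_matrix <- function(clean, drop_nodes = NULL, node_ids = NULL) {
  X <- as.matrix(clean)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(ncol(X)))
  stopifnot(length(node_ids) == ncol(X))
  if (!is.null(drop_nodes) && length(drop_nodes)) {
    X <- X[, -drop_nodes, drop = FALSE]
    node_ids <- node_ids[-drop_nodes]
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance node(s): ", paste(node_ids[sds == 0], collapse = ", "))
  r <- stats::cor(X)
  clip <- 1 - 1e-7
  off <- row(r) != col(r)
  n_clipped <- sum(abs(r[off]) >= clip) / 2
  r[off] <- pmin(pmax(r[off], -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  structure(list(z = z, node_ids = node_ids,
                 n_volumes_used = attr(clean, "n_volumes_used") %||% nrow(X),
                 clipped = n_clipped),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  n <- nrow(x$z)
  cat(sprintf("Fisher-z connectivity matrix: %d x %d (%d edges), %s volumes used\n",
              n, n, n * (n - 1) / 2, x$n_volumes_used))
  if (x$clipped > 0) cat("  ", x$clipped, "near-degenerate pair(s) clipped\n")
  invisible(x)
}

#' Full per-run connectivity processing
#'
#' Convenience wrapper: FD spike flagging, the >25% motion exclusion rule,
#' cleaning and Fisher-z correlation in one call.
#'
#' @param timecourses T x N matrix.
#' @param confounds nuisance table whose last column
#'   (`framewise_displacement`) supplies FD when `fd` is not given.
#' @param fd optional explicit FD vector.
#' @param fd_threshold spike threshold, mm.
#' @param max_spike_fraction run-exclusion fraction.
#' @param drop_nodes,node_ids passed to [connectivity_matrix()].
#' @return a `conn_matrix`, or `NULL` for runs failing the motion criterion.
#' @export
process_run <- function(timecourses, confounds, fd = NULL, fd_threshold = 0.5,
                        max_spike_fraction = 0.25, drop_nodes = NULL,
                        node_ids = NULL) {
  if (is.null(fd)) {
    if (!"framewise_displacement" %in% colnames(confounds))
      stop("no FD vector and no 'framewise_displacement' confound column")
    fd <- confounds[, "framewise_displacement"]
    fd <- as.numeric(unlist(fd))
  }
  flags <- flag_spikes(fd, fd_threshold)
  if (exclude_run(flags, max_spike_fraction)) return(NULL)
  clean <- clean_timecourses(timecourses, confounds, flags)
  connectivity_matrix(clean, drop_nodes = drop_nodes, node_ids = node_ids)
}
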