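#' Enumerate edges of an undirected graph on N nodes
#'
#' Edges are the strict upper triangle of an N x N matrix in row-major order,
#' with 0-based node indices: (0,1), (0,2), ..., (0,N-1), (1,2), ... This
#' fixed convention makes edge indices portable across runs and output files.
#'
#' @param n_nodes number of nodes.
#' @return data frame with integer columns `i` and `j` (0-based, `i < j`),
#'   one row per edge, `n_nodes * (n_nodes - 1) / 2` rows in total.
#' @examples
#' edge_pairs(4)
#' nrow(edge_pairs(220))  # 24090
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 2)
  n <- as.integer(n_nodes)
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L))) + i
  data.frame(i = i - 1L, j = j - 1L)
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Returns entries in the edge order of [edge_pairs()] (row-major upper
#' triangle). For a symmetric matrix this equals the column-major lower
#' triangle, which is how the extraction is implemented.
#'
#' @param m square symmetric matrix.
#' @return numeric vector of length `N (N - 1) / 2`.
#' @export
upper_vec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[lower.tri(m)]
}

# Derive a stage-specific seed from a root seed so that independent stages
# draw from decorrelated streams but everything reproduces from one integer.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
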