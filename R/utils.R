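#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pchisq pnorm pt qt rnorm rpois runif sd var median
#'   quantile rbinom lm.fit fft
#' @importFrom utils head write.csv read.csv write.table read.delim
NULL

# Upper-triangle edge bookkeeping: every N x N symmetric matrix is flattened
# to a length-N(N-1)/2 vector in (i, j) lexicographic order (i < j, 1-based).

#' Enumerate node pairs of an N-node undirected graph
#'
#' Returns all unordered pairs (i, j), i < j, in lexicographic order. This is
#' the canonical edge ordering used throughout the package when a symmetric
#' matrix is flattened to an edge vector.
#'
#' @param n_nodes number of nodes.
#' @return integer matrix with columns `i`, `j` and `n_nodes*(n_nodes-1)/2` rows.
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

# Flatten the upper triangle of a symmetric matrix in (i, j) lex order.
ut_vector <- function(m) {
  n <- nrow(m)
  ep <- edge_pairs(n)
  m[cbind(ep[, 1L], ep[, 2L])]
}

# Rebuild a symmetric matrix (zero diagonal) from a lex-ordered edge vector.
ut_matrix <- function(v, n_nodes) {
  ep <- edge_pairs(n_nodes)
  stopifnot(length(v) == nrow(ep))
  m <- matrix(0, n_nodes, n_nodes)
  m[cbind(ep[, 1L], ep[, 2L])] <- v
  m[cbind(ep[, 2L], ep[, 1L])] <- v
  m
}

# Half-up rounding to the nearest integer (round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Stop unless x is a single finite number inside [lo, hi].
check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  bad_lo <- if (open_lo) x <= lo else x < lo
  bad_hi <- if (open_hi) x >= hi else x > hi
  if (bad_lo || bad_hi)
    stop(sprintf("`%s` = %g is outside %s%g, %g%s", name, x,
                 if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a master seed (double
# arithmetic: products stay well below 2^53 before the modulus).
derive_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483563) * 1103 +
                as.numeric(stream) * 12289) %% 2147483563)
}
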