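# Connectivity matrices and sparsity-thresholded binary graphs.

#' Pearson connectivity matrix of a subject
#'
#' Pearson correlation between every pair of regional time series, stored
#' with a zeroed diagonal alongside its Fisher-z transform.
#'
#' @param ts a [roi_timeseries()] with at least 3 timepoints.
#' @param subject_id optional identifier carried on the result.
#' @return an object of class `connectivity_matrix` with fields `r`, `z`,
#'   `subject_id`, `region_ids`.
#' @export
correlation_matrix <- function(ts, subject_id = NA_character_) {
  stopifnot(inherits(ts, "roi_timeseries"), nrow(ts$data) >= 3)
  sds <- apply(ts$data, 2, sd)
  if (any(sds == 0))
    stop(sprintf("constant time series in region(s): %s",
                 paste(ts$region_ids[sds == 0], collapse = ", ")))
  r <- cor(ts$data)
  diag(r) <- 0
  z <- fisher_z(r)
  dimnames(r) <- dimnames(z) <- list(ts$region_ids, ts$region_ids)
  structure(list(r = r, z = z, subject_id = subject_id,
                 region_ids = ts$region_ids), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix: %d x %d (subject %s), mean off-diag r = %.3f\n",
              nrow(x$r), ncol(x$r), x$subject_id, mean(ut_vector(x$r))))
  invisible(x)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, variance-stabilizing Pearson correlations. Values at or
#' beyond |r| = 1 - 1e-7 are clipped (with a warning for |r| = 1) so the
#' transform stays finite.
#'
#' @param r correlation value(s); vectors and matrices accepted.
#' @return transformed values of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    warning("correlations at |r| = 1 clipped before Fisher transform")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Threshold a connectivity matrix into a binary graph at fixed sparsity
#'
#' Retains the `K = round_half_up(s * N(N-1)/2)` largest off-diagonal
#' weights as edges (signed ranking: largest positive correlations first).
#' Ties at the cutoff are broken by ascending (i, j) lexicographic order,
#' so the edge count is exact and the result deterministic.
#'
#' @param m a [correlation_matrix()] result, or a symmetric numeric matrix.
#' @param s sparsity in (0, 1]: fraction of all node pairs kept as edges.
#' @param absolute rank by |weight| instead of signed weight.
#' @return an object of class `binary_graph`: fields `adj` (logical N x N),
#'   `edges` (two-column matrix, lex order), `n_nodes`, `sparsity`.
#' @export
binarize_at_sparsity <- function(m, s, absolute = FALSE) {
  w <- if (inherits(m, "connectivity_matrix")) m$r else as.matrix(m)
  check_scalar(s, "s", 0, 1, open_lo = TRUE)
  n <- nrow(w)
  ep <- edge_pairs(n)
  wv <- ut_vector(w)
  if (absolute) wv <- abs(wv)
  k <- round_half_up(s * n * (n - 1) / 2)
  if (k < 1) stop("sparsity too low: zero edges requested")
  ord <- order(-wv, ep[, 1L], ep[, 2L])
  sel <- sort(ord[seq_len(k)])
  edges <- ep[sel, , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  structure(list(adj = adj, edges = edges, n_nodes = n, sparsity = s),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges (sparsity %.2f)\n",
              x$n_nodes, nrow(x$edges), x$sparsity))
  invisible(x)
}

# igraph view of a binary graph (undirected, simple).
as_igraph <- function(g) {
  igraph::make_graph(as.vector(t(g$edges)), n = g$n_nodes, directed = FALSE)
}

#' Sweep a connectivity matrix across a range of sparsities
#'
#' Produces one binary graph per sparsity level. Because the edge ranking
#' (including the tie-break) is computed once, the graphs are nested: the
#' edge set at a lower sparsity is a subset of the edge set at any higher
#' sparsity.
#'
#' @param m a [correlation_matrix()] or symmetric matrix.
#' @param s_min,s_max,step sweep definition; defaults 0.10 to 0.40 in steps
#'   of 0.01 (31 levels).
#' @param absolute rank by absolute weight.
#' @return list of `binary_graph`s, named by sparsity.
#' @export
sparsity_sweep <- function(m, s_min = 0.10, s_max = 0.40, step = 0.01,
                           absolute = FALSE) {
  check_scalar(step, "step", 0, open_lo = TRUE)
  check_scalar(s_min, "s_min", 0, 1, open_lo = TRUE)
  check_scalar(s_max, "s_max", s_min, 1)
  sparsities <- seq(s_min, s_max + step / 2, by = step)
  sparsities <- sparsities[sparsities <= s_max + 1e-12]
  graphs <- lapply(sparsities, function(s) binarize_at_sparsity(m, s, absolute))
  names(graphs) <- sprintf("%.4g", sparsities)
  graphs
}
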