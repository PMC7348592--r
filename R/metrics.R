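# Small-world and efficiency metrics on binary graphs, degree-preserving
# null ensembles, normalized indices, and AUC across the sparsity sweep.
#
# Conventions (fixed so denominators do not drift across sparsities):
#  - nodes with degree < 2 contribute 0 to both Cp and Eloc, and stay in
#    the node average;
#  - Lp on a disconnected graph is the mean over reachable pairs only, with
#    the number of unreachable pairs reported alongside (a harmonic-mean
#    variant is available);
#  - Eglob treats unreachable pairs as zero efficiency (1/Inf).

# Shortest-path distance matrix of a binary graph (hop counts, Inf if
# unreachable).
graph_distances <- function(g) {
  igraph::distances(as_igraph(g))
}

# Floyd-Warshall on a small logical adjacency; used for neighbor subgraphs.
fw_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

#' Average clustering coefficient
#'
#' Watts-Strogatz clustering: per node, the fraction of pairs of its
#' neighbors that are themselves connected (`C_i = 2 E_i / (k_i (k_i - 1))`,
#' zero for degree < 2), averaged over all nodes.
#'
#' @param g a [binarize_at_sparsity()] graph.
#' @return scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  a <- g$adj * 1
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path length over node pairs. On a disconnected graph the
#' default averages over reachable pairs only and reports how many
#' unordered pairs were unreachable; `method = "harmonic"` instead returns
#' the harmonic mean over all pairs (the inverse of global efficiency).
#'
#' @param g a binary graph.
#' @param method `"reachable"` (default) or `"harmonic"`.
#' @return list with `lp` and `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(g, method = c("reachable", "harmonic")) {
  method <- match.arg(method)
  d <- graph_distances(g)
  dv <- ut_vector(d)
  n_unreachable <- sum(!is.finite(dv))
  lp <- if (method == "reachable") {
    if (all(!is.finite(dv))) NA_real_ else mean(dv[is.finite(dv)])
  } else {
    1 / mean(ifelse(is.finite(dv), 1 / dv, 0))
  }
  list(lp = lp, n_unreachable_pairs = n_unreachable)
}

# Mean inverse distance over the upper triangle of a distance matrix.
.eff_from_dist <- function(d) {
  dv <- ut_vector(d)
  mean(ifelse(is.finite(dv), 1 / dv, 0))
}

#' Global efficiency
#'
#' Latora-Marchiori efficiency: the mean of inverse shortest-path lengths
#' over all node pairs, with unreachable pairs contributing zero.
#'
#' @param g a binary graph.
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  .eff_from_dist(graph_distances(g))
}

#' Local efficiency
#'
#' Mean, over nodes, of the global efficiency of the subgraph induced by
#' each node's neighbors; nodes with fewer than two neighbors contribute
#' zero and remain in the average.
#'
#' @param g a binary graph.
#' @return scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  a <- g$adj
  vals <- vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(a[i, ])
    if (length(nb) < 2) return(0)
    .eff_from_dist(fw_distances(a[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(vals)
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes a graph by repeated double-edge swaps that preserve every
#' node's degree (no self-loops or multi-edges), yielding a null graph with
#' the same size and degree sequence but destroyed higher-order structure.
#'
#' @param g a binary graph with at least 2 edges.
#' @param n_swaps_per_edge rewiring intensity: `n_swaps_per_edge * |E|` swap
#'   trials are performed (default 10, a standard mixing heuristic).
#' @param seed integer seed.
#' @return a rewired `binary_graph` with identical degree sequence.
#' @export
rewire_degree_preserving <- function(g, n_swaps_per_edge = 10, seed = 1L) {
  n_edges <- nrow(g$edges)
  if (n_edges < 2) stop("rewiring needs at least 2 edges")
  max_edges <- g$n_nodes * (g$n_nodes - 1) / 2
  if (n_edges == max_edges)
    warning("complete graph cannot be rewired; returning it unchanged")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 13L))
  ig <- igraph::rewire(as_igraph(g), igraph::keeping_degseq(
    loops = FALSE, niter = n_swaps_per_edge * n_edges))
  el <- igraph::as_edgelist(ig, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  adj <- matrix(FALSE, g$n_nodes, g$n_nodes)
  adj[el] <- TRUE
  adj[el[, c(2, 1), drop = FALSE]] <- TRUE
  structure(list(adj = adj, edges = el, n_nodes = g$n_nodes,
                 sparsity = g$sparsity), class = "binary_graph")
}

#' Small-world indices against a rewired null ensemble
#'
#' Computes Cp, Lp, Eglob and Eloc of the graph, then normalizes Cp and Lp
#' by their means over `n_nulls` degree-preserving rewired surrogates:
#' `gamma = Cp / Cp_rand`, `lambda = Lp / Lp_rand`,
#' `sigma = gamma / lambda`. `sigma > 1` is the small-world criterion.
#'
#' @param g a binary graph.
#' @param n_nulls number of rewired null graphs (default 100).
#' @param seed integer seed for the null ensemble.
#' @param n_swaps_per_edge rewiring intensity per null.
#' @param compute_eloc set `FALSE` to skip local efficiency (the slowest
#'   metric) when only the small-world indices are needed.
#' @return an object of class `global_metrics`: `cp`, `lp`, `e_glob`,
#'   `e_loc`, `gamma`, `lambda_`, `sigma`, `n_unreachable_pairs`, and the
#'   per-null values in `null_cp` / `null_lp`.
#' @export
small_world_indices <- function(g, n_nulls = 100, seed = 1L,
                                n_swaps_per_edge = 10, compute_eloc = TRUE) {
  stopifnot(n_nulls >= 1)
  d <- graph_distances(g)
  dv <- ut_vector(d)
  cp <- clustering_coefficient(g)
  lp <- mean(dv[is.finite(dv)])
  e_glob <- .eff_from_dist(d)
  e_loc <- if (compute_eloc) local_efficiency(g) else NA_real_
  null_cp <- numeric(n_nulls)
  null_lp <- numeric(n_nulls)
  for (b in seq_len(n_nulls)) {
    gb <- rewire_degree_preserving(g, n_swaps_per_edge,
                                   seed = derive_seed(seed, 500L + b))
    null_cp[b] <- clustering_coefficient(gb)
    nl <- characteristic_path_length(gb)
    null_lp[b] <- nl$lp
  }
  gamma <- cp / mean(null_cp)
  lambda_ <- lp / mean(null_lp)
  structure(list(cp = cp, lp = lp, e_glob = e_glob, e_loc = e_loc,
                 gamma = gamma, lambda_ = lambda_, sigma = gamma / lambda_,
                 n_unreachable_pairs = sum(!is.finite(dv)),
                 null_cp = null_cp, null_lp = null_lp,
                 n_nulls = n_nulls), class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("Cp %.4f  Lp %.4f  Eglob %.4f  Eloc %s\n", x$cp, x$lp,
              x$e_glob, ifelse(is.na(x$e_loc), "-", sprintf("%.4f", x$e_loc))))
  cat(sprintf("gamma %.3f  lambda %.3f  sigma %.3f  (%d nulls, %d unreachable pairs)\n",
              x$gamma, x$lambda_, x$sigma, x$n_nulls, x$n_unreachable_pairs))
  invisible(x)
}

#' Metric-versus-sparsity curve and its area under the curve
#'
#' @param sparsities strictly increasing sparsity levels (>= 2 of them).
#' @param values metric value at each sparsity.
#' @param metric optional metric name.
#' @return object of class `metric_curve` with the trapezoidal `auc`.
#' @export
metric_curve <- function(sparsities, values, metric = NA_character_) {
  stopifnot(length(sparsities) == length(values))
  if (length(sparsities) < 2) stop("a metric curve needs at least 2 points")
  if (any(diff(sparsities) <= 0)) stop("sparsities must be strictly increasing")
  structure(list(sparsities = sparsities, values = values, metric = metric,
                 auc = pracma::trapz(sparsities, values)),
            class = "metric_curve")
}

#' @rdname metric_curve
#' @param curve a `metric_curve`.
#' @export
metric_curve_auc <- function(curve) {
  stopifnot(inherits(curve, "metric_curve"))
  curve$auc
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("Metric curve%s: %d points over sparsity [%.2f, %.2f], AUC = %.4f\n",
              if (is.na(x$metric)) "" else paste0(" (", x$metric, ")"),
              length(x$values), min(x$sparsities), max(x$sparsities), x$auc))
  invisible(x)
}

#' @export
plot.metric_curve <- function(x, ...) {
  plot(x$sparsities, x$values, type = "b", pch = 16,
       xlab = "Sparsity", ylab = if (is.na(x$metric)) "Metric" else x$metric,
       main = sprintf("AUC = %.4f", x$auc), ...)
  invisible(x)
}

#' Metric curves of one subject across a sparsity sweep
#'
#' Runs the full per-subject metric battery: for each graph of the sweep,
#' Cp, Lp, Eglob, Eloc and the normalized indices against `n_nulls` rewired
#' surrogates, then the AUC of every metric over the sweep.
#'
#' @param graphs a [sparsity_sweep()] result.
#' @param n_nulls rewired nulls per graph.
#' @param seed integer seed.
#' @return list with `table` (one row per sparsity, one column per metric)
#'   and `auc` (named vector of per-metric AUCs).
#' @export
subject_metric_curves <- function(graphs, n_nulls = 100, seed = 1L) {
  sparsities <- vapply(graphs, `[[`, 0, "sparsity")
  rows <- lapply(seq_along(graphs), function(k) {
    m <- small_world_indices(graphs[[k]], n_nulls = n_nulls,
                             seed = derive_seed(seed, k))
    c(cp = m$cp, lp = m$lp, e_glob = m$e_glob, e_loc = m$e_loc,
      gamma = m$gamma, lambda = m$lambda_, sigma = m$sigma)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(graphs)
  auc <- apply(tab, 2, function(v) pracma::trapz(sparsities, v))
  list(table = as.data.frame(tab), sparsities = sparsities, auc = auc)
}
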