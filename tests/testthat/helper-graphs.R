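# Small-graph fixtures and independent brute-force metric oracles.
# The oracles deliberately avoid the package's code paths: distances come
# from an explicit Floyd-Warshall triple loop and clustering from direct
# neighbour-pair enumeration.

graph_from_edges <- function(edges, n_nodes) {
  edges <- matrix(as.integer(edges), ncol = 2)
  adj <- matrix(FALSE, n_nodes, n_nodes)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  structure(list(adj = adj, edges = edges, n_nodes = n_nodes, sparsity = NA),
            class = "binary_graph")
}

complete_graph <- function(n) graph_from_edges(t(combn(n, 2)), n)

star_graph <- function(n_leaves) {
  graph_from_edges(cbind(1L, 2:(n_leaves + 1L)), n_leaves + 1L)
}

path_graph <- function(n) graph_from_edges(cbind(1:(n - 1L), 2:n), n)

# triangle on 1-2-3 with pendant node 4 attached to node 1
triangle_pendant <- function() {
  graph_from_edges(rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4)), 4L)
}

ring_lattice <- function(n, k) {
  stopifnot(k %% 2 == 0)
  edges <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ((i + seq_len(k / 2) - 1L) %% n) + 1L)))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  graph_from_edges(unique(edges), n)
}

random_graph <- function(n_nodes, p_edge) {
  all_e <- t(combn(n_nodes, 2))
  keep <- runif(nrow(all_e)) < p_edge
  graph_from_edges(all_e[keep, , drop = FALSE], n_nodes)
}

# -- oracles ----------------------------------------------------------------

oracle_distances <- function(g) {
  n <- g$n_nodes
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges[e, 1]; j <- g$edges[e, 2]
    d[i, j] <- d[j, i] <- 1
  }
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_clustering <- function(g) {
  n <- g$n_nodes
  ci <- numeric(n)
  for (i in 1:n) {
    nb <- which(g$adj[i, ])
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (g$adj[nb[a], nb[b]]) links <- links + 1
    ci[i] <- 2 * links / (k * (k - 1))
  }
  mean(ci)
}

oracle_lp <- function(g) {
  d <- oracle_distances(g)
  vals <- d[upper.tri(d)]
  list(lp = mean(vals[is.finite(vals)]),
       n_unreachable = sum(!is.finite(vals)))
}

oracle_eglob <- function(g) {
  d <- oracle_distances(g)
  vals <- d[upper.tri(d)]
  mean(ifelse(is.finite(vals), 1 / vals, 0))
}

oracle_eloc <- function(g) {
  n <- g$n_nodes
  vals <- numeric(n)
  for (i in 1:n) {
    nb <- which(g$adj[i, ])
    if (length(nb) < 2) next
    sub_edges <- which(g$adj[nb, nb, drop = FALSE] & upper.tri(diag(length(nb))),
                       arr.ind = TRUE)
    sub <- graph_from_edges(sub_edges, length(nb))
    vals[i] <- oracle_eglob(sub)
  }
  mean(vals)
}

# union-find connected components over an edge list; returns the list of
# edge-index groups sorted by decreasing size
oracle_edge_components <- function(edges, n_nodes) {
  if (nrow(edges) == 0) return(list())
  parent <- seq_len(n_nodes)
  for (e in seq_len(nrow(edges))) {
    ri <- edges[e, 1]; rj <- edges[e, 2]
    while (parent[ri] != ri) ri <- parent[ri]
    while (parent[rj] != rj) rj <- parent[rj]
    if (ri != rj) parent[ri] <- rj
  }
  root_of <- vapply(seq_len(n_nodes), function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }, integer(1))
  groups <- split(seq_len(nrow(edges)), root_of[edges[, 1]])
  groups[order(-lengths(groups))]
}

# minimal cohort -> connectivity + covariates, shared by inference tests
build_group_connectivity <- function(spec) {
  coh <- generate_cohort(spec)
  conn <- lapply(coh, function(s) correlation_matrix(s$timeseries, s$subject_id))
  grp <- vapply(coh, `[[`, "", "group")
  cov <- covariate_table(grp,
                         vapply(coh, `[[`, 0, "age"),
                         vapply(coh, `[[`, "", "gender"),
                         vapply(coh, `[[`, 0, "education"))
  list(cohort = coh, conn = conn, group = grp, covariates = cov)
}
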