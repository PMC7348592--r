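# Covariate-adjusted nonparametric group inference: permutation tests on
# global metrics and the network-based statistic (NBS).

#' Assemble a covariate table
#'
#' @param group character or factor group labels.
#' @param age,education numeric vectors (years).
#' @param gender 0/1 coding (or a character vector, coded 1 = male).
#' @param subject_id optional ids.
#' @return data frame of class `covariate_table`.
#' @export
covariate_table <- function(group, age, gender, education,
                            subject_id = NULL) {
  if (is.character(gender) || is.factor(gender))
    gender <- as.integer(as.character(gender) == "male")
  n <- length(group)
  stopifnot(length(age) == n, length(gender) == n, length(education) == n)
  if (anyNA(age) || anyNA(gender) || anyNA(education))
    stop("covariates must not contain missing values")
  df <- data.frame(subject_id = if (is.null(subject_id))
    sprintf("S%03d", seq_len(n)) else subject_id,
    group = as.character(group), age = age, gender = gender,
    education = education, stringsAsFactors = FALSE)
  class(df) <- c("covariate_table", "data.frame")
  df
}

# Design matrix [1 | age | gender | education]; errors on collinearity.
covariate_design <- function(covariates, n_expected = NULL) {
  stopifnot(is.data.frame(covariates))
  d <- cbind(intercept = 1, age = covariates$age,
             gender = covariates$gender, education = covariates$education)
  if (!is.null(n_expected) && nrow(d) != n_expected)
    stop("covariate table does not match the number of subjects")
  if (qr(d)$rank < ncol(d)) stop("collinear covariates")
  d
}

#' Remove covariate effects by regression
#'
#' OLS residuals of `values` on an intercept plus age, gender and education,
#' fitted across all subjects pooled (both groups together). Matrices are
#' residualized column by column.
#'
#' @param values numeric vector (one value per subject) or subject-by-
#'   variable matrix.
#' @param covariates a [covariate_table()] (or data frame with `age`,
#'   `gender`, `education`), rows aligned with `values`.
#' @return residuals with the shape of `values`.
#' @export
residualize <- function(values, covariates) {
  v <- as.matrix(values)
  d <- covariate_design(covariates, nrow(v))
  if (nrow(v) <= ncol(d)) stop("need more subjects than covariates + 1")
  res <- lm.fit(d, v)$residuals
  if (is.vector(values)) as.numeric(res) else res
}

#' Covariate-adjusted permutation test on a group difference of means
#'
#' Residualizes the pooled values on age, gender and education, takes the
#' observed difference of group means of the residuals, and compares it with
#' the distribution obtained by randomly reallocating subjects to two groups
#' of the original sizes. Two-tailed: the absolute observed difference is
#' compared with the absolute null differences, and the critical value is
#' the 95th percentile of the absolute null distribution.
#'
#' @param group_a,group_b per-subject metric values of the two groups.
#' @param covariates [covariate_table()] with rows for `c(group_a, group_b)`
#'   in order; `NULL` for an unadjusted test.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return object of class `permutation_result`: `observed_diff`,
#'   `null_diffs`, `p_value`, `critical_value`, `n_permutations`.
#' @export
permutation_test_metric <- function(group_a, group_b, covariates = NULL,
                                    n_perm = 10000, seed = 1L) {
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 subjects")
  stopifnot(n_perm >= 100)
  values <- c(group_a, group_b)
  res <- if (is.null(covariates)) values - mean(values)
         else residualize(values, covariates)
  n <- n_a + n_b
  observed <- mean(res[seq_len(n_a)]) - mean(res[n_a + seq_len(n_b)])
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 29L))
  tot <- sum(res)
  null_diffs <- vapply(seq_len(n_perm), function(p) {
    sa <- sum(res[sample.int(n, n_a)])
    sa / n_a - (tot - sa) / n_b
  }, numeric(1))
  p <- (1 + sum(abs(null_diffs) >= abs(observed))) / (1 + n_perm)
  structure(list(observed_diff = observed, null_diffs = null_diffs,
                 p_value = p, n_permutations = n_perm,
                 critical_value = unname(quantile(abs(null_diffs), 0.95))),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed diff %.4g, p = %.4g (%d permutations, |crit| %.4g)\n",
    x$observed_diff, x$p_value, x$n_permutations, x$critical_value))
  invisible(x)
}

# Stack per-subject connectivity into a subjects x edges matrix of
# Fisher-z values (lex edge order).
z_stack <- function(z_matrices) {
  mats <- lapply(z_matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$z else as.matrix(m))
  t(vapply(mats, ut_vector, numeric(nrow(mats[[1]]) * (nrow(mats[[1]]) - 1) / 2)))
}

#' Within-group nonzero-connection mask for NBS
#'
#' Per edge and group, a two-tailed one-sample t-test of the Fisher-z values
#' against zero; the mask is the union of edges significant (uncorrected
#' `p < alpha_mask`) in either group. The NBS search is restricted to this
#' mask so that only connections actually present in at least one group are
#' tested for group differences.
#'
#' @param z_matrices_a,z_matrices_b lists of `connectivity_matrix` objects
#'   (or symmetric z matrices), one per subject; at least 3 per group.
#' @param alpha_mask uncorrected threshold (default 0.05).
#' @return logical vector over the canonical edge ordering (see
#'   [edge_pairs()]), with attribute `n_nodes`.
#' @export
nbs_connection_mask <- function(z_matrices_a, z_matrices_b,
                                alpha_mask = 0.05) {
  stopifnot(length(z_matrices_a) >= 3, length(z_matrices_b) >= 3)
  za <- z_stack(z_matrices_a); zb <- z_stack(z_matrices_b)
  stopifnot(ncol(za) == ncol(zb))
  one_sample_p <- function(z) {
    n <- nrow(z)
    m <- colMeans(z)
    s <- sqrt((colSums(z^2) - n * m^2) / (n - 1))
    t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf))
    2 * pt(-abs(t), n - 1)
  }
  mask <- one_sample_p(za) < alpha_mask | one_sample_p(zb) < alpha_mask
  n_nodes <- nrow(if (inherits(z_matrices_a[[1]], "connectivity_matrix"))
    z_matrices_a[[1]]$z else z_matrices_a[[1]])
  attr(mask, "n_nodes") <- n_nodes
  mask
}

# Covariate-adjusted group t statistics for many label permutations at
# once. The statistic per edge is the t of the group-indicator coefficient
# in the GLM `z ~ group + covariates`; by Frisch-Waugh it is computed from
# the covariate-residualized z values (`x`, subjects x edges) and the
# covariate-residualized group indicators (`gmat`, n_perm x subjects, one
# permuted indicator per row). With no covariates (indicator merely
# centered) this is exactly the pooled two-sample t. `df` is
# n - 2 - n_covariates. Returns an n_perm x edges matrix.
perm_t_matrix <- function(x, gmat, df) {
  num <- gmat %*% x                       # cross-products per perm x edge
  sxx <- rowSums(gmat^2)
  syy <- colSums(x^2)
  r <- num / sqrt(outer(sxx, syy))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  r * sqrt(df) / sqrt(1 - r^2)
}

# Residualize rows of a 0/1 indicator matrix on the covariate design
# (columns of `design` must include the intercept).
residualize_indicators <- function(gmat, design) {
  gmat - gmat %*% design %*% solve(crossprod(design), t(design))
}

# Connected components over a set of suprathreshold edges. Returns a list
# of components (edge row indices into `edges`) ordered by link count,
# descending; `max_only = TRUE` returns just the maximal link count.
edge_components <- function(edges, n_nodes, max_only = FALSE) {
  if (nrow(edges) == 0) return(if (max_only) 0L else list())
  ig <- igraph::make_graph(as.vector(t(edges)), n = n_nodes,
                           directed = FALSE)
  memb <- igraph::components(ig)$membership
  comp_of_edge <- memb[edges[, 1L]]
  sizes <- table(comp_of_edge)
  if (max_only) return(as.integer(max(sizes)))
  ids <- names(sort(sizes, decreasing = TRUE))
  lapply(ids, function(id) which(comp_of_edge == as.integer(id)))
}

#' Network-based statistic (NBS)
#'
#' Component-level familywise-corrected inference on edgewise group
#' differences. Within the nonzero-connection mask, each edge is tested
#' with a one-tailed t-statistic for the group term of the linear model
#' `z ~ group + age + gender + education` (the plain pooled two-sample t
#' when no covariates are given), in the direction `tail`. Edges exceeding
#' the primary threshold `t_crit(primary_alpha, df)` form suprathreshold
#' components whose sizes (link counts) are compared with the null
#' distribution of the maximal component size under `n_perm` random group
#' reallocations, the identical adjusted statistic being recomputed for
#' every permuted labelling.
#'
#' @param z_matrices_a,z_matrices_b per-subject connectivity (lists of
#'   `connectivity_matrix` or z matrices); group A first (conventionally the
#'   controls), at least 3 subjects each.
#' @param covariates [covariate_table()] for `c(a, b)` rows, or `NULL`.
#' @param primary_alpha one-tailed primary threshold (default 0.05).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param tail `"a_gt_b"` tests A > B (e.g., controls more connected than
#'   patients); `"b_gt_a"` the reverse.
#' @param alpha_mask threshold of the within-group nonzero mask.
#' @param literal if `TRUE`, the corrected p is the plain proportion of
#'   permutations whose maximal component is strictly larger than the
#'   observed size; the default adds the +1 correction and uses >= so that
#'   p-values are valid (never zero).
#' @param perm_block permutations processed per matrix block (memory knob).
#' @return object of class `nbs_result`.
#' @export
nbs <- function(z_matrices_a, z_matrices_b, covariates = NULL,
                primary_alpha = 0.05, n_perm = 10000, seed = 1L,
                tail = c("a_gt_b", "b_gt_a"), alpha_mask = 0.05,
                literal = FALSE, perm_block = 1000L) {
  tail <- match.arg(tail)
  n_a <- length(z_matrices_a); n_b <- length(z_matrices_b)
  if (n_a < 3 || n_b < 3) stop("each group needs at least 3 subjects")
  mask <- nbs_connection_mask(z_matrices_a, z_matrices_b, alpha_mask)
  n_nodes <- attr(mask, "n_nodes")
  ep <- edge_pairs(n_nodes)
  n <- n_a + n_b
  n_cov <- if (is.null(covariates)) 0L else 3L
  df <- n - 2L - n_cov
  t_crit <- qt(1 - primary_alpha, df = df)
  empty <- structure(list(
    mask = ep[mask, , drop = FALSE], t_threshold = t_crit,
    components = list(), max_component_size = 0L,
    null_max_sizes = integer(0), n_permutations = n_perm, tail = tail,
    n_nodes = n_nodes), class = "nbs_result")
  if (!any(mask)) return(empty)
  x <- rbind(z_stack(z_matrices_a),
             z_stack(z_matrices_b))[, mask, drop = FALSE]
  design <- if (is.null(covariates)) matrix(1, n, 1)
            else covariate_design(covariates, n)
  x <- lm.fit(design, x)$residuals
  if (tail == "b_gt_a") x <- -x
  ep_mask <- ep[mask, , drop = FALSE]

  g_obs <- matrix(c(rep(1, n_a), rep(0, n_b)), 1)
  obs_t <- perm_t_matrix(x, residualize_indicators(g_obs, design), df)[1, ]
  supra <- obs_t > t_crit
  comps <- edge_components(ep_mask[supra, , drop = FALSE], n_nodes)
  supra_idx <- which(supra)

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 37L))
  null_max <- integer(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(perm_block, n_perm - done)
    gmat <- matrix(0, nb, n)
    for (p in seq_len(nb)) gmat[p, sample.int(n, n_a)] <- 1
    tmat <- perm_t_matrix(x, residualize_indicators(gmat, design), df)
    for (p in seq_len(nb)) {
      sup <- tmat[p, ] > t_crit
      null_max[done + p] <- edge_components(
        ep_mask[sup, , drop = FALSE], n_nodes, max_only = TRUE)
    }
    done <- done + nb
  }
  components <- lapply(comps, function(rows) {
    eidx <- supra_idx[rows]
    comp_edges <- ep_mask[eidx, , drop = FALSE]
    m <- nrow(comp_edges)
    p_corr <- if (literal) mean(null_max > m)
              else (1 + sum(null_max >= m)) / (1 + n_perm)
    list(edges = comp_edges, nodes = sort(unique(as.vector(comp_edges))),
         size = m, t = obs_t[eidx], corrected_p = p_corr)
  })
  structure(list(
    mask = ep_mask, t_threshold = t_crit, components = components,
    max_component_size = if (length(components)) components[[1]]$size else 0L,
    null_max_sizes = null_max, n_permutations = n_perm, tail = tail,
    n_nodes = n_nodes), class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS (%s, t > %.3f, %d permutations): %d masked edges\n",
              x$tail, x$t_threshold, x$n_permutations, nrow(x$mask)))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cm <- x$components[[k]]
      cat(sprintf("  component %d: %d links, %d nodes, corrected p = %.4g\n",
                  k, cm$size, length(cm$nodes), cm$corrected_p))
    }
  }
  invisible(x)
}

#' @export
summary.nbs_result <- function(object, ...) {
  data.frame(
    component = seq_along(object$components),
    links = vapply(object$components, `[[`, 0L, "size"),
    nodes = vapply(object$components, function(cm) length(cm$nodes), 0L),
    corrected_p = vapply(object$components, `[[`, 0, "corrected_p"))
}

#' Mean connectivity over a component's edges
#'
#' Per subject, the mean Fisher-z value over the edges of a (typically
#' NBS-significant) component; the usual scalar for brain-behavior
#' correlation and classification features.
#'
#' @param z_matrices list of `connectivity_matrix` or z matrices.
#' @param component_edges two-column edge matrix (e.g.,
#'   `result$components[[1]]$edges`).
#' @return numeric vector, one value per subject.
#' @export
mean_component_connectivity <- function(z_matrices, component_edges) {
  component_edges <- as.matrix(component_edges)
  if (nrow(component_edges) == 0) stop("component has no edges")
  vapply(z_matrices, function(m) {
    z <- if (inherits(m, "connectivity_matrix")) m$z else as.matrix(m)
    mean(z[component_edges])
  }, numeric(1))
}
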