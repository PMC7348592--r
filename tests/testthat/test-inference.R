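fake_covariates <- function(n, seed = 1) {
  set.seed(seed)
  covariate_table(group = rep(c("control", "patient"), length.out = n),
                  age = rnorm(n, 65, 8),
                  gender = rbinom(n, 1, 0.5),
                  education = rnorm(n, 11, 3))
}

test_that("residualization removes covariate effects exactly", {
  cov <- fake_covariates(40, seed = 61)
  y <- 3 * cov$age
  expect_lt(max(abs(residualize(y, cov))), 1e-8)
  set.seed(62)
  y2 <- rnorm(40)
  r2 <- residualize(y2, cov)
  d <- cbind(cov$age, cov$gender, cov$education)
  expect_lt(max(abs(crossprod(scale(d, scale = FALSE), r2))) /
              max(abs(y2)), 1e-8)
  # values orthogonal to the (centered) covariates just lose their mean
  q <- qr.Q(qr(cbind(1, d)))
  y3 <- rnorm(40); y3 <- y3 - q %*% crossprod(q, y3)
  expect_equal(as.numeric(residualize(y3 + 5, cov)), as.numeric(y3),
               tolerance = 1e-8)
  cov_bad <- cov; cov_bad$education <- 2 * cov_bad$age
  expect_error(residualize(y2, cov_bad), "collinear")
})

test_that("the permutation test reproduces the exact two-group p-value", {
  # five 0s vs five 1s: exhaustive two-tailed p = 2 / choose(10, 5)
  res <- permutation_test_metric(rep(0, 5), rep(1, 5), NULL,
                                 n_perm = 4000, seed = 63)
  expect_gt(res$p_value, 0.004)
  expect_lt(res$p_value, 0.015)
  # identical groups: p near 1
  x <- c(1, 2, 3, 4, 5)
  res0 <- permutation_test_metric(x, x, NULL, n_perm = 500, seed = 64)
  expect_gt(res0$p_value, 0.9)
  expect_equal(res0$observed_diff, 0)
  # same seed reproduces the null vector exactly
  expect_identical(
    permutation_test_metric(x, x + 1, NULL, 300, seed = 66)$null_diffs,
    permutation_test_metric(x, x + 1, NULL, 300, seed = 66)$null_diffs)
  expect_error(permutation_test_metric(1, c(1, 2), NULL, 300), "at least 2")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(67)
  n <- 16
  alphas <- c(0.05, 0.1, 0.2)
  p <- vapply(1:400, function(k) {
    cov <- fake_covariates(n, seed = 7000 + k)
    permutation_test_metric(rnorm(n / 2), rnorm(n / 2), cov,
                            n_perm = 200, seed = k)$p_value
  }, numeric(1))
  for (a in alphas) {
    se <- sqrt(a * (1 - a) / 400)
    expect_lte(mean(p <= a), a + 3 * se)
  }
})

test_that("the connection mask uses within-group union semantics", {
  make_z <- function(val, n_sub, jitter = 0) {
    lapply(seq_len(n_sub), function(k) {
      m <- matrix(0, 4, 4)
      m[1, 2] <- m[2, 1] <- val + jitter * sin(k)
      m
    })
  }
  # all zeros: empty mask
  mask0 <- nbs_connection_mask(make_z(0, 5), make_z(0, 5))
  expect_false(any(mask0))
  # strong edge in group A only -> in the union mask
  za <- lapply(1:30, function(k) {
    m <- matrix(0, 4, 4); set.seed(800 + k)
    m[1, 2] <- m[2, 1] <- rnorm(1, 1, 0.1); m
  })
  zb <- lapply(1:30, function(k) matrix(0, 4, 4))
  mask_a <- nbs_connection_mask(za, zb)
  mask_b <- nbs_connection_mask(zb, za)   # significant only in group B
  expect_true(mask_a[1])                   # edge (1,2) is the first lex edge
  expect_true(mask_b[1])
  expect_false(any(mask_a[-1]))
})

test_that("NBS handles the no-signal and identical-group cases", {
  set.seed(68)
  base <- lapply(1:6, function(k) {
    m <- matrix(0.8, 6, 6) + matrix(rnorm(36, 0, 0.01), 6); m <- (m + t(m)) / 2
    diag(m) <- 0; m
  })
  res <- nbs(base, base, NULL, n_perm = 200, seed = 69)
  expect_length(res$components, 0)
  expect_identical(res$max_component_size, 0L)
  expect_error(nbs(base[1:2], base, NULL), "at least 3")
})

test_that("component extraction matches a union-find oracle", {
  set.seed(70)
  for (rep in 1:100) {
    n_nodes <- sample(6:20, 1)
    all_e <- t(combn(n_nodes, 2))
    edges <- all_e[runif(nrow(all_e)) < 0.12, , drop = FALSE]
    got <- fconnectome:::edge_components(edges, n_nodes)
    want <- oracle_edge_components(edges, n_nodes)
    expect_identical(lengths(got), unname(lengths(want)))
    canon <- function(l) sort(unname(vapply(l, function(ix)
      paste(sort(ix), collapse = ","), character(1))))
    expect_identical(canon(got), canon(want))
    expect_identical(
      fconnectome:::edge_components(edges, n_nodes, max_only = TRUE),
      if (nrow(edges)) max(lengths(want)) else 0L)
  }
})

test_that("NBS is reproducible and detects a planted component", {
  planted <- t(combn(1:5, 2))
  spec <- cohort_spec(15, 15, n_regions = 30, n_timepoints = 200,
                      module_labels = rep(1:6, each = 5),
                      within_module_r = 0.4, between_module_r = 0,
                      effect_size = 0.6, target_edges = planted, seed = 71)
  built <- build_group_connectivity(spec)
  a <- built$conn[built$group == "control"]
  b <- built$conn[built$group == "patient"]
  r1 <- nbs(a, b, built$covariates, n_perm = 300, seed = 72)
  r2 <- nbs(a, b, built$covariates, n_perm = 300, seed = 72)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  expect_gt(length(r1$components), 0)
  top <- r1$components[[1]]
  hit <- apply(planted, 1, function(e)
    any(top$edges[, 1] == e[1] & top$edges[, 2] == e[2]))
  expect_gte(mean(hit), 0.8)
  expect_lt(top$corrected_p, 0.05)
  # direction matters: the opposite tail never recovers the planted clique
  # as a significant component
  r_wrong <- nbs(a, b, built$covariates, n_perm = 300, seed = 72,
                 tail = "b_gt_a")
  sig_wrong <- Filter(function(cm) cm$corrected_p < 0.05, r_wrong$components)
  planted_hit <- vapply(sig_wrong, function(cm)
    mean(apply(planted, 1, function(e)
      any(cm$edges[, 1] == e[1] & cm$edges[, 2] == e[2]))), numeric(1))
  expect_true(length(planted_hit) == 0 || max(planted_hit) < 0.5)
})

test_that("mean component connectivity averages the right entries", {
  z1 <- matrix(0, 4, 4); z1[1, 2] <- z1[2, 1] <- 0.6
  z1[3, 4] <- z1[4, 3] <- 0.2; z1[1, 3] <- z1[3, 1] <- 0.1
  z2 <- z1 * 2
  comp <- rbind(c(1, 2), c(3, 4), c(1, 3))
  got <- mean_component_connectivity(list(z1, z2), comp)
  expect_equal(got, c(mean(c(0.6, 0.2, 0.1)), mean(c(1.2, 0.4, 0.2))))
  single <- mean_component_connectivity(list(z1, z2), rbind(c(1, 2)))
  expect_equal(single, c(0.6, 1.2))
  const <- matrix(0.3, 4, 4); diag(const) <- 0
  expect_equal(mean_component_connectivity(list(const), comp), 0.3)
})
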