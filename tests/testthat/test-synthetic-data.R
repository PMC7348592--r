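test_that("identical spec and seed reproduce the cohort exactly", {
  spec1 <- cohort_spec(3, 3, n_regions = 20, n_timepoints = 60, seed = 42)
  spec2 <- cohort_spec(3, 3, n_regions = 20, n_timepoints = 60, seed = 42)
  c1 <- generate_cohort(spec1)
  c2 <- generate_cohort(spec2)
  expect_identical(c1[[1]]$timeseries$data, c2[[1]]$timeseries$data)
  expect_identical(c1[[6]]$motion$fd, c2[[6]]$motion$fd)
  expect_identical(c1[[4]]$behavior, c2[[4]]$behavior)
  expect_identical(vapply(c1, `[[`, 0, "age"), vapply(c2, `[[`, 0, "age"))
})

test_that("model correlation matrices are symmetric, unit-diagonal, PSD", {
  spec <- cohort_spec(2, 2, effect_size = 0.8, seed = 5)
  for (g in c("control", "patient")) {
    r <- spec$model_r[[g]]
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, 90))
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  # effect reduces target entries for patients only
  te <- spec$target_edges
  expect_true(all(spec$model_r$patient[te] < spec$model_r$control[te]))
})

test_that("effect_size 0 leaves the groups exchangeable at the edge level", {
  spec <- cohort_spec(12, 12, effect_size = 0, seed = 77)
  built <- build_group_connectivity(spec)
  za <- sapply(built$conn[built$group == "control"],
               function(m) m$z[upper.tri(m$z)])
  zb <- sapply(built$conn[built$group == "patient"],
               function(m) m$z[upper.tri(m$z)])
  p <- vapply(seq_len(nrow(za)), function(e)
    t.test(za[e, ], zb[e, ])$p.value, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("sample correlations approach the model values as T grows", {
  labels <- rep(1:4, each = 5)
  errs <- vapply(c(200, 2000, 20000), function(tp) {
    spec <- cohort_spec(1, 1, n_regions = 20, n_timepoints = tp,
                        module_labels = labels, within_module_r = 0.5,
                        between_module_r = 0.1, effect_size = 0,
                        target_edges = cbind(1L, 2L), seed = 9)
    coh <- generate_cohort(spec)
    r_hat <- cor(coh[[1]]$timeseries$data)
    max(abs(r_hat - spec$model_r$control))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # within-module correlations at T = 2000 sit near the model value
  spec <- cohort_spec(1, 1, n_regions = 20, n_timepoints = 2000,
                      module_labels = labels, within_module_r = 0.5,
                      between_module_r = 0.1, effect_size = 0,
                      target_edges = cbind(1L, 2L), seed = 10)
  coh <- generate_cohort(spec)
  r_hat <- cor(coh[[1]]$timeseries$data)
  within <- outer(labels, labels, "==") & upper.tri(r_hat)
  expect_lt(max(abs(r_hat[within] - 0.5)), 0.06)
  expect_lt(abs(mean(r_hat[within]) - 0.5), 0.02)
})

test_that("patient-minus-control gap on target edges grows with effect size", {
  labels <- rep(1:4, each = 5)
  te <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(1L, 5L))
  gap <- function(es, seed) {
    spec <- cohort_spec(8, 8, n_regions = 20, n_timepoints = 150,
                        module_labels = labels, effect_size = es,
                        target_edges = te, seed = seed)
    built <- build_group_connectivity(spec)
    mean_te <- vapply(built$conn, function(m) mean(m$z[te]), numeric(1))
    mean(mean_te[built$group == "patient"]) -
      mean(mean_te[built$group == "control"])
  }
  gaps <- vapply(c(0, 0.3, 0.6), function(es)
    mean(vapply(1:20, function(s) gap(es, 300 + s), numeric(1))), numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(abs(gaps[1]), 0.02)
})

test_that("behavior scores track realized target-edge connectivity", {
  spec <- cohort_spec(15, 15, effect_size = 0.5, seed = 21)
  coh <- generate_cohort(spec)
  te <- spec$target_edges
  mean_z <- vapply(coh, function(s)
    mean(atanh(pmin(pmax(cor(s$timeseries$data)[te], -1 + 1e-7), 1 - 1e-7))),
    numeric(1))
  beh <- do.call(rbind, lapply(coh, `[[`, "behavior"))
  expect_gt(cor(mean_z, beh[, "Similarity"]), 0.2)
  expect_lt(cor(mean_z, beh[, "StroopC"]), -0.1)
})

test_that("motion traces respect the spike rate and the 5-minute rule", {
  quiet <- generate_motion_traces(230, spike_rate = 0, seed = 3)
  expect_true(all(quiet$fd < 0.5))
  expect_identical(quiet$fd[1], 0)
  # heavy spiking leaves less than 5 min of data at TR = 2 s
  ts <- roi_timeseries(matrix(rnorm(230 * 4), 230, 4), tr_seconds = 2)
  noisy <- generate_motion_traces(230, spike_rate = 40, seed = 4)
  sc <- scrub(ts, noisy)
  expect_lt(sum(sc$report$keep_mask), 150)
  expect_true(sc$report$excluded)
  # seeded reproducibility
  expect_identical(generate_motion_traces(100, 2, seed = 8)$fd,
                   generate_motion_traces(100, 2, seed = 8)$fd)
})

test_that("voxel label counts concentrate according to the purity", {
  pure <- generate_voxel_label_counts(20, purity = 1, seed = 6,
                                      module_labels = rep(1:4, each = 5))
  counts <- as.matrix(pure[, system_names()[1:7]])
  expect_true(all(apply(counts, 1, max) == rowSums(counts)))
  lc <- generate_voxel_label_counts(90, purity = 0.8, seed = 7)
  counts <- as.matrix(lc[, system_names()[1:7]])
  share <- apply(counts, 1, max) / rowSums(counts)
  cortical <- !lc$subcortical
  expect_lt(max(abs(share[cortical] - 0.8)), 0.04)
  # subcortical flag survives a round trip through CSV
  f <- tempfile(fileext = ".csv")
  write.csv(lc, f, row.names = FALSE)
  back <- read.csv(f)
  expect_identical(back$subcortical, lc$subcortical)
})

test_that("a written cohort reads back with identical signal content", {
  spec <- cohort_spec(2, 2, n_regions = 12, n_timepoints = 40, seed = 31)
  coh <- generate_cohort(spec)
  d <- tempfile("cohort")
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_equal(back[[1]]$timeseries$data, coh[[1]]$timeseries$data,
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_identical(vapply(back, `[[`, "", "group"),
                   vapply(coh, `[[`, "", "group"))
  unlink(d, recursive = TRUE)
})
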