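# End-to-end orchestration: simulate (optional) -> preprocess -> networks
# -> metrics -> group inference -> NBS -> module labelling -> behavior and
# classification, with one config object and per-stage derived seeds.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end analysis.
#'
#' @param cohort_spec a [cohort_spec()] used when no cohort is passed to
#'   [run_pipeline()].
#' @param band bandpass edges in Hz (default `c(0.01, 0.1)`).
#' @param fd_threshold scrubbing FD threshold in mm.
#' @param min_remaining_minutes scrub exclusion boundary (default 5).
#' @param scrub apply FD scrubbing before network construction.
#' @param sweep `c(s_min, s_max, step)` sparsity sweep (default
#'   `c(0.10, 0.40, 0.01)`).
#' @param n_nulls rewired nulls per graph for the normalized indices.
#' @param n_perm permutations for the metric tests and NBS.
#' @param primary_alpha NBS primary threshold.
#' @param tail NBS direction (`"a_gt_b"`: controls > patients).
#' @param fixed_sparsity_for_behavior sparsity at which metric values are
#'   correlated with behavior (default 0.40).
#' @param atlas_purity purity of the synthetic voxel-label counts used for
#'   the modular partition.
#' @param seed master seed; every stage derives its own stream from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_spec = NULL, band = c(0.01, 0.1),
                            fd_threshold = 0.5, min_remaining_minutes = 5,
                            scrub = FALSE, sweep = c(0.10, 0.40, 0.01),
                            n_nulls = 100, n_perm = 10000,
                            primary_alpha = 0.05, tail = "a_gt_b",
                            fixed_sparsity_for_behavior = 0.40,
                            atlas_purity = 0.8, seed = 1L) {
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
  stopifnot(length(sweep) == 3)
  check_scalar(sweep[1], "s_min", 0, 1, open_lo = TRUE)
  check_scalar(sweep[2], "s_max", sweep[1], 1)
  check_scalar(sweep[3], "step", 0, open_lo = TRUE)
  check_scalar(fd_threshold, "fd_threshold", 0, open_lo = TRUE)
  check_scalar(n_nulls, "n_nulls", 1)
  check_scalar(n_perm, "n_perm", 100)
  check_scalar(primary_alpha, "primary_alpha", 0, 1,
               open_lo = TRUE, open_hi = TRUE)
  check_scalar(fixed_sparsity_for_behavior, "fixed_sparsity_for_behavior",
               sweep[1], sweep[2])
  tail <- match.arg(tail, c("a_gt_b", "b_gt_a"))
  structure(list(cohort_spec = cohort_spec, band = band,
                 fd_threshold = fd_threshold,
                 min_remaining_minutes = min_remaining_minutes,
                 scrub = scrub, sweep = sweep, n_nulls = as.integer(n_nulls),
                 n_perm = as.integer(n_perm), primary_alpha = primary_alpha,
                 tail = tail,
                 fixed_sparsity_for_behavior = fixed_sparsity_for_behavior,
                 atlas_purity = atlas_purity, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full connectome group analysis
#'
#' Executes every stage on a cohort (supplied, or generated from
#' `config$cohort_spec`): motion exclusion, temporal cleaning (detrend,
#' bandpass, nuisance regression on the six motion parameters — filtered
#' identically to the data), optional FD scrubbing, Pearson/Fisher-z
#' connectivity, the sparsity sweep with small-world metrics and AUCs,
#' covariate-adjusted permutation tests per metric AUC, NBS, purity-based
#' module labelling of the significant component, brain-behavior partial
#' correlations in the patient group, and stepwise LDA classification.
#' Identical config and cohort reproduce identical results.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built [generate_cohort()] cohort.
#' @param out_dir optional directory; when given, tabular results and a JSON
#'   summary are written there.
#' @return object of class `connectome_analysis`.
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$cohort_spec))
      stop("no cohort supplied and no cohort_spec in the config")
    cohort <- generate_cohort(config$cohort_spec)
  }

  ## -- preprocessing and quality control ---------------------------------
  excluded <- character(0)
  clean <- list()
  for (s in cohort) {
    if (motion_exclusion(s$motion)) {
      excluded <- c(excluded, s$subject_id); next
    }
    ts <- detrend_and_bandpass(s$timeseries, config$band[1], config$band[2])
    reg <- cbind(s$motion$translations, s$motion$rotations)
    reg <- detrend_and_bandpass(
      roi_timeseries(reg, ts$tr_seconds, paste0("m", 1:6)),
      config$band[1], config$band[2])$data
    ts <- regress_nuisance(ts, reg)
    if (config$scrub) {
      sc <- scrub(ts, s$motion, config$fd_threshold,
                  min_remaining_seconds = config$min_remaining_minutes * 60)
      if (sc$report$excluded) {
        excluded <- c(excluded, s$subject_id); next
      }
      ts <- sc$timeseries
    }
    s$clean <- ts
    clean[[length(clean) + 1L]] <- s
  }
  if (length(clean) < 6) stop("fewer than 6 subjects survive quality control")
  groups <- vapply(clean, `[[`, "", "group")
  is_a <- groups == "control"
  covariates <- covariate_table(
    group = groups,
    age = vapply(clean, `[[`, 0, "age"),
    gender = vapply(clean, `[[`, "", "gender"),
    education = vapply(clean, `[[`, 0, "education"),
    subject_id = vapply(clean, `[[`, "", "subject_id"))

  ## -- connectivity and graph metrics ------------------------------------
  conn <- lapply(clean, function(s) correlation_matrix(s$clean, s$subject_id))
  curves <- lapply(seq_along(clean), function(k) {
    graphs <- sparsity_sweep(conn[[k]], config$sweep[1], config$sweep[2],
                             config$sweep[3])
    subject_metric_curves(graphs, n_nulls = config$n_nulls,
                          seed = derive_seed(config$seed, 100L + k))
  })
  auc <- do.call(rbind, lapply(curves, `[[`, "auc"))
  rownames(auc) <- covariates$subject_id

  ## -- covariate-adjusted permutation tests on metric AUCs ---------------
  perm_tests <- lapply(colnames(auc), function(metric) {
    permutation_test_metric(auc[is_a, metric], auc[!is_a, metric],
                            covariates[c(which(is_a), which(!is_a)), ],
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 200L))
  })
  names(perm_tests) <- colnames(auc)

  ## -- NBS ----------------------------------------------------------------
  nbs_res <- nbs(conn[is_a], conn[!is_a],
                 covariates[c(which(is_a), which(!is_a)), ],
                 primary_alpha = config$primary_alpha,
                 n_perm = config$n_perm,
                 seed = derive_seed(config$seed, 300L), tail = config$tail)

  ## -- modular partition of the largest component ------------------------
  spec <- attr(cohort, "spec")
  n_regions <- ncol(conn[[1]]$r)
  label_counts <- generate_voxel_label_counts(
    n_regions, purity = config$atlas_purity,
    seed = derive_seed(config$seed, 400L),
    module_labels = if (!is.null(spec)) spec$module_labels
    else default_module_labels(n_regions))
  partition <- assign_systems_by_purity(label_counts)
  edge_labels <- if (length(nbs_res$components))
    label_edges_by_module(nbs_res$components[[1]]$edges, partition)
  else NULL

  ## -- behavior: partial correlations in the patient group ---------------
  fixed_s <- sprintf("%.4g", config$fixed_sparsity_for_behavior)
  metrics_at_s <- do.call(rbind, lapply(curves, function(cu)
    unlist(cu$table[fixed_s, ])))
  beh <- do.call(rbind, lapply(clean, `[[`, "behavior"))
  nbs_conn <- if (length(nbs_res$components))
    mean_component_connectivity(conn, nbs_res$components[[1]]$edges)
  else NULL
  pat <- which(!is_a)
  behavior_cor <- NULL
  if (!is.null(beh) && length(pat) > 7) {
    rows <- list()
    for (score in colnames(beh)) for (metric in colnames(metrics_at_s)) {
      pc <- partial_correlation(metrics_at_s[pat, metric], beh[pat, score],
                                covariates[pat, ])
      rows[[length(rows) + 1L]] <- data.frame(
        score = score, measure = metric, r = pc$r_partial, p = pc$p_value)
    }
    if (!is.null(nbs_conn)) for (score in colnames(beh)) {
      pc <- partial_correlation(nbs_conn[pat], beh[pat, score],
                                covariates[pat, ])
      rows[[length(rows) + 1L]] <- data.frame(
        score = score, measure = "nbs_connectivity", r = pc$r_partial,
        p = pc$p_value)
    }
    behavior_cor <- do.call(rbind, rows)
  }

  ## -- classification -----------------------------------------------------
  features <- auc[, c("lp", "gamma", "lambda", "sigma", "e_glob", "e_loc")]
  if (!is.null(nbs_conn)) features <- cbind(features, nbs_conn = nbs_conn)
  classification <- stepwise_lda_loocv(features, groups)

  result <- structure(list(
    config = config, covariates = covariates, excluded = excluded,
    connectivity = conn, metric_curves = curves, metric_auc = auc,
    permutation_tests = perm_tests, nbs = nbs_res, partition = partition,
    edge_labels = edge_labels, behavior_correlations = behavior_cor,
    classification = classification), class = "connectome_analysis")
  if (!is.null(out_dir)) write_analysis(result, out_dir)
  result
}

# Write the tabular artifacts of an analysis bundle.
write_analysis <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(subject_id = rownames(result$metric_auc),
                       result$metric_auc, row.names = NULL),
            file.path(out_dir, "metric_auc.csv"), row.names = FALSE)
  ptab <- data.frame(
    metric = names(result$permutation_tests),
    observed_diff = vapply(result$permutation_tests, `[[`, 0, "observed_diff"),
    p_value = vapply(result$permutation_tests, `[[`, 0, "p_value"),
    row.names = NULL)
  write.csv(ptab, file.path(out_dir, "permutation_tests.csv"),
            row.names = FALSE)
  write.csv(result$partition, file.path(out_dir, "module_partition.csv"),
            row.names = FALSE)
  if (!is.null(result$edge_labels))
    write.table(result$edge_labels,
                file.path(out_dir, "nbs_component_edges.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$behavior_correlations))
    write.csv(result$behavior_correlations,
              file.path(out_dir, "behavior_correlations.csv"),
              row.names = FALSE)
  summary_json <- list(
    excluded = result$excluded,
    nbs = summary(result$nbs),
    classification = result$classification$summary,
    roc_auc = result$classification$roc_auc)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.connectome_analysis <- function(x, ...) {
  tab <- table(x$covariates$group)
  cat(sprintf("Connectome group analysis: %s analyzed (%s), %d excluded\n",
              sum(tab), paste(sprintf("%d %s", tab, names(tab)),
                              collapse = ", "), length(x$excluded)))
  cat("Permutation tests on metric AUCs (covariate-adjusted):\n")
  for (m in names(x$permutation_tests))
    cat(sprintf("  %-8s diff %+ .4f  p = %.4g\n", m,
                x$permutation_tests[[m]]$observed_diff,
                x$permutation_tests[[m]]$p_value))
  print(x$nbs)
  print(x$classification)
  invisible(x)
}

#' @export
summary.connectome_analysis <- function(object, ...) {
  list(groups = table(object$covariates$group),
       metric_p = vapply(object$permutation_tests, `[[`, 0, "p_value"),
       nbs = summary(object$nbs),
       classification = object$classification$summary)
}
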