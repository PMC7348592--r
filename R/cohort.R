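# Synthetic two-group cohort generator.
#
# Emulates a case-control resting-state fMRI study at the regional level:
# per-subject ROI time series drawn from a zero-mean multivariate normal
# whose correlation matrix has modular (block) structure over eight
# functional systems, a patient-group reduction of connectivity on a
# designated edge set, group-confounded covariates, behavior scores linked
# to realized connectivity, six-parameter motion traces with occasional
# spikes, and a voxel-label count table for purity-index system assignment.

#' Functional-system names used for the modular partition
#'
#' Seven cortical systems in their conventional order plus an eighth
#' subcortical module. The integer position of a name is its system id;
#' ties in purity assignment are broken toward the lowest id.
#'
#' @return character vector of length 8.
#' @export
system_names <- function() {
  c("visual", "sensorimotor", "dorsal_attention", "ventral_attention",
    "limbic", "frontoparietal", "default_mode", "subcortical")
}

#' Default assignment of regions to the eight functional systems
#'
#' Splits `n_regions` nodes into contiguous blocks whose relative sizes
#' roughly follow a 90-region anatomical parcellation (visual 12,
#' sensorimotor 12, dorsal attention 10, ventral attention 10, limbic 8,
#' frontoparietal 12, default mode 16, subcortical 10 at N = 90).
#'
#' @param n_regions number of regions.
#' @return integer vector of system ids in `1:8`, named by system.
#' @export
default_module_labels <- function(n_regions = 90) {
  stopifnot(n_regions >= 8)
  base <- c(12, 12, 10, 10, 8, 12, 16, 10) / 90
  sizes <- round_half_up(base * n_regions)
  # fix rounding drift on the largest block
  sizes[7] <- sizes[7] + (n_regions - sum(sizes))
  stopifnot(all(sizes >= 1), sum(sizes) == n_regions)
  labels <- rep.int(seq_len(8L), times = sizes)
  names(labels) <- system_names()[labels]
  labels
}

#' Default edge set carrying the patient-group effect
#'
#' Draws a deterministic (seeded) subset of edges from the categories where
#' leukoaraiosis-type disconnection concentrates: between-module edges among
#' the default-mode, frontoparietal, ventral-attention and limbic systems,
#' plus within-module edges of the ventral-attention and limbic systems.
#'
#' @param module_labels integer system ids per region (see
#'   [default_module_labels()]).
#' @param n_edges number of edges to draw; the default takes 56 (the size
#'   of a typical disconnected subnetwork at the 90-region scale) or the
#'   whole affected pool when it is smaller.
#' @param seed integer seed for the subset draw.
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
default_target_edges <- function(module_labels, n_edges = NULL, seed = 1L) {
  ep <- edge_pairs(length(module_labels))
  si <- module_labels[ep[, 1L]]
  sj <- module_labels[ep[, 2L]]
  affected <- c(4L, 5L, 6L, 7L)          # VAN, limbic, FPN, DMN
  inter <- si != sj & si %in% affected & sj %in% affected
  intra <- si == sj & si %in% c(4L, 5L)  # within VAN / limbic
  pool <- which(inter | intra)
  if (is.null(n_edges)) n_edges <- min(56L, length(pool))
  if (n_edges > length(pool))
    stop("requested more target edges than the affected categories contain")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 97L))
  sel <- sort(sample(pool, n_edges))
  ep[sel, , drop = FALSE]
}

# Save/restore the RNG state so seeded helpers do not disturb the caller.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Specify a synthetic two-group cohort
#'
#' Collects and validates every parameter of the generative model. The
#' model correlation matrix for controls is block structured:
#' `within_module_r` off the diagonal inside a system, `between_module_r`
#' across systems, unit diagonal. Patients use the same matrix with the
#' entries on `target_edges` scaled by `1 - effect_size`, followed by a
#' positive-semidefinite repair. `effect_size = 0` makes the two groups'
#' generative distributions identical.
#'
#' @param n_control,n_patient group sizes.
#' @param n_regions number of regions (default 90).
#' @param n_timepoints volumes per subject (default 230).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param module_labels per-region system id in `1:8`; default
#'   [default_module_labels()].
#' @param within_module_r,between_module_r model correlations inside and
#'   across systems; `0 <= between < within < 1`.
#' @param effect_size fractional reduction in `[0, 1]` applied to
#'   `target_edges` in the patient group.
#' @param target_edges two-column integer matrix of edges carrying the
#'   effect; default [default_target_edges()].
#' @param covariate_model list with per-group means/SDs of age and education
#'   and the male proportion; see defaults.
#' @param behavior_model named list; each element `c(intercept, slope, sd)`
#'   links a score linearly to the subject's realized mean Fisher-z
#'   connectivity over `target_edges` plus Gaussian noise.
#' @param spike_rate expected motion spikes per subject (Poisson mean).
#' @param ar1 optional lag-1 autocorrelation of the time series (default 0,
#'   temporally white).
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_patient,
                        n_regions = 90, n_timepoints = 230, tr_seconds = 2,
                        module_labels = default_module_labels(n_regions),
                        within_module_r = 0.5, between_module_r = 0.1,
                        effect_size = 0.3,
                        target_edges = default_target_edges(module_labels,
                                                            seed = seed),
                        covariate_model = list(
                          control = list(age = c(60.8, 10.7),
                                         education = c(11.3, 3.3),
                                         male_prop = 16 / 31),
                          patient = list(age = c(72.5, 7.9),
                                         education = c(11.1, 3.6),
                                         male_prop = 17 / 34)),
                        behavior_model = list(
                          Similarity = c(intercept = 10, slope = 25, sd = 3),
                          StroopC = c(intercept = 130, slope = -180, sd = 25)),
                        spike_rate = 0.5, ar1 = 0, seed = 1L) {
  check_scalar(n_control, "n_control", 1); check_scalar(n_patient, "n_patient", 1)
  check_scalar(n_regions, "n_regions", 2)
  check_scalar(n_timepoints, "n_timepoints", 2)
  check_scalar(tr_seconds, "tr_seconds", 0, open_lo = TRUE)
  check_scalar(within_module_r, "within_module_r", 0, 1,
               open_lo = TRUE, open_hi = TRUE)
  check_scalar(between_module_r, "between_module_r", 0, within_module_r,
               open_hi = TRUE)
  check_scalar(effect_size, "effect_size", 0, 1)
  check_scalar(spike_rate, "spike_rate", 0)
  check_scalar(ar1, "ar1", 0, 1, open_hi = TRUE)
  stopifnot(length(module_labels) == n_regions,
            all(module_labels %in% 1:8))
  target_edges <- as.matrix(target_edges)
  stopifnot(ncol(target_edges) == 2,
            all(target_edges >= 1), all(target_edges <= n_regions),
            all(target_edges[, 1] < target_edges[, 2]))
  spec <- structure(list(
    n_control = as.integer(n_control), n_patient = as.integer(n_patient),
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, module_labels = as.integer(module_labels),
    within_module_r = within_module_r, between_module_r = between_module_r,
    effect_size = effect_size, target_edges = target_edges,
    covariate_model = covariate_model, behavior_model = behavior_model,
    spike_rate = spike_rate, ar1 = ar1, seed = as.integer(seed),
    rank_deficient = n_timepoints < n_regions), class = "cohort_spec")
  # model matrices are part of the spec: fail early if they cannot be built
  spec$model_r <- list(control = model_correlation(spec, "control"),
                       patient = model_correlation(spec, "patient"))
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d controls + %d patients, %d regions, T = %d (TR %gs)\n",
    x$n_control, x$n_patient, x$n_regions, x$n_timepoints, x$tr_seconds))
  cat(sprintf("  within/between-module r: %.2f / %.2f; effect size %.2f on %d edges\n",
              x$within_module_r, x$between_module_r, x$effect_size,
              nrow(x$target_edges)))
  invisible(x)
}

# Clip negative eigenvalues at `floor` and rescale to unit diagonal.
psd_repair <- function(r, floor = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= floor) return(r)
  v <- pmax(e$values, floor)
  r2 <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(r2))
  r2 <- r2 * tcrossprod(d)
  diag(r2) <- 1
  (r2 + t(r2)) / 2
}

#' Model correlation matrix of one group
#'
#' @param spec a [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @return symmetric `n_regions` x `n_regions` correlation matrix with unit
#'   diagonal, positive semidefinite (repaired by eigenvalue clipping when
#'   the patient-group edge reduction breaks semidefiniteness).
#' @export
model_correlation <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  same <- outer(spec$module_labels, spec$module_labels, "==")
  r <- ifelse(same, spec$within_module_r, spec$between_module_r)
  diag(r) <- 1
  if (group == "patient" && spec$effect_size > 0) {
    te <- spec$target_edges
    r[te] <- r[te] * (1 - spec$effect_size)
    r[te[, c(2, 1), drop = FALSE]] <- r[te]
  }
  r <- psd_repair(r)
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("model correlation matrix is not positive semidefinite after repair")
  r
}

# Draw a T x N zero-mean Gaussian series with cross-correlation `r` and
# optional AR(1) temporal structure (stationary, unit marginal variance).
draw_timeseries <- function(n_t, r, ar1 = 0) {
  ch <- chol(psd_repair(r, 1e-8) + diag(1e-10, nrow(r)))
  e <- matrix(rnorm(n_t * nrow(r)), n_t, nrow(r))
  if (ar1 > 0) {
    e <- apply(e, 2, function(x) as.numeric(stats::filter(
      x * sqrt(1 - ar1^2), ar1, method = "recursive",
      init = x[1])))
  }
  e %*% ch
}

#' Generate a synthetic cohort
#'
#' Draws every subject's regional time series, motion trace, covariates and
#' behavior scores from the generative model in `spec`. Behavior scores
#' follow `score = intercept + slope * mean_z + noise`, where `mean_z` is
#' the subject's realized mean Fisher-z connectivity over the target edges,
#' so brain-behavior associations are recoverable by construction. Identical
#' spec and seed reproduce the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort`: a list of `subject_record`s with the
#'   spec attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$rank_deficient)
    warning("n_timepoints < n_regions: sample correlation matrices are rank deficient")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  groups <- rep(c("control", "patient"), c(spec$n_control, spec$n_patient))
  n <- length(groups)
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    set.seed(derive_seed(spec$seed, s))
    grp <- groups[s]
    cm <- spec$covariate_model[[grp]]
    age <- rnorm(1, cm$age[1], cm$age[2])
    education <- max(0, rnorm(1, cm$education[1], cm$education[2]))
    gender <- if (runif(1) < cm$male_prop) "male" else "female"
    x <- draw_timeseries(spec$n_timepoints, spec$model_r[[grp]], spec$ar1)
    region_ids <- sprintf("R%03d", seq_len(spec$n_regions))
    ts <- roi_timeseries(x, spec$tr_seconds, region_ids)
    motion <- generate_motion_traces(spec$n_timepoints, spec$spike_rate,
                                     seed = derive_seed(spec$seed, 10000L + s),
                                     tr_seconds = spec$tr_seconds)
    rz <- ut_vector(cor(x))
    te_idx <- match_edge_index(spec$target_edges, spec$n_regions)
    mean_z <- mean(fisher_z(rz[te_idx]))
    set.seed(derive_seed(spec$seed, 20000L + s))
    behavior <- vapply(spec$behavior_model, function(b)
      unname(b["intercept"] + b["slope"] * mean_z + rnorm(1, 0, b["sd"])),
      numeric(1))
    subjects[[s]] <- structure(list(
      subject_id = sprintf("S%03d", s), group = grp,
      age = age, gender = gender, education = education,
      behavior = behavior, timeseries = ts, motion = motion),
      class = "subject_record")
  }
  structure(subjects, spec = spec, class = "cohort")
}

# Map (i, j) edge rows to positions in the lex-ordered edge vector.
match_edge_index <- function(edges, n_nodes) {
  i <- edges[, 1L]; j <- edges[, 2L]
  # offset of row block for first index i, then position of j
  as.integer((i - 1L) * n_nodes - i * (i - 1L) / 2 + (j - i))
}

#' @export
print.cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  tab <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("Synthetic cohort: %s subjects (%s)\n", length(x),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", ")))
  cat(sprintf("  %d regions x %d timepoints, TR %gs, seed %d\n",
              spec$n_regions, spec$n_timepoints, spec$tr_seconds, spec$seed))
  invisible(x)
}

#' Covariate table of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data frame with subject_id, group, age, gender (coded 0 = female,
#'   1 = male), education and one column per behavior score.
#' @export
cohort_covariates <- function(cohort) {
  df <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    group = vapply(cohort, `[[`, "", "group"),
    age = vapply(cohort, `[[`, 0, "age"),
    gender = as.integer(vapply(cohort, `[[`, "", "gender") == "male"),
    education = vapply(cohort, `[[`, 0, "education"),
    stringsAsFactors = FALSE)
  beh <- do.call(rbind, lapply(cohort, `[[`, "behavior"))
  cbind(df, as.data.frame(beh))
}

#' Generate a six-parameter head-motion trace
#'
#' Smooth low-amplitude drift in three translations (mm) and three rotations
#' (radians), with Poisson-placed single-volume spikes whose framewise
#' displacement exceeds 0.5 mm.
#'
#' @param n_volumes number of volumes (>= 1).
#' @param spike_rate expected number of spikes (Poisson mean).
#' @param seed integer seed.
#' @param tr_seconds repetition time, stored for downstream scrub reports.
#' @return a `motion_trace` with framewise displacement precomputed.
#' @export
generate_motion_traces <- function(n_volumes, spike_rate, seed = 1L,
                                   tr_seconds = 2) {
  stopifnot(n_volumes >= 1)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 7L))
  trans <- matrix(0, n_volumes, 3)
  rot <- matrix(0, n_volumes, 3)
  for (k in 1:3) {
    trans[, k] <- cumsum(rnorm(n_volumes, 0, 0.01))
    rot[, k] <- cumsum(rnorm(n_volumes, 0, 2e-4))
  }
  n_spikes <- rpois(1, spike_rate)
  if (n_spikes > 0 && n_volumes >= 2) {
    at <- sample(2:n_volumes, min(n_spikes, n_volumes - 1L))
    for (t in at) trans[t, ] <- trans[t, ] + c(0.4, 0.35, 0.35)
  }
  framewise_displacement(motion_trace(trans, rot, tr_seconds))
}

#' Generate a per-region voxel label-count table
#'
#' Emulates overlaying an anatomical parcellation on a voxelwise 7-system
#' functional atlas: each region's nonzero voxels are multinomial over the
#' seven cortical systems with probability `purity` on the region's true
#' system. Subcortical regions carry a `subcortical` flag (and nominally
#' limbic-dominated counts, which the flag overrides downstream).
#'
#' @param n_regions number of regions.
#' @param purity probability of the true system label per voxel, in (0, 1].
#' @param seed integer seed.
#' @param module_labels per-region system ids (default
#'   [default_module_labels()]).
#' @param n_voxels nonzero voxels per region (default 1000).
#' @return data frame: `region`, one count column per cortical system,
#'   logical `subcortical`.
#' @export
generate_voxel_label_counts <- function(n_regions, purity, seed = 1L,
                                        module_labels = default_module_labels(n_regions),
                                        n_voxels = 1000) {
  check_scalar(purity, "purity", 0, 1, open_lo = TRUE)
  stopifnot(length(module_labels) == n_regions)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 11L))
  sys7 <- system_names()[1:7]
  counts <- matrix(0L, n_regions, 7, dimnames = list(NULL, sys7))
  subcortical <- module_labels == 8L
  for (g in seq_len(n_regions)) {
    true_sys <- if (subcortical[g]) 5L else module_labels[g]  # limbic-dominant
    p <- rep((1 - purity) / 6, 7)
    p[true_sys] <- purity
    counts[g, ] <- as.integer(stats::rmultinom(1, n_voxels, p))
  }
  data.frame(region = sprintf("R%03d", seq_len(n_regions)), counts,
             subcortical = subcortical, stringsAsFactors = FALSE)
}

#' Write a cohort to a directory tree
#'
#' Per-subject time-series TSV (one row per timepoint, header = region ids),
#' motion TSV (six columns), a covariate CSV and a JSON manifest.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(cohort, "spec")
  for (s in cohort) {
    ts <- s$timeseries
    df <- as.data.frame(ts$data); names(df) <- ts$region_ids
    write.table(df, file.path(dir, paste0(s$subject_id, "_timeseries.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    m <- cbind(s$motion$translations, s$motion$rotations)
    colnames(m) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
    write.table(m, file.path(dir, paste0(s$subject_id, "_motion.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.csv(cohort_covariates(cohort), file.path(dir, "covariates.csv"),
            row.names = FALSE)
  manifest <- list(n_subjects = length(cohort),
                   n_regions = spec$n_regions,
                   n_timepoints = spec$n_timepoints,
                   tr_seconds = spec$tr_seconds, seed = spec$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `cohort` (without a generative spec attribute).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cov <- read.csv(file.path(dir, "covariates.csv"), stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(cov)), function(k) {
    id <- cov$subject_id[k]
    ts <- as.matrix(read.delim(file.path(dir, paste0(id, "_timeseries.tsv"))))
    m <- as.matrix(read.delim(file.path(dir, paste0(id, "_motion.tsv"))))
    beh_cols <- setdiff(names(cov),
                        c("subject_id", "group", "age", "gender", "education"))
    structure(list(
      subject_id = id, group = cov$group[k], age = cov$age[k],
      gender = if (cov$gender[k] == 1) "male" else "female",
      education = cov$education[k],
      behavior = unlist(cov[k, beh_cols, drop = FALSE]),
      timeseries = roi_timeseries(ts, manifest$tr_seconds, colnames(ts)),
      motion = framewise_displacement(
        motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE],
                     manifest$tr_seconds))), class = "subject_record")
  })
  structure(subjects, class = "cohort")
}
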