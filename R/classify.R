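# Stepwise linear discriminant classification with leave-one-out
# cross-validation and ROC.

# Wilks' lambda of a variable subset: det(W)/det(T) with W the pooled
# within-group and T the total SSCP matrix.
wilks_lambda <- function(w, t, subset) {
  if (!length(subset)) return(1)
  dw <- det(w[subset, subset, drop = FALSE])
  dt <- det(t[subset, subset, drop = FALSE])
  if (!is.finite(dw) || !is.finite(dt) || dt <= 0) return(NA_real_)
  max(dw / dt, 0)
}

sscp <- function(x, labels) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  t_mat <- crossprod(xc)
  w_mat <- matrix(0, ncol(x), ncol(x))
  for (g in levels(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    xg <- scale(xg, center = TRUE, scale = FALSE)
    w_mat <- w_mat + crossprod(xg)
  }
  list(w = w_mat, t = t_mat)
}

# Stepwise selection by partial F on Wilks' lambda (SPSS convention:
# enter when partial F >= f_enter, remove when <= f_remove).
stepwise_wilks <- function(x, labels, f_enter = 3.84, f_remove = 2.71,
                           max_steps = 100) {
  n <- nrow(x); g <- nlevels(labels); p_all <- ncol(x)
  s <- sscp(x, labels)
  selected <- integer(0)
  lambda_of <- function(set) wilks_lambda(s$w, s$t, set)
  f_enter_stat <- function(v) {
    p <- length(selected)
    l0 <- lambda_of(selected); l1 <- lambda_of(c(selected, v))
    if (is.na(l1) || l1 < 1e-12) return(NA_real_)
    (n - g - p) / (g - 1) * (l0 / l1 - 1)
  }
  f_remove_stat <- function(v) {
    p <- length(selected)
    l1 <- lambda_of(selected); l0 <- lambda_of(setdiff(selected, v))
    if (is.na(l1) || l1 < 1e-12) return(Inf)
    (n - g - p + 1) / (g - 1) * (l0 / l1 - 1)
  }
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    cand <- setdiff(seq_len(p_all), selected)
    if (length(cand) && n - g - length(selected) > 0) {
      fs <- vapply(cand, f_enter_stat, numeric(1))
      if (any(is.finite(fs)) && max(fs, na.rm = TRUE) >= f_enter) {
        selected <- c(selected, cand[which.max(fs)])
        changed <- TRUE
      }
    }
    while (length(selected) > 1) {
      fr <- vapply(selected, f_remove_stat, numeric(1))
      if (min(fr) <= f_remove) {
        selected <- selected[-which.min(fr)]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  selected
}

#' Summarize a 2 x 2 confusion matrix
#'
#' Rows are true classes (negative first, positive second), columns are
#' predicted classes in the same order; the positive class is the patient
#' group. Percentages are reported to one decimal.
#'
#' @param confusion 2 x 2 count matrix.
#' @return named vector: `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
confusion_summary <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == 2), sum(confusion) > 0)
  tn <- confusion[1, 1]; fp <- confusion[1, 2]
  fn <- confusion[2, 1]; tp <- confusion[2, 2]
  c(accuracy = round(100 * (tp + tn) / sum(confusion), 1),
    sensitivity = round(100 * tp / (tp + fn), 1),
    specificity = round(100 * tn / (tn + fp), 1))
}

#' Stepwise linear discriminant classification with LOOCV
#'
#' Wilks'-lambda stepwise feature selection (partial-F entry/removal at the
#' SPSS defaults 3.84 / 2.71) followed by a linear discriminant fit, with
#' resubstitution and leave-one-out confusion matrices and the ROC AUC of
#' the discriminant scores. By default the stepwise selection is re-run
#' inside every leave-one-out fold (honest cross-validation);
#' `select_in_folds = FALSE` reuses the full-sample selection, the
#' optimistic variant common in clinical reports.
#'
#' @param features subject x feature numeric matrix or data frame.
#' @param labels two-level factor (or character) of group membership.
#' @param f_enter,f_remove partial-F thresholds (defaults 3.84 / 2.71).
#' @param positive label treated as the positive (patient) class; default
#'   `"patient"` when present, otherwise the second factor level.
#' @param equal_priors use equal class priors instead of the observed
#'   frequencies.
#' @param select_in_folds re-run stepwise selection inside each fold.
#' @return object of class `classification_report`.
#' @export
stepwise_lda_loocv <- function(features, labels, f_enter = 3.84,
                               f_remove = 2.71, positive = NULL,
                               equal_priors = FALSE,
                               select_in_folds = TRUE) {
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("features must be finite")
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, all(table(labels) >= 2))
  if (is.null(positive))
    positive <- if ("patient" %in% levels(labels)) "patient"
                else levels(labels)[2]
  negative <- setdiff(levels(labels), positive)
  labels <- factor(labels, levels = c(negative, positive))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  prior <- if (equal_priors) c(0.5, 0.5)
           else as.numeric(table(labels)) / length(labels)

  fit_predict <- function(train_idx, test_idx, sel) {
    if (!length(sel)) {
      maj <- names(which.max(table(labels[train_idx])))
      return(list(class = factor(rep(maj, length(test_idx)),
                                 levels = levels(labels)),
                  score = rep(0.5, length(test_idx))))
    }
    fit <- MASS::lda(x[train_idx, sel, drop = FALSE],
                     grouping = labels[train_idx], prior = prior)
    pr <- stats::predict(fit, x[test_idx, sel, drop = FALSE])
    list(class = pr$class, score = pr$posterior[, positive])
  }

  sel_full <- stepwise_wilks(x, labels, f_enter, f_remove)
  all_idx <- seq_len(nrow(x))
  resub <- fit_predict(all_idx, all_idx, sel_full)
  conf_resub <- table(true = labels, predicted = resub$class)

  cv_class <- factor(rep(NA, nrow(x)), levels = levels(labels))
  cv_score <- numeric(nrow(x))
  for (i in all_idx) {
    tr <- all_idx[-i]
    sel_i <- if (select_in_folds)
      stepwise_wilks(x[tr, , drop = FALSE], droplevels(labels[tr]),
                     f_enter, f_remove)
    else sel_full
    pr <- fit_predict(tr, i, sel_i)
    cv_class[i] <- pr$class
    cv_score[i] <- pr$score
  }
  conf_cv <- table(true = labels, predicted = cv_class)

  roc_auc <- if (length(sel_full) && length(unique(resub$score)) > 1)
    as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = resub$score,
      levels = c(negative, positive), direction = "<", quiet = TRUE)))
  else 0.5

  structure(list(
    selected_features = colnames(x)[sel_full],
    positive = positive,
    confusion = list(resubstitution = unclass(conf_resub),
                     loocv = unclass(conf_cv)),
    summary = list(resubstitution = confusion_summary(conf_resub),
                   loocv = confusion_summary(conf_cv)),
    roc_auc = roc_auc, prior = prior,
    resub_scores = resub$score,
    loocv_scores = cv_score), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Stepwise LDA classification\n")
  cat(sprintf("  selected features: %s\n",
              if (length(x$selected_features))
                paste(x$selected_features, collapse = ", ") else "(none)"))
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-15s accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
                nm, s["accuracy"], s["sensitivity"], s["specificity"]))
  }
  cat(sprintf("  ROC AUC (resubstitution scores): %.3f\n", x$roc_auc))
  invisible(x)
}
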