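#' PCA + SVM classification with fused, inter- and intra-patient frameworks
#'
#' Spectral signatures (59-dim) are compressed to their top five principal
#' component scores, which feed a support vector machine. Three evaluation
#' frameworks are distinguished by what the classifier is trained on:
#' `fused` uses relative signatures (per-patient normalized) pooled across
#' patients; `inter_patient` uses raw signatures pooled across patients;
#' `intra_patient` trains and tests within one patient. Performance is
#' quantified by rank-based ROC/AUC, stratified K-fold cross validation and
#' leave-one-patient-out evaluation, with PCA and SVM refit inside every
#' training split.
#'
#' @name classification
NULL

#' Fit a principal component model
#'
#' Centered PCA; component signs are fixed by making each component's
#' largest-magnitude loading positive, so fits are deterministic.
#'
#' @param x data matrix (rows = observations)
#' @param k number of components to keep (default 5)
#' @return an `afmi_pca` with `mean`, `components` (k x p, orthonormal
#'   rows), `explained_variance_ratio` (all p components), `k`
#' @export
fit_pca <- function(x, k = 5L) {
  x <- as.matrix(x)
  if (nrow(x) < k + 1)
    afmi_stop("afmi_pca_too_few_rows", "need >= k+1 = %d rows, got %d",
              k + 1, nrow(x))
  if (!all(is.finite(x)))
    afmi_stop("afmi_pca_nonfinite", "non-finite entries in PCA input")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-10)
  if (rank < k)
    afmi_stop("afmi_pca_rank_deficient",
              "requested k = %d but achievable rank is %d", k, rank)
  rot <- t(pr$rotation[, seq_len(k), drop = FALSE])
  dimnames(rot) <- NULL
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[j, ]))
    if (rot[j, i] < 0) rot[j, ] <- -rot[j, ]
  }
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(mean = pr$center, components = rot,
                 explained_variance_ratio = evr, k = as.integer(k)),
            class = "afmi_pca")
}

#' Project rows onto the top-k PCA scores
#' @param pca an `afmi_pca`
#' @param x data matrix
#' @return scores matrix (n x k)
#' @export
pca_scores <- function(pca, x) {
  sweep(as.matrix(x), 2, pca$mean) %*% t(pca$components)
}

#' Train a PCA + SVM classifier bundle
#'
#' @param table signature table rows for training (tissue sectors with
#'   labels in normal/PTG/OSSN)
#' @param framework `"fused"` (uses `rss_*` columns), `"inter_patient"` or
#'   `"intra_patient"` (use raw `ch_*` columns)
#' @param pca_k number of PCA scores (default 5)
#' @param kernel,cost,gamma passed to [svm_fit()]
#' @param classes restrict to these classes (default: all present)
#' @return an `afmi_classifier_bundle`
#' @export
train_classifier <- function(table, framework = c("fused", "inter_patient",
                                                  "intra_patient"),
                             pca_k = 5L, kernel = "rbf", cost = 1,
                             gamma = NULL, classes = NULL) {
  framework <- match.arg(framework)
  # fused and intra-patient operate on per-patient normalized features
  prefix <- if (framework == "inter_patient") "ch_" else "rss_"
  keep <- table$label %in% (classes %||% afmi_classes())
  table <- table[keep, , drop = FALSE]
  y <- table$label
  if (length(unique(y)) < 2)
    afmi_stop("afmi_single_class", "training data has a single class")
  x <- signature_matrix(table, prefix)
  pca <- fit_pca(x, k = pca_k)
  scores <- pca_scores(pca, x)
  svm <- svm_fit(scores, y, kernel = kernel, cost = cost, gamma = gamma)
  manifest <- list(
    patients = sort(unique(table$patient_id)),
    sector_ids = paste(table$patient_id, table$sector_row, table$sector_col,
                       sep = ":"),
    n_per_class = table(y))
  structure(list(pca = pca, svm = svm, classes = sort(unique(y)),
                 framework = framework, prefix = prefix,
                 training_manifest = manifest),
            class = "afmi_classifier_bundle")
}

#' Decision scores / predictions from a bundle
#' @param bundle an `afmi_classifier_bundle`
#' @param table signature table rows
#' @return [classifier_scores()]: matrix of decision values;
#'   [classifier_predict()]: character labels
#' @export
classifier_scores <- function(bundle, table) {
  x <- signature_matrix(table, bundle$prefix)
  svm_decision(bundle$svm, pca_scores(bundle$pca, x))
}

#' @rdname classifier_scores
#' @export
classifier_predict <- function(bundle, table) {
  x <- signature_matrix(table, bundle$prefix)
  svm_predict(bundle$svm, pca_scores(bundle$pca, x))
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Ties contribute 1/2 via midranks; equals brute-force concordant-pair
#' counting.
#' @param scores continuous decision scores
#' @param positive logical vector, `TRUE` for the positive class
#' @return AUC in `[0, 1]`
#' @export
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    afmi_stop("afmi_missing_class", "both classes required for AUC")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(positive[ord]); fp <- cumsum(!positive[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(!positive)),
             tpr = c(0, tp[keep] / sum(positive)))
}

#' ROC / AUC evaluation of a bundle on held-out rows
#'
#' Pairwise tasks use the decision score for the positive class; three-way
#' tasks report the unweighted macro mean of one-vs-rest AUCs.
#'
#' @param bundle an `afmi_classifier_bundle`
#' @param table held-out signature table rows
#' @param positive positive class for pairwise tasks (default `"OSSN"` when
#'   present)
#' @return list with `auc`, `roc` (pairwise: data frame of fpr/tpr),
#'   `per_class_auc` (three-way)
#' @export
evaluate_roc_auc <- function(bundle, table, positive = NULL) {
  table <- table[table$label %in% bundle$classes, , drop = FALSE]
  y <- table$label
  missing <- setdiff(bundle$classes, unique(y))
  if (length(missing))
    afmi_stop("afmi_missing_class", "test set missing class(es): %s",
              paste(missing, collapse = ", "))
  sc <- classifier_scores(bundle, table)
  if (length(bundle$classes) == 2) {
    positive <- positive %||% if ("OSSN" %in% bundle$classes) "OSSN" else
      bundle$classes[2]
    s <- sc[, 1]
    if (positive != colnames(sc)[1]) s <- -s
    pos <- y == positive
    list(task = paste(bundle$classes, collapse = "-vs-"),
         positive = positive, auc = rank_auc(s, pos),
         roc = roc_points(s, pos))
  } else {
    aucs <- vapply(bundle$classes, function(cl)
      rank_auc(sc[, cl], y == cl), numeric(1))
    list(task = "three-way", auc = mean(aucs), per_class_auc = aucs)
  }
}

#' Accuracy, sensitivity and specificity
#'
#' Sensitivity is `TP/(TP+FN)` for the designated positive class,
#' specificity `TN/(TN+FP)`; with more than two classes, accuracy is the
#' overall fraction correct and sensitivity/specificity are one-vs-rest for
#' the positive class.
#' @param y_true,y_pred equal-length label vectors
#' @param positive positive class (default `"OSSN"` if present)
#' @return named numeric vector (accuracy, sensitivity, specificity)
#' @export
confusion_metrics <- function(y_true, y_pred, positive = NULL) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    afmi_stop("afmi_bad_labels", "label vectors empty or unequal length")
  positive <- positive %||% if ("OSSN" %in% y_true) "OSSN" else
    sort(unique(y_true))[1]
  if (!positive %in% c(y_true, y_pred))
    afmi_stop("afmi_bad_labels", "positive class '%s' absent", positive)
  acc <- mean(y_true == y_pred)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  c(accuracy = acc,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Cross-validated evaluation
#'
#' `kfold`: folds stratified by class at sector level (a patient may span
#' folds; set `group_by_patient = TRUE` for patient-disjoint folds).
#' `lopo`: one fold per patient, all of that patient's sectors held out.
#' PCA and SVM are refit inside every training split. The report carries
#' mean +/- sd of accuracy/sensitivity/specificity over folds, the pooled
#' AUC over all held-out decision scores, and (for lopo) per-patient and
#' pooled overall accuracy.
#'
#' @param table signature table (tissue sectors, labeled)
#' @param mode `"kfold"` or `"lopo"`
#' @param k number of folds for kfold (default 10)
#' @param framework passed to [train_classifier()]
#' @param classes restrict task to these classes (e.g. `c("PTG", "OSSN")`)
#' @param seed RNG seed for fold assignment
#' @param group_by_patient patient-disjoint kfold folds?
#' @param positive positive class for pairwise metrics
#' @param ... further arguments to [train_classifier()]
#' @return an `afmi_eval_report` list
#' @export
cross_validate <- function(table, mode = c("kfold", "lopo"), k = 10L,
                           framework = "fused", classes = NULL, seed = 1,
                           group_by_patient = FALSE, positive = NULL, ...) {
  mode <- match.arg(mode)
  classes <- classes %||% intersect(afmi_classes(), unique(table$label))
  table <- table[table$label %in% classes, , drop = FALSE]
  y <- table$label
  n <- nrow(table)
  if (mode == "kfold" && n < k)
    afmi_stop("afmi_too_few_rows", "need >= k rows")
  if (mode == "lopo" && length(unique(table$patient_id)) < 3)
    afmi_stop("afmi_too_few_patients", "lopo needs >= 3 patients")

  set.seed(derive_seed(seed, "cv_folds"))
  fold <- integer(n)
  if (mode == "lopo") {
    pid <- unique(table$patient_id)
    fold <- match(table$patient_id, pid)
    nf <- length(pid)
  } else if (group_by_patient) {
    pid <- sample(unique(table$patient_id))
    fold <- (match(table$patient_id, pid) - 1L) %% k + 1L
    nf <- k
  } else {
    for (cl in classes) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    nf <- k
  }

  per_fold <- list()
  pooled_scores <- numeric(0); pooled_pos <- logical(0)
  pooled_true <- character(0); pooled_pred <- character(0)
  per_patient <- list()
  skipped <- 0L
  positive <- positive %||% if ("OSSN" %in% classes) "OSSN" else classes[2]
  for (f in seq_len(nf)) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    if (length(unique(tr$label)) < 2 || !nrow(te)) {
      skipped <- skipped + 1L
      warning(sprintf("fold %d skipped (single-class or empty)", f))
      next
    }
    bundle <- train_classifier(tr, framework = framework, classes = classes,
                               ...)
    pred <- classifier_predict(bundle, te)
    cm <- confusion_metrics(te$label, pred, positive = positive)
    per_fold[[length(per_fold) + 1L]] <- cm
    pooled_true <- c(pooled_true, te$label)
    pooled_pred <- c(pooled_pred, pred)
    if (length(classes) == 2 && length(unique(te$label)) == 2) {
      sc <- classifier_scores(bundle, te)
      s <- sc[, 1]
      if (positive != colnames(sc)[1]) s <- -s
      pooled_scores <- c(pooled_scores, s)
      pooled_pos <- c(pooled_pos, te$label == positive)
    }
    if (mode == "lopo")
      per_patient[[te$patient_id[1]]] <- unname(cm["accuracy"])
  }
  if (length(per_fold) < 2)
    afmi_stop("afmi_too_few_folds", "fewer than 2 usable folds")
  fm <- do.call(rbind, per_fold)
  auc <- if (length(pooled_pos) && any(pooled_pos) && any(!pooled_pos))
    rank_auc(pooled_scores, pooled_pos) else NA_real_
  structure(list(
    mode = mode, framework = framework, classes = classes,
    positive = positive, n_folds = length(per_fold), skipped = skipped,
    auc = auc,
    accuracy_mean = mean(fm[, "accuracy"]), accuracy_sd = sd(fm[, "accuracy"]),
    sensitivity_mean = mean(fm[, "sensitivity"], na.rm = TRUE),
    sensitivity_sd = sd(fm[, "sensitivity"], na.rm = TRUE),
    specificity_mean = mean(fm[, "specificity"], na.rm = TRUE),
    specificity_sd = sd(fm[, "specificity"], na.rm = TRUE),
    overall_accuracy = mean(pooled_true == pooled_pred),
    per_patient_accuracy = if (mode == "lopo") unlist(per_patient) else NULL),
    class = "afmi_eval_report")
}

#' @export
print.afmi_eval_report <- function(x, ...) {
  cat(sprintf("<afmi_eval_report> %s, %s, %d folds\n", x$framework, x$mode,
              x$n_folds))
  if (!is.na(x$auc)) cat(sprintf("  pooled AUC: %.3f\n", x$auc))
  cat(sprintf("  accuracy %.0f +/- %.0f%%, sensitivity %.0f +/- %.0f%%, specificity %.0f +/- %.0f%%\n",
              100 * x$accuracy_mean, 100 * x$accuracy_sd,
              100 * x$sensitivity_mean, 100 * x$sensitivity_sd,
              100 * x$specificity_mean, 100 * x$specificity_sd))
  if (!is.null(x$per_patient_accuracy))
    cat(sprintf("  lopo overall accuracy: %.0f%%\n",
                100 * x$overall_accuracy))
  invisible(x)
}
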