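test_that("fit_pca matches a brute-force eigendecomposition oracle", {
  set.seed(12)
  x <- matrix(rnorm(18), 6, 3)
  p <- fit_pca(x, k = 2)
  # oracle: eigenvectors of the (population-scaled) covariance matrix
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  for (j in 1:2) {
    v <- ev$vectors[, j]
    got <- p$components[j, ]
    expect_equal(abs(sum(v * got)), 1, tolerance = 1e-8) # same axis up to sign
  }
  expect_equal(p$explained_variance_ratio,
               ev$values / sum(ev$values), tolerance = 1e-8)
  # scores agree with the oracle projection up to sign
  sc <- pca_scores(p, x)
  for (j in 1:2)
    expect_equal(abs(sc[, j]), abs(xc %*% ev$vectors[, j])[, 1],
                 tolerance = 1e-8)
})

test_that("fit_pca: exact low rank, ratio normalization, rank errors", {
  set.seed(13)
  basis <- matrix(rnorm(10), 5, 2)
  x <- matrix(rnorm(40), 20, 2) %*% t(basis) + 3 # exact 2-D affine subspace
  p <- fit_pca(x, k = 2)
  expect_equal(sum(p$explained_variance_ratio[1:2]), 1, tolerance = 1e-10)
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-12)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  # orthonormal loadings
  expect_equal(p$components %*% t(p$components), diag(2), tolerance = 1e-8)
  expect_error(fit_pca(x, k = 4), class = "afmi_pca_rank_deficient")
  expect_error(fit_pca(x[1:3, ], k = 3), class = "afmi_pca_too_few_rows")
  xb <- x; xb[1, 1] <- NA
  expect_error(fit_pca(xb, k = 2), class = "afmi_pca_nonfinite")
})

test_that("rank AUC equals brute-force pairwise concordance", {
  expect_equal(rank_auc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T)), 0.75)
  expect_equal(rank_auc(c(1, 2, 3, 4), c(F, F, T, T)), 1)
  brute <- function(s, pos) {
    sp <- s[pos]; sn <- s[!pos]
    mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(14)
  for (i in 1:20) {
    s <- sample(round(rnorm(30), 1)) # coarse rounding forces ties
    pos <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(pos) || all(pos)) next
    expect_equal(rank_auc(s, pos), brute(s, pos), tolerance = 1e-12)
    expect_equal(rank_auc(s, !pos), 1 - rank_auc(s, pos), tolerance = 1e-12)
  }
  # chance level at large n
  set.seed(15)
  expect_equal(rank_auc(rnorm(1e4), rbinom(1e4, 1, 0.5) == 1), 0.5,
               tolerance = 0.02)
})

test_that("confusion metrics follow the standard definitions", {
  y <- rep(c("OSSN", "PTG"), c(50, 50))
  expect_equal(unname(confusion_metrics(y, y)), c(1, 1, 1))
  # TP=42 FN=8 TN=45 FP=5
  pred <- c(rep("OSSN", 42), rep("PTG", 8), rep("PTG", 45), rep("OSSN", 5))
  expect_equal(unname(confusion_metrics(y, pred, positive = "OSSN")),
               c(0.87, 0.84, 0.90), tolerance = 1e-12)
  allneg <- rep("PTG", 100)
  expect_equal(unname(confusion_metrics(y, allneg, positive = "OSSN")),
               c(0.5, 0, 1), tolerance = 1e-12)
  expect_error(confusion_metrics(character(0), character(0)),
               class = "afmi_bad_labels")
})

test_that("train_classifier separates well-separated synthetic classes", {
  set.seed(16)
  n <- 40; n_ch <- 8
  sig <- rbind(matrix(rnorm(n * n_ch, 0, 1), n),
               matrix(rnorm(n * n_ch, 6, 1), n))
  colnames(sig) <- paste0("rss_", seq_len(n_ch))
  tab <- cbind(make_sig_table(matrix(0, 2 * n, 1), rep(c("PTG", "OSSN"),
                                                       each = n)),
               as.data.frame(sig))
  bundle <- train_classifier(tab, framework = "fused", pca_k = 3)
  expect_gte(mean(classifier_predict(bundle, tab) == tab$label), 0.99)
  expect_identical(bundle$prefix, "rss_")
  expect_error(train_classifier(tab[tab$label == "PTG", ]),
               class = "afmi_single_class")
})

test_that("training manifests record exactly the rows used (leakage audit)", {
  spec <- small_spec(n_patients = 3, seed = 17)
  rel <- relative_signatures(cohort_signature_table(spec))
  tt <- rel$table[rel$table$label %in% c("PTG", "OSSN"), ]
  hold <- tt$patient_id == "P003"
  bundle <- train_classifier(tt[!hold, ], framework = "fused")
  test_ids <- paste(tt$patient_id[hold], tt$sector_row[hold],
                    tt$sector_col[hold], sep = ":")
  expect_length(intersect(bundle$training_manifest$sector_ids, test_ids), 0)
  expect_false("P003" %in% bundle$training_manifest$patients)
  rep <- evaluate_roc_auc(bundle, tt[hold, ])
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_error(evaluate_roc_auc(bundle, tt[hold & tt$label == "OSSN", ]),
               class = "afmi_missing_class")
})

test_that("cross_validate is deterministic and lopo folds are per patient", {
  spec <- small_spec(n_patients = 5, seed = 18)
  rel <- relative_signatures(cohort_signature_table(spec))
  tt <- rel$table
  r1 <- cross_validate(tt, mode = "lopo", framework = "fused",
                       classes = c("PTG", "OSSN"), seed = 3)
  r2 <- cross_validate(tt, mode = "lopo", framework = "fused",
                       classes = c("PTG", "OSSN"), seed = 3)
  expect_identical(r1, r2)
  expect_identical(r1$n_folds, 5L)
  expect_setequal(names(r1$per_patient_accuracy), unique(tt$patient_id))
  r3 <- cross_validate(tt, mode = "kfold", k = 5, framework = "fused",
                       classes = c("PTG", "OSSN"), seed = 3)
  expect_identical(r3$n_folds, 5L)
  expect_true(abs(r3$auc - 0.5) <= 0.5)
  expect_error(cross_validate(tt[tt$patient_id %in% c("P001", "P002"), ],
                              mode = "lopo"),
               class = "afmi_too_few_patients")
})

test_that("three-way evaluation reports macro one-vs-rest AUC", {
  spec <- small_spec(n_patients = 3, seed = 19)
  rel <- relative_signatures(cohort_signature_table(spec))
  tt <- rel$table[rel$table$label %in% c("normal", "PTG", "OSSN"), ]
  tr <- tt$patient_id != "P003"
  bundle <- train_classifier(tt[tr, ], framework = "fused")
  rep <- evaluate_roc_auc(bundle, tt[!tr, ])
  expect_identical(rep$task, "three-way")
  expect_length(rep$per_class_auc, 3)
  expect_equal(rep$auc, mean(rep$per_class_auc), tolerance = 1e-12)
})
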