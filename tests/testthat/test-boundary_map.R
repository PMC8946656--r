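test_that("noise-free phantom boundary is recovered exactly", {
  spec <- noise_free_spec(image_shape = c(128, 128), seed = 3)
  st <- generate_patient(spec, 1)
  tab <- extract_signatures(st)
  ann <- select_annotations(tab, min_per_class = 8, seed = 3)
  bm <- detect_boundaries(st, ann, table = tab, pca_k = 2,
                          min_per_class = 8, min_normal = 5)
  expect_identical(bm$agreement, 1)
  # predicted label transition columns match the ground-truth band layout
  tissue_rows <- which(apply(bm$grid, 1, function(r) any(r != "outside")))
  for (i in tissue_rows) {
    r <- bm$grid[i, ]
    expect_identical(unname(rle(r[r != "outside"])$values),
                     c("normal", "PTG", "OSSN"))
  }
  # per-column agreement with the mask majority is exact
  expect_true(all(bm$table$predicted[bm$table$label != "outside"] ==
                    bm$table$majority[bm$table$label != "outside"]))
})

test_that("annotations covering one class are rejected", {
  spec <- noise_free_spec(image_shape = c(64, 64))
  st <- generate_patient(spec, 1)
  tab <- extract_signatures(st)
  ann <- tab$label == "normal"
  expect_error(detect_boundaries(st, ann, table = tab, min_per_class = 2,
                                 min_normal = 2),
               class = "afmi_single_class")
})

test_that("default-noise phantom reaches >= 0.9 held-out sector agreement", {
  spec <- small_spec(n_patients = 1, image_shape = c(256, 256), seed = 3)
  st <- preprocess_stack(generate_patient(spec, 1))
  tab <- extract_signatures(st)
  ann <- select_annotations(tab, min_per_class = 20, seed = 3)
  bm <- detect_boundaries(st, ann, table = tab, min_per_class = 20)
  expect_gte(bm$agreement, 0.9)
  # training sectors are never scored in the agreement metric
  expect_true(all(bm$table$training[ann]))
})

test_that("smooth_map follows the modal tie-keep-center rule", {
  uni <- matrix("PTG", 5, 5)
  expect_identical(smooth_map(uni), uni)

  spot <- matrix("normal", 3, 3); spot[2, 2] <- "OSSN"
  expect_identical(smooth_map(spot)[2, 2], "normal")

  checker <- matrix(c("PTG", "OSSN"), 6, 6)
  checker[, seq(2, 6, 2)] <- matrix(c("OSSN", "PTG"), 6, 3)
  sm <- smooth_map(checker)
  # every 3x3 neighborhood splits 5-4 or 4-5; center always in a majority
  # or tie, so the grid is unchanged
  expect_identical(sm, checker)

  # outside never changes and never votes
  g <- matrix("outside", 3, 3); g[2, 2] <- "OSSN"; g[2, 3] <- "OSSN"
  sm2 <- smooth_map(g)
  expect_identical(sm2[2, 2], "OSSN")
  expect_identical(sum(sm2 == "outside"), 7L)

  # never introduces a label absent from the input
  set.seed(22)
  for (i in 1:10) {
    g <- matrix(sample(c("normal", "OSSN", "outside"), 36, replace = TRUE),
                6, 6)
    expect_true(all(unique(as.vector(smooth_map(g, radius = 1,
                                                iterations = 2))) %in%
                      unique(as.vector(g))))
  }
})

test_that("overlay legend is bit-exact at full opacity", {
  spec <- noise_free_spec(image_shape = c(128, 128))
  st <- generate_patient(spec, 1)
  tab <- extract_signatures(st)
  ann <- select_annotations(tab, min_per_class = 8, seed = 1)
  bm <- detect_boundaries(st, ann, table = tab, pca_k = 2,
                          min_per_class = 8, min_normal = 5)
  rgb <- render_boundary_overlay(bm, opacity = 1)
  legend <- list(normal = c(0, 1, 0), PTG = c(1, 165 / 255, 0),
                 OSSN = c(1, 0, 0))
  for (k in which(!is.na(bm$table$predicted))[1:5]) {
    lab <- bm$table$predicted[k]
    px <- rgb[bm$table$r0[k], bm$table$c0[k], ]
    expect_identical(unname(px), legend[[lab]])
  }
  p <- withr::local_tempfile(fileext = ".ppm")
  write_ppm(rgb, p)
  hdr <- readLines(p, 3)
  expect_identical(hdr, c("P3", "128 128", "255"))
})

test_that("PCA false color separates classes more than within-class noise", {
  spec <- small_spec(n_patients = 1, image_shape = c(128, 128), seed = 8)
  st <- preprocess_stack(generate_patient(spec, 1))
  tab <- extract_signatures(st)
  tis <- tab$label %in% c("normal", "PTG", "OSSN")
  pca <- fit_pca(signature_matrix(tab[tis, ], "ch_"), k = 3)
  rgb <- render_pca_falsecolor(st, pca, table = tab)
  expect_true(all(rgb >= 0 & rgb <= 1))
  # identical signatures map to identical colors; endpoints hit 0/1
  sc <- pca_scores(pca, signature_matrix(tab, "ch_"))
  expect_equal(range((sc[, 1] - min(sc[, 1])) / diff(range(sc[, 1]))),
               c(0, 1))
  sector_rgb <- t(vapply(seq_len(nrow(tab)), function(k)
    rgb[tab$r0[k], tab$c0[k], ], numeric(3)))
  ossn <- sector_rgb[tab$label == "OSSN", , drop = FALSE]
  norm <- sector_rgb[tab$label == "normal", , drop = FALSE]
  between <- mean(sqrt(rowSums((ossn - colMeans(norm)[col(ossn)])^2)))
  within <- mean(sqrt(rowSums(sweep(norm, 2, colMeans(norm))^2)))
  expect_gt(between, within)
  p2 <- fit_pca(signature_matrix(tab[tis, ], "ch_"), k = 2)
  expect_error(render_pca_falsecolor(st, p2, table = tab),
               class = "afmi_pca_too_few_components")
})
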