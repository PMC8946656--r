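test_that("sector grid arithmetic matches the stated drop policy", {
  big <- make_stack(array(0, c(1024, 1024, 1)))
  expect_identical(nrow(tile_sectors(big)), 4096L) # 64 x 64 grid
  one <- make_stack(array(0, c(16, 16, 1)))
  expect_identical(nrow(tile_sectors(one)), 1L)
  partial <- make_stack(array(0, c(20, 20, 1)))
  expect_identical(nrow(tile_sectors(partial)), 1L)
  expect_error(tile_sectors(make_stack(array(0, c(8, 8, 1)))),
               class = "afmi_image_too_small")
})

test_that("sector labels: majority, purity, mixed and outside rules", {
  mask <- matrix(0L, 32, 16)
  mask[1:16, ] <- 1L                   # sector 1: pure normal
  mask[17:32, ] <- 2L
  mask[17:22, ] <- 3L                  # sector 2: 10/16 PTG, 6/16 OSSN
  st <- make_stack(array(0, c(32, 16, 1)), mask)
  g <- tile_sectors(st)
  expect_identical(g$label, c("normal", "mixed"))
  expect_identical(g$majority, c("normal", "PTG"))
  expect_equal(g$purity, c(1, 10 / 16), tolerance = 1e-12)
  # below 50% tissue -> outside
  mask2 <- matrix(0L, 16, 16); mask2[1:7, ] <- 1L
  g2 <- tile_sectors(make_stack(array(0, c(16, 16, 1)), mask2))
  expect_identical(g2$label, "outside")
})

test_that("signatures are per-sector channel means", {
  # channelwise-constant sectors return the constants
  arr <- array(0, c(16, 32, 3))
  for (ch in 1:3) arr[, , ch] <- ch * 10
  tab <- extract_signatures(make_stack(arr))
  expect_equal(unname(as.matrix(tab[, c("ch_1", "ch_2", "ch_3")])),
               matrix(rep(c(10, 20, 30), each = 2), 2), tolerance = 0)
  # 2x2 test-mode sector: mean of {1,2,3,6} is 3 by direct sum/4
  arr2 <- array(c(1, 2, 3, 6), c(2, 2, 1))
  tab2 <- extract_signatures(make_stack(arr2), sector_px = 2)
  expect_identical(tab2$ch_1, sum(c(1, 2, 3, 6)) / 4)
  # full channel dimension
  spec <- noise_free_spec(image_shape = c(48, 48))
  tab3 <- extract_signatures(generate_patient(spec, 1))
  expect_identical(sum(grepl("^ch_", names(tab3))), 59L)
  bad <- make_stack(array(NaN, c(16, 16, 1)))
  expect_error(extract_signatures(bad), class = "afmi_nan_pixels")
})

test_that("relative signatures implement (SS - Med) / Std exactly", {
  set.seed(10)
  n_ch <- 4
  normal <- matrix(rnorm(11 * n_ch, 100, 10), 11)
  med <- apply(normal, 2, median)
  std <- apply(normal, 2, function(v) sqrt(mean((v - mean(v))^2))) # ddof 0
  probe <- rbind(med,                 # rss must be 0
                 med + std,           # rss must be 1
                 c(10, 4, 50, 50))
  sig <- rbind(normal, probe)
  tab <- make_sig_table(sig, c(rep("normal", 11), rep("PTG", 3)))
  rel <- relative_signatures(tab, min_normal = 10)
  rss <- signature_matrix(rel$table, "rss_")
  expect_equal(unname(rss[12, ]), rep(0, n_ch), tolerance = 1e-12)
  expect_equal(unname(rss[13, ]), rep(1, n_ch), tolerance = 1e-12)
  expect_equal(unname(rss[14, ]), (probe[3, ] - med) / std,
               tolerance = 1e-12, ignore_attr = TRUE)
  ref <- rel$references[["P001"]]
  expect_equal(ref$med, med, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ref$std, std, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(ref$n_normal_sectors, 11L)
  # worked example: signature [10,4], med [4,4], std [2,1] -> rss [3,0]
  expect_equal(unname((c(10, 4) - c(4, 4)) / c(2, 1)), c(3, 0))
})

test_that("median of normal-sector rss is exactly zero (odd counts)", {
  sig <- matrix(rnorm(11 * 3, 80, 9), 11)
  rel0 <- relative_signatures(make_sig_table(sig, rep("normal", 11)),
                              min_normal = 10)
  rss0 <- signature_matrix(rel0$table, "rss_")
  expect_equal(unname(apply(rss0, 2, median)), rep(0, 3), tolerance = 1e-12)

  spec <- small_spec(n_patients = 2, seed = 9)
  tab <- cohort_signature_table(spec)
  rel <- relative_signatures(tab)
  for (pid in names(rel$references)) {
    rows <- rel$table$patient_id == pid & rel$table$label == "normal"
    rss <- signature_matrix(rel$table[rows, ], "rss_")
    if (nrow(rss) %% 2 == 1)
      expect_equal(unname(apply(rss, 2, median)), rep(0, ncol(rss)),
                   tolerance = 1e-12)
  }
})

test_that("rss is invariant to per-patient per-channel affine transforms", {
  spec <- small_spec(n_patients = 1, seed = 3)
  st <- generate_patient(spec, 1)
  st$truth <- NULL
  tab <- extract_signatures(st)
  rel <- relative_signatures(tab)

  set.seed(21)
  a <- runif(59, 0.5, 2); b <- runif(59, -20, 50)
  st2 <- st
  for (ch in 1:59) st2$stack[, , ch] <- a[ch] * st$stack[, , ch] + b[ch]
  rel2 <- relative_signatures(extract_signatures(st2))
  expect_equal(signature_matrix(rel2$table, "rss_"),
               signature_matrix(rel$table, "rss_"), tolerance = 1e-9)
})

test_that("patients without enough normal sectors are excluded with a log", {
  sig <- matrix(rnorm(8, 100, 5), 4, 2)
  tab <- rbind(make_sig_table(sig, rep("normal", 4), "A"),
               make_sig_table(sig + 5, rep("normal", 4), "B"))
  expect_error(relative_signatures(tab, min_normal = 10),
               class = "afmi_too_few_normal")
  tab2 <- rbind(make_sig_table(matrix(rnorm(22, 100, 5), 11, 2),
                               rep("normal", 11), "A"),
                make_sig_table(sig, rep("normal", 4), "B"))
  expect_warning(rel <- relative_signatures(tab2, min_normal = 10),
                 "excluded")
  expect_identical(rel$excluded, "B")
})

test_that("normal reference round-trips through JSON", {
  spec <- small_spec(n_patients = 1, seed = 5)
  rel <- relative_signatures(cohort_signature_table(spec))
  ref <- rel$references[[1]]
  p <- withr::local_tempfile(fileext = ".json")
  write_normal_reference(ref, p)
  rt <- read_normal_reference(p)
  expect_equal(rt$med, ref$med, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rt$std, ref$std, tolerance = 1e-12, ignore_attr = TRUE)
})
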