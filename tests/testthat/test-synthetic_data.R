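test_that("cohorts are bit-identical under a fixed seed", {
  spec <- small_spec(n_patients = 2, image_shape = c(64, 64), seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # and patient generation is order-independent
  expect_identical(generate_patient(spec, 2), a[[2]])
})

test_that("noise-free limit reproduces the class spectra exactly", {
  spec <- noise_free_spec()
  st <- generate_patient(spec, 1)
  for (cls in 1:3) {
    pix <- which(st$mask == cls, arr.ind = TRUE)[1:20, ]
    for (ch in c(1, 3, 12, 30, 52, 59))
      expect_equal(unname(st$stack[cbind(pix, ch)]),
                   rep(unname(spec$class_spectra[ch, cls]), nrow(pix)),
                   tolerance = 0, ignore_attr = TRUE)
  }
  expect_true(all(st$stack[rep(st$mask == 0L, dim(st$stack)[3])] == 0))
})

test_that("apply_degradations: identity case and dead-pixel bookkeeping", {
  spec0 <- noise_free_spec(image_shape = c(64, 64))
  st <- generate_patient(spec0, 1)
  again <- apply_degradations(st, spec0)
  expect_equal(again$stack, st$stack, tolerance = 0)

  spec_d <- noise_free_spec(image_shape = c(64, 64),
                            dead_pixel_fraction = 0.01)
  std <- generate_patient(spec_d, 1)
  expect_identical(nrow(std$truth$dead_pixels),
                   as.integer(round(0.01 * 64 * 64)))
  # dead pixels are zero in every channel
  for (k in seq_len(nrow(std$truth$dead_pixels)))
    expect_true(all(std$stack[std$truth$dead_pixels[k, 1],
                              std$truth$dead_pixels[k, 2], ] == 0))
})

test_that("vignette field follows the analytic radial profile", {
  spec <- noise_free_spec(image_shape = c(64, 64), vignette_strength = 0.5)
  # flat 1000-count input through the degradation model
  st <- generate_patient(spec, 1)
  flat <- st
  flat$stack <- array(1000, dim(st$stack))
  flat$mask <- matrix(1L, 64, 64)
  flat$truth <- list(gain = rep(1, 59), offset = rep(0, 59))
  deg <- apply_degradations(flat, spec)
  v <- vignette_field(c(64, 64), 0.5)
  expect_equal(deg$stack[, , 1], 1000 * v, tolerance = 1e-12)
  # corner/center ratio equals the falloff profile at the corner radius
  ctr <- deg$stack[32, 32, 1] / 1000
  expect_equal(deg$stack[1, 1, 1] / 1000, v[1, 1], tolerance = 1e-12)
  expect_equal(v[1, 1] / max(v), 1 - 0.5, tolerance = 0.02)
  expect_gt(ctr, 0.99)
})

test_that("Poisson degradation preserves the clean class mean", {
  spec <- phantom_spec(n_patients = 1, image_shape = c(256, 256),
                      patient_scale_sd = 0, patient_offset_sd = 0,
                      texture_sd = 0, vignette_strength = 0,
                      background_level = 0, dead_pixel_fraction = 0,
                      saturated_pixel_fraction = 0, poisson = TRUE, seed = 11)
  st <- generate_patient(spec, 1)
  for (cls in 1:3) {
    sel <- st$mask == cls
    expect_gt(sum(sel), 1e4)
    for (ch in c(3, 12, 30)) {
      mu <- spec$class_spectra[ch, cls]
      se <- sqrt(mu / sum(sel))
      expect_lt(abs(mean(st$stack[, , ch][sel]) - mu), 3 * se)
    }
  }
})

test_that("patient effect is affine given the recorded texture field", {
  spec <- small_spec(n_patients = 1, seed = 2)
  st <- generate_patient(spec, 1)
  tr <- st$truth
  for (ch in c(3, 30)) {
    recon <- (tr$clean[, , ch] - ifelse(st$mask > 0L, tr$offset[ch], 0)) /
      tr$gain[ch]
    tissue <- st$mask > 0L
    expect_equal(recon[tissue] / tr$texture[tissue],
                 spec$class_spectra[ch, st$mask[tissue]],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # with texture off the spec's literal affine invariant holds
  spec0 <- small_spec(n_patients = 1, texture_sd = 0, seed = 2)
  st0 <- generate_patient(spec0, 1)
  tis0 <- st0$mask > 0L
  recon0 <- (st0$truth$clean[, , 3][tis0] - st0$truth$offset[3]) /
    st0$truth$gain[3]
  expect_equal(recon0, spec0$class_spectra[3, st0$mask[tis0]],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fluorophore-channel class ordering holds in generated data", {
  spec <- small_spec(n_patients = 1, seed = 4)
  st <- generate_patient(spec, 1)
  cm <- function(ch, cls) mean(st$stack[, , ch][st$mask == cls])
  # elastin channel: normal > PTG > OSSN
  expect_gt(cm(3, 1), cm(3, 2)); expect_gt(cm(3, 2), cm(3, 3))
  # lipopigment: OSSN elevated, normal ~ PTG
  expect_gt(cm(12, 3), cm(12, 1))
  expect_lt(abs(cm(12, 1) - cm(12, 2)) / cm(12, 1), 0.1)
  # flavins / PPIX: OSSN reduced, normal ~ PTG
  for (ch in c(30, 52)) {
    expect_lt(cm(ch, 3), cm(ch, 2))
    expect_lt(abs(cm(ch, 1) - cm(ch, 2)) / cm(ch, 1), 0.1)
  }
})

test_that("degenerate specs are rejected", {
  expect_error(phantom_spec(n_patients = 0), class = "afmi_degenerate_spec")
  expect_error(phantom_spec(image_shape = c(16, 16)),
               class = "afmi_degenerate_spec")
  expect_error(phantom_spec(dead_pixel_fraction = 1),
               class = "afmi_degenerate_spec")
  sp <- default_class_spectra(); sp[1, 1] <- -1
  expect_error(phantom_spec(class_spectra = sp),
               class = "afmi_degenerate_spec")
})

test_that("stack text serialization round-trips", {
  spec <- noise_free_spec(image_shape = c(48, 48))
  st <- generate_patient(spec, 1)
  p <- withr::local_tempfile(fileext = ".txt")
  write_stack(st, p)
  rt <- read_stack(p)
  expect_equal(rt$stack, st$stack, tolerance = 1e-10)
  expect_identical(rt$patient_id, st$patient_id)
  pm <- withr::local_tempfile(fileext = ".csv")
  write_mask(st$mask, pm)
  expect_identical(unname(read_mask(pm)), unname(st$mask))
})
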