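# Small phantom specs shared across test files. Generator parameters are the
# package defaults (the stated synthetic world); only spatial size / cohort
# size are reduced to keep the suite fast.

small_spec <- function(n_patients = 2, image_shape = c(128, 128), seed = 1,
                       ...) {
  phantom_spec(n_patients = n_patients, image_shape = image_shape,
               seed = seed, ...)
}

# all stochastic/degradation knobs off: pixels equal the class spectra
noise_free_spec <- function(n_patients = 1, image_shape = c(128, 128),
                            seed = 1, ...) {
  args <- list(n_patients = n_patients, image_shape = image_shape,
               patient_scale_sd = 0, patient_offset_sd = 0, texture_sd = 0,
               vignette_strength = 0, background_level = 0,
               dead_pixel_fraction = 0, saturated_pixel_fraction = 0,
               poisson = FALSE, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# a bare stack object without going through the generator
make_stack <- function(arr, mask = NULL, patient_id = "T001") {
  if (is.null(mask)) mask <- matrix(1L, dim(arr)[1], dim(arr)[2])
  structure(list(patient_id = patient_id, stack = arr, mask = mask,
                 channel_table = NULL, truth = NULL),
            class = "afmi_patient_stack")
}

# build a signature table by hand (patients x sectors x channels)
make_sig_table <- function(sig, label, patient_id = "P001") {
  n <- nrow(sig)
  colnames(sig) <- paste0("ch_", seq_len(ncol(sig)))
  cbind(data.frame(patient_id = patient_id, sector_row = seq_len(n) - 1L,
                   sector_col = 0L, r0 = 1L, r1 = 17L, c0 = 1L, c1 = 17L,
                   label = label, majority = label, purity = 1,
                   stringsAsFactors = FALSE),
        as.data.frame(sig))
}
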