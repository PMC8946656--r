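#' Synthetic multispectral tissue phantoms
#'
#' Generates cohorts of 59-channel image stacks emulating autofluorescence
#' microscopy of ocular surface biopsies containing contiguous normal,
#' pterygium (PTG) and ocular surface squamous neoplasia (OSSN) regions.
#' Class spectra are nonnegative mixtures of smooth fluorophore basis curves
#' (elastin, lipopigment, flavins, PPIX, plus a broad background term); the
#' mixture weights encode the class contrasts seen in tissue: the elastin
#' channel decreases normal > PTG > OSSN, the lipopigment channel is elevated
#' in OSSN only, and the flavins and PPIX channels are reduced in OSSN only.
#' Patient-level variability is a per-patient, per-channel affine effect
#' (log-normal gain, additive offset) -- exactly the confounder the
#' relative-signature normalization removes. Camera degradations follow the
#' acquisition physics: radial illumination falloff, additive background
#' fluorescence, dead and saturated sensor pixels, and Poisson photon noise.
#'
#' @name synthetic_data
NULL

# truncated Gaussian bump over channel index; hard zero beyond 2.5 sd so
# fluorophore-specific contrasts stay confined to their channel neighborhood
chan_bump <- function(idx, center, sd = 3, trunc = 2.5) {
  v <- exp(-(idx - center)^2 / (2 * sd^2))
  v[abs(idx - center) > trunc * sd] <- 0
  v
}

#' Fluorophore basis spectra over channel index
#' @param n_ch number of channels
#' @return matrix `n_ch x 5`, columns elastin, lipopigment, flavins, PPIX,
#'   background; each column peaks at 1
#' @export
fluorophore_basis <- function(n_ch = 59) {
  idx <- seq_len(n_ch)
  cbind(elastin = chan_bump(idx, 3),
        lipopigment = chan_bump(idx, 12),
        flavins = chan_bump(idx, 30),
        PPIX = chan_bump(idx, 52),
        background = exp(-(idx - 30)^2 / (2 * 30^2)))
}

#' Default class emission spectra (photon counts)
#'
#' Mixture weights x 800 counts peak intensity. Normal and PTG differ only in
#' elastin; OSSN additionally gains lipopigment and loses flavins and PPIX.
#' @param channel_table channel scheme (defaults to the bundled 59 channels)
#' @return matrix `n_ch x 3` with columns normal, PTG, OSSN
#' @export
default_class_spectra <- function(channel_table = default_channel_table()) {
  basis <- fluorophore_basis(channel_table$n_channels)
  w <- cbind(normal = c(1.00, 0.55, 1.00, 0.85, 0.35),
             PTG    = c(0.68, 0.55, 1.00, 0.85, 0.35),
             OSSN   = c(0.40, 0.95, 0.55, 0.45, 0.35))
  800 * (basis %*% w)
}

#' Phantom cohort specification
#'
#' Defaults are the package's stated synthetic world; see the methods
#' vignette for the rationale behind each value.
#'
#' @param n_patients cohort size (default 20)
#' @param image_shape `c(rows, cols)` in pixels (default 512 x 512)
#' @param channel_table channel scheme
#' @param class_spectra `n_ch x 3` nonnegative matrix (normal, PTG, OSSN)
#' @param patient_scale_sd sd of per-patient per-channel log-normal gain
#'   (log units, default 0.25)
#' @param patient_offset_sd sd of per-patient per-channel additive offset,
#'   as a fraction of the mean class signal (default 0.10)
#' @param texture_sd sd (log units) of the smooth multiplicative biological
#'   texture field shared across channels (default 0.15)
#' @param texture_scale_px correlation length of the texture field
#' @param vignette_strength radial illumination falloff amplitude in `[0,1]`
#' @param background_level additive background fluorescence (counts)
#' @param dead_pixel_fraction,saturated_pixel_fraction sensor defect rates
#' @param poisson apply Poisson photon noise?
#' @param saturation_value full-well value (default 65535, 16-bit)
#' @param layout `"bands"` (three vertical bands normal|PTG|OSSN) or
#'   `"blobs"` (irregular PTG/OSSN blobs in a normal field)
#' @param tissue_margin_px width of the outside-tissue border
#' @param seed integer RNG seed
#' @return an `afmi_phantom_spec` list
#' @export
phantom_spec <- function(n_patients = 20, image_shape = c(512, 512),
                         channel_table = default_channel_table(),
                         class_spectra = default_class_spectra(channel_table),
                         patient_scale_sd = 0.25, patient_offset_sd = 0.10,
                         texture_sd = 0.15, texture_scale_px = 32,
                         vignette_strength = 0.3, background_level = 20,
                         dead_pixel_fraction = 0.001,
                         saturated_pixel_fraction = 0.0005,
                         poisson = TRUE, saturation_value = 65535,
                         layout = c("bands", "blobs"),
                         tissue_margin_px = 16, seed = 1) {
  layout <- match.arg(layout)
  spec <- list(n_patients = as.integer(n_patients),
               image_shape = as.integer(image_shape),
               channel_table = channel_table, class_spectra = class_spectra,
               patient_scale_sd = patient_scale_sd,
               patient_offset_sd = patient_offset_sd,
               texture_sd = texture_sd, texture_scale_px = texture_scale_px,
               vignette_strength = vignette_strength,
               background_level = background_level,
               dead_pixel_fraction = dead_pixel_fraction,
               saturated_pixel_fraction = saturated_pixel_fraction,
               poisson = poisson, saturation_value = saturation_value,
               layout = layout, tissue_margin_px = as.integer(tissue_margin_px),
               seed = as.integer(seed))
  class(spec) <- "afmi_phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$n_patients < 1)
    afmi_stop("afmi_degenerate_spec", "n_patients must be >= 1")
  if (any(spec$image_shape < 48))
    afmi_stop("afmi_degenerate_spec",
              "image_shape too small for three tissue classes")
  if (any(spec$class_spectra < 0))
    afmi_stop("afmi_degenerate_spec", "class_spectra must be nonnegative")
  if (ncol(spec$class_spectra) != 3)
    afmi_stop("afmi_degenerate_spec",
              "class_spectra needs the 3 columns normal, PTG, OSSN")
  if (nrow(spec$class_spectra) != spec$channel_table$n_channels)
    afmi_stop("afmi_degenerate_spec", "class_spectra rows != n_channels")
  frac_ok <- function(x) x >= 0 && x < 1
  if (!frac_ok(spec$dead_pixel_fraction) ||
      !frac_ok(spec$saturated_pixel_fraction) ||
      spec$vignette_strength < 0 || spec$vignette_strength > 1)
    afmi_stop("afmi_degenerate_spec", "fraction parameter out of range")
  invisible(spec)
}

#' @export
print.afmi_phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<afmi_phantom_spec> %d patients, %dx%d px, %d ",
                     "channels, layout '%s', seed %d\n"),
              x$n_patients, x$image_shape[1], x$image_shape[2],
              x$channel_table$n_channels, x$layout, x$seed))
  invisible(x)
}

# tissue label mask: 0 outside, 1 normal, 2 PTG, 3 OSSN
phantom_mask <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  m <- spec$tissue_margin_px
  mask <- matrix(0L, nr, nc)
  rin <- (m + 1):(nr - m); cin <- (m + 1):(nc - m)
  if (spec$layout == "bands") {
    w <- length(cin)
    b1 <- floor(w / 3); b2 <- floor(2 * w / 3)
    mask[rin, cin[seq_len(b1)]] <- 1L
    mask[rin, cin[(b1 + 1):b2]] <- 2L
    mask[rin, cin[(b2 + 1):w]] <- 3L
  } else {
    mask[rin, cin] <- 1L
    rg <- row(mask); cg <- col(mask)
    inside <- mask == 1L
    e1 <- ((rg - nr * 0.45) / (nr * 0.28))^2 +
      ((cg - nc * 0.40) / (nc * 0.22))^2 <= 1
    e2 <- ((rg - nr * 0.58) / (nr * 0.20))^2 +
      ((cg - nc * 0.72) / (nc * 0.18))^2 <= 1
    mask[inside & e1] <- 2L
    mask[inside & e2] <- 3L   # OSSN blob overlays PTG where they intersect
  }
  mask
}

# smooth multiplicative texture: bilinear upsampling of a coarse iid normal
# grid, exponentiated; correlation length ~ texture_scale_px
texture_field <- function(shape, sd_log, scale_px) {
  if (sd_log <= 0) return(matrix(1, shape[1], shape[2]))
  gr <- ceiling(shape[1] / scale_px) + 1L
  gc <- ceiling(shape[2] / scale_px) + 1L
  coarse <- matrix(rnorm(gr * gc, 0, sd_log), gr, gc)
  ri <- (seq_len(shape[1]) - 1) / scale_px
  ci <- (seq_len(shape[2]) - 1) / scale_px
  r0 <- pmin(floor(ri), gr - 2); c0 <- pmin(floor(ci), gc - 2)
  fr <- ri - r0; fc <- ci - c0
  a <- coarse[cbind(rep(r0 + 1, length(c0)), rep(c0 + 1, each = length(r0)))]
  b <- coarse[cbind(rep(r0 + 2, length(c0)), rep(c0 + 1, each = length(r0)))]
  cc <- coarse[cbind(rep(r0 + 1, length(c0)), rep(c0 + 2, each = length(r0)))]
  d <- coarse[cbind(rep(r0 + 2, length(c0)), rep(c0 + 2, each = length(r0)))]
  wfr <- rep(fr, length(c0)); wfc <- rep(fc, each = length(r0))
  z <- (1 - wfr) * (1 - wfc) * a + wfr * (1 - wfc) * b +
    (1 - wfr) * wfc * cc + wfr * wfc * d
  exp(matrix(z, shape[1], shape[2]))
}

#' Radial illumination (vignette) field
#'
#' `V(r) = 1 - strength * (d / d_corner)^2` with `d` the distance from the
#' image center; value 1 at the center, `1 - strength` at the corners.
#' @param shape `c(rows, cols)`
#' @param strength falloff amplitude in `[0,1]`
#' @return matrix of the same shape
#' @export
vignette_field <- function(shape, strength) {
  nr <- shape[1]; nc <- shape[2]
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  d2 <- outer((seq_len(nr) - rc)^2, (seq_len(nc) - cc)^2, `+`)
  1 - strength * d2 / max(d2)
}

# smooth random curve over channel index: K spline knots, unit marginal sd.
# Patient-level gain/offset drift is spectrally smooth in real instruments
# (lamp aging, filter transmission, section thickness); smoothness is what
# makes it a genuine confounder for inter-patient classification while
# remaining exactly per-channel affine (so the relative-signature
# normalization removes it).
smooth_channel_curve <- function(n_ch, knots = 7L) {
  kx <- seq(1, n_ch, length.out = knots)
  stats::spline(kx, rnorm(knots), xout = seq_len(n_ch))$y
}

new_patient_stack <- function(patient_id, stack, mask, channel_table,
                              truth = NULL) {
  structure(list(patient_id = patient_id, stack = stack, mask = mask,
                 channel_table = channel_table, truth = truth),
            class = "afmi_patient_stack")
}

#' @export
print.afmi_patient_stack <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<afmi_patient_stack> %s: %dx%d px, %d channels%s\n",
              x$patient_id, d[1], d[2], d[3],
              if (is.null(x$truth)) "" else ", truth attached"))
  invisible(x)
}

# noise-free class image + texture, before patient affine effects
ideal_stack <- function(spec, mask, texture) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  n_ch <- spec$channel_table$n_channels
  stack <- array(0, dim = c(nr, nc, n_ch))
  tissue <- mask > 0L
  cls <- mask[tissue]
  tex <- texture[tissue]
  for (ch in seq_len(n_ch)) {
    plane <- matrix(0, nr, nc)
    plane[tissue] <- spec$class_spectra[ch, cls] * tex
    stack[, , ch] <- plane
  }
  stack
}

#' Generate one phantom patient
#'
#' Reproducible independently of cohort order: the patient's RNG stream is
#' derived from `spec$seed` and the patient index.
#' @param spec an `afmi_phantom_spec`
#' @param i patient index in `1..n_patients`
#' @return an `afmi_patient_stack` with `truth` populated
#' @export
generate_patient <- function(spec, i) {
  validate_phantom_spec(spec)
  set.seed(derive_seed(spec$seed, sprintf("patient%04d", i)))
  n_ch <- spec$channel_table$n_channels
  mask <- phantom_mask(spec)
  texture <- texture_field(spec$image_shape, spec$texture_sd,
                           spec$texture_scale_px)
  gain <- exp(spec$patient_scale_sd * smooth_channel_curve(n_ch))
  offset <- spec$patient_offset_sd * mean(spec$class_spectra) *
    smooth_channel_curve(n_ch)
  clean <- ideal_stack(spec, mask, texture)
  st <- new_patient_stack(sprintf("P%03d", i), clean, mask,
                          spec$channel_table,
                          truth = list(gain = gain, offset = offset,
                                       texture = texture))
  apply_degradations(st, spec)
}

#' Generate a phantom cohort
#' @param spec an `afmi_phantom_spec`
#' @return list of `afmi_patient_stack`
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  lapply(seq_len(spec$n_patients), function(i) generate_patient(spec, i))
}

#' Apply acquisition degradations to a clean stack
#'
#' `degraded = Poisson(vignette * (gain * clean + offset) + background)`,
#' then dead pixels forced to 0 and saturated pixels to the full-well value.
#' The patient affine effect (gain, offset) is applied to tissue pixels;
#' outside-tissue pixels carry only background and noise. Every injected
#' artifact is recorded in `truth`.
#'
#' @param clean an `afmi_patient_stack` whose `truth` holds `gain`, `offset`
#'   (per channel) and the biological `texture` field
#' @param spec the `afmi_phantom_spec` holding degradation settings
#' @return degraded `afmi_patient_stack`; `truth$clean` is the noise-free
#'   patient stack (affine effects applied, no optics/camera artifacts)
#' @export
apply_degradations <- function(clean, spec) {
  validate_phantom_spec(spec)
  truth <- clean$truth
  if (is.null(truth$gain))
    afmi_stop("afmi_truth_missing", "clean stack must carry truth gain/offset")
  dims <- dim(clean$stack)
  nr <- dims[1]; nc <- dims[2]; n_ch <- dims[3]
  tissue <- clean$mask > 0L
  vig <- vignette_field(c(nr, nc), spec$vignette_strength)

  npix <- nr * nc
  n_dead <- round(spec$dead_pixel_fraction * npix)
  n_sat <- round(spec$saturated_pixel_fraction * npix)
  defect <- if (n_dead + n_sat > 0) sample.int(npix, n_dead + n_sat) else integer(0)
  dead_idx <- defect[seq_len(n_dead)]
  sat_idx <- defect[n_dead + seq_len(n_sat)]

  clean_affine <- array(0, dims)
  out <- array(0, dims)
  for (ch in seq_len(n_ch)) {
    plane <- clean$stack[, , ch] * truth$gain[ch]
    plane[tissue] <- plane[tissue] + truth$offset[ch]
    plane[plane < 0] <- 0
    clean_affine[, , ch] <- plane
    lam <- vig * plane + spec$background_level
    deg <- if (spec$poisson) {
      matrix(rpois(npix, pmax(lam, 0)), nr, nc)
    } else lam
    deg[dead_idx] <- 0
    deg[sat_idx] <- spec$saturation_value
    out[, , ch] <- deg
  }
  idx2rc <- function(idx) cbind(row = ((idx - 1L) %% nr) + 1L,
                                col = ((idx - 1L) %/% nr) + 1L)
  truth$clean <- clean_affine
  truth$vignette <- vig
  truth$dead_pixels <- idx2rc(dead_idx)
  truth$sat_pixels <- idx2rc(sat_idx)
  truth$background_level <- spec$background_level
  new_patient_stack(clean$patient_id, out, clean$mask, clean$channel_table,
                    truth = truth)
}
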