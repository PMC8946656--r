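#' Image preprocessing
#'
#' Minimizes the acquisition degradations before signature extraction:
#' dead/saturated pixel repair (median of the 8 neighbors), per-channel
#' background subtraction, flat-field (illumination curvature) correction,
#' and translation-only tile stitching by phase correlation. Poisson noise is
#' deliberately not filtered by default: the 256-pixel sector averaging in
#' the signatures stage is the variance-reduction step. An optional
#' variance-stabilizing route (Anscombe transform + Gaussian smoothing) is
#' available behind a flag.
#'
#' @name preprocessing
NULL

#' Preprocessing configuration
#'
#' @param background_mode `"constant_from_dark_region"` (median of the
#'   outside-tissue region, per channel), `"percentile"` (configurable
#'   percentile of the outside-tissue region, falling back to the whole
#'   frame when no mask is available) or `"none"` (e.g. for flat
#'   calibration frames)
#' @param background_percentile percentile in `(0, 50]` (default 5)
#' @param flatfield_mode `"radial_fit"` (default: centered radial falloff,
#'   log-linear in squared radius -- one amplitude parameter, so tissue
#'   structure cannot be absorbed into the field), `"polynomial_fit"`
#'   (degree-`poly_degree` surface on the log image; appropriate for
#'   near-uniform scenes such as flat calibration fields),
#'   `"provided_field"` or `"none"`
#' @param poly_degree polynomial surface degree (1..4, default 2)
#' @param badpixel_detect `"zeros_and_saturated"` or `"mad_outlier"`
#' @param mad_k MAD multiplier for outlier detection (default 8)
#' @param saturation_value full-well value (default 65535)
#' @param anscombe apply Anscombe transform + Gaussian smoothing?
#' @param smooth_sigma Gaussian sigma (pixels) for the Anscombe route
#' @return an `afmi_preprocess_config`
#' @export
preprocess_config <- function(background_mode = c("percentile",
                                                  "constant_from_dark_region",
                                                  "none"),
                              background_percentile = 5,
                              flatfield_mode = c("radial_fit",
                                                 "polynomial_fit",
                                                 "provided_field", "none"),
                              poly_degree = 2,
                              badpixel_detect = c("zeros_and_saturated",
                                                  "mad_outlier"),
                              mad_k = 8, saturation_value = 65535,
                              anscombe = FALSE, smooth_sigma = 1) {
  if (background_percentile <= 0 || background_percentile > 50)
    afmi_stop("afmi_bad_config", "background_percentile must be in (0, 50]")
  if (poly_degree < 1 || poly_degree > 4)
    afmi_stop("afmi_bad_config", "poly_degree must be in 1..4")
  structure(list(background_mode = match.arg(background_mode),
                 background_percentile = background_percentile,
                 flatfield_mode = match.arg(flatfield_mode),
                 poly_degree = as.integer(poly_degree),
                 badpixel_detect = match.arg(badpixel_detect),
                 mad_k = mad_k, saturation_value = saturation_value,
                 anscombe = anscombe, smooth_sigma = smooth_sigma),
            class = "afmi_preprocess_config")
}

median8 <- function(plane, rows, cols, exclude) {
  nr <- nrow(plane); nc <- ncol(plane)
  vapply(seq_along(rows), function(k) {
    rr <- max(1, rows[k] - 1):min(nr, rows[k] + 1)
    cc <- max(1, cols[k] - 1):min(nc, cols[k] + 1)
    nb <- plane[rr, cc]
    keep <- !exclude[rr, cc]
    keep[which(rr == rows[k]), which(cc == cols[k])] <- FALSE
    v <- nb[keep]
    if (!length(v)) return(plane[rows[k], cols[k]])
    median(v)
  }, numeric(1))
}

#' Repair dead and saturated camera pixels
#'
#' Flags pixels at 0 (dead), at/above the full-well value (saturated), or --
#' in `mad_outlier` mode -- further than `mad_k` MADs from the channel
#' median, and replaces each by the median of its available 8 neighbors.
#'
#' @param stack an `afmi_patient_stack`
#' @param cfg an `afmi_preprocess_config`
#' @return list with the repaired `stack` and a `report` data frame
#'   (channel, row, col, kind)
#' @export
repair_bad_pixels <- function(stack, cfg = preprocess_config()) {
  d <- dim(stack$stack)
  out <- stack$stack
  reports <- list()
  for (ch in seq_len(d[3])) {
    plane <- out[, , ch]
    dead <- plane == 0
    sat <- plane >= cfg$saturation_value
    kind <- NULL
    flag <- dead | sat
    if (cfg$badpixel_detect == "mad_outlier") {
      m <- median(plane); s <- mad(plane)
      if (s > 0) flag <- flag | abs(plane - m) > cfg$mad_k * s
    }
    n_flag <- sum(flag)
    if (n_flag > 0.2 * d[1] * d[2])
      afmi_stop("afmi_corrupted_channel",
                "channel %d: %.0f%% of pixels flagged; input looks corrupted",
                ch, 100 * n_flag / (d[1] * d[2]))
    if (n_flag) {
      idx <- which(flag, arr.ind = TRUE)
      kind <- ifelse(dead[flag], "dead",
                     ifelse(sat[flag], "saturated", "outlier"))
      plane[flag] <- median8(plane, idx[, 1], idx[, 2], flag)
      out[, , ch] <- plane
      reports[[length(reports) + 1L]] <-
        data.frame(channel = ch, row = idx[, 1], col = idx[, 2],
                   kind = kind, stringsAsFactors = FALSE)
    }
  }
  report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(channel = integer(), row = integer(), col = integer(),
               kind = character(), stringsAsFactors = FALSE)
  stack$stack <- out
  list(stack = stack, report = report)
}

# block means of a matrix over a coarse grid (for fast, smoothed poly fits)
block_means <- function(plane, block = 16L) {
  nr <- nrow(plane); nc <- ncol(plane)
  br <- nr %/% block; bc <- nc %/% block
  sub <- plane[seq_len(br * block), seq_len(bc * block), drop = FALSE]
  a <- matrix(colMeans(matrix(sub, nrow = block)), nrow = br, ncol = bc * block)
  res <- matrix(colMeans(matrix(t(a), nrow = block)), nrow = bc, ncol = br)
  list(means = t(res),
       row_centers = (seq_len(br) - 0.5) * block,
       col_centers = (seq_len(bc) - 0.5) * block)
}

# centered radial vignette model: log I ~ scene + b * u with
# u = (d/d_max)^2 and b <= 0. Tissue structure is absorbed by a
# block-column nuisance factor, so b is identified from the *within-column*
# radial variation; because exp(b*u) is separable in row/column, the full
# 2-D field is then reconstructed from b alone. Fitted on tissue blocks
# only: the dark outside-tissue border mimics vignetting.
fit_radial_field <- function(plane, mask = NULL) {
  blk <- max(8L, nrow(plane) %/% 32L)
  bm <- block_means(plane, block = blk)
  z <- log(pmax(as.vector(bm$means), 1e-6))
  rc <- (nrow(plane) + 1) / 2; cc <- (ncol(plane) + 1) / 2
  d2 <- outer((bm$row_centers - rc)^2, (bm$col_centers - cc)^2, `+`)
  d2max <- (nrow(plane) / 2 - 0.5)^2 + (ncol(plane) / 2 - 0.5)^2
  u <- as.vector(d2) / d2max
  colf <- factor(rep(seq_along(bm$col_centers),
                     each = length(bm$row_centers)))
  keep <- rep(TRUE, length(z))
  if (!is.null(mask) && any(mask > 0L)) {
    tis <- as.vector(block_means((mask > 0L) * 1, block = blk)$means) >= 0.5
    if (sum(tis) >= 10) keep <- tis
  }
  df <- data.frame(z = z[keep], u = u[keep], colf = droplevels(colf[keep]))
  b <- if (nlevels(df$colf) > 1 && nrow(df) > nlevels(df$colf) + 1) {
    fit <- lm(z ~ colf + u, data = df)
    co <- coef(fit)[["u"]]
    if (is.na(co)) 0 else min(0, co)
  } else min(0, cov(df$u, df$z) / max(var(df$u), 1e-12))
  ufull <- outer((seq_len(nrow(plane)) - rc)^2,
                 (seq_len(ncol(plane)) - cc)^2, `+`) / d2max
  field <- exp(b * ufull)
  field / max(field)
}

fit_illumination_field <- function(plane, degree) {
  bm <- block_means(plane, block = max(8L, nrow(plane) %/% 32L))
  z <- log(pmax(bm$means, 1e-6))
  r <- rep(bm$row_centers, times = length(bm$col_centers)) / nrow(plane)
  cc <- rep(bm$col_centers, each = length(bm$row_centers)) / ncol(plane)
  df <- data.frame(z = as.vector(z), r = r, c = cc)
  fit <- lm(z ~ poly(r, degree, raw = TRUE) + poly(c, degree, raw = TRUE) +
              I(r * c), data = df)
  rg <- seq_len(nrow(plane)) / nrow(plane)
  cg <- seq_len(ncol(plane)) / ncol(plane)
  newdata <- data.frame(r = rep(rg, times = length(cg)),
                        c = rep(cg, each = length(rg)))
  field <- exp(matrix(predict(fit, newdata), nrow(plane), ncol(plane)))
  field / max(field)
}

#' Background and illumination-curvature correction
#'
#' Per channel: subtracts the estimated constant background (clamped at 0),
#' then divides by a peak-one illumination field -- either a provided field
#' or a low-order polynomial surface fitted to the log of the block-smoothed
#' image. The peak-one normalization makes a provided ground-truth vignette
#' an exact inverse.
#'
#' @param stack an `afmi_patient_stack`
#' @param cfg an `afmi_preprocess_config`
#' @param field illumination field matrix for `flatfield_mode =
#'   "provided_field"`
#' @return corrected `afmi_patient_stack`
#' @export
correct_field <- function(stack, cfg = preprocess_config(), field = NULL) {
  d <- dim(stack$stack)
  outside <- stack$mask == 0L
  use_outside <- any(outside)
  if (cfg$flatfield_mode == "provided_field") {
    if (is.null(field))
      afmi_stop("afmi_bad_config", "provided_field mode needs a field")
    if (any(field <= 0))
      afmi_stop("afmi_bad_field", "illumination field must be positive")
    # used as given: a ground-truth field is then an exact inverse
  }
  out <- stack$stack
  for (ch in seq_len(d[3])) {
    plane <- out[, , ch]
    b <- if (cfg$background_mode == "none") {
      0
    } else if (cfg$background_mode == "constant_from_dark_region") {
      if (!use_outside)
        afmi_stop("afmi_no_dark_region",
                  "constant_from_dark_region needs outside-tissue pixels")
      median(plane[outside])
    } else if (use_outside) {
      quantile(plane[outside], cfg$background_percentile / 100, names = FALSE)
    } else {
      quantile(plane, 0.01, names = FALSE)
    }
    plane <- pmax(plane - b, 0)
    if (cfg$flatfield_mode == "radial_fit") {
      f <- fit_radial_field(plane, stack$mask)
      plane <- plane / f
    } else if (cfg$flatfield_mode == "polynomial_fit") {
      f <- fit_illumination_field(plane + b, cfg$poly_degree)
      if (any(f <= 0))
        afmi_stop("afmi_bad_field", "fitted illumination field non-positive")
      plane <- plane / f
    } else if (cfg$flatfield_mode == "provided_field") {
      plane <- plane / field
    }
    out[, , ch] <- plane
  }
  stack$stack <- out
  stack
}

gaussian_smooth <- function(plane, sigma) {
  if (sigma <= 0) return(plane)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_apply <- function(m) {
    n <- nrow(m)
    mp <- m[c(rep(1, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1) + seq_len(n), ,
                                                   drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(plane))))
}

#' Full per-stack preprocessing chain
#'
#' Order: bad-pixel repair, then background subtraction, then flat-field
#' correction (then the optional Anscombe route).
#' @inheritParams correct_field
#' @return corrected `afmi_patient_stack`, with the bad-pixel report in
#'   `$preprocess_report`
#' @export
preprocess_stack <- function(stack, cfg = preprocess_config(), field = NULL) {
  rep0 <- repair_bad_pixels(stack, cfg)
  out <- correct_field(rep0$stack, cfg, field = field)
  if (cfg$anscombe) {
    for (ch in seq_len(dim(out$stack)[3])) {
      a <- 2 * sqrt(out$stack[, , ch] + 3 / 8)
      a <- gaussian_smooth(a, cfg$smooth_sigma)
      out$stack[, , ch] <- pmax((a / 2)^2 - 3 / 8, 0)
    }
  }
  out$preprocess_report <- rep0$report
  out
}

#' Phase correlation between two equal-size images
#'
#' Returns the integer translation `c(dr, dc)` such that shifting `b` by
#' `(dr, dc)` (content moving down/right for positive values) best aligns it
#' with `a`.
#' @param a,b numeric matrices of identical size
#' @return integer vector `c(dr, dc)`
#' @export
phase_correlate <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  fa <- fft(a); fb <- fft(b)
  cross <- fa * Conj(fb)
  denom <- Mod(cross); denom[denom < 1e-12] <- 1e-12
  r <- Re(fft(cross / denom, inverse = TRUE)) / length(a)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) { s <- i - 1L; if (s > n / 2) s - n else s }
  unname(c(wrap(pk[1], nrow(a)), wrap(pk[2], ncol(a))))
}

#' Stitch image tiles into one stack
#'
#' Translation-only registration: each tile is phase-correlated against the
#' already-composed mosaic over its nominal overlap window on one reference
#' channel; overlapping pixels are blended by linear feathering.
#'
#' @param tiles list of `list(stack = afmi_patient_stack, origin = c(r, c))`
#'   with 1-based nominal origins on the output canvas
#' @param overlap_px nominal overlap (>= 8 when more than one tile)
#' @param ref_channel channel used for registration
#' @return an `afmi_patient_stack` covering the union of tile footprints
#' @export
stitch_tiles <- function(tiles, overlap_px = 32L, ref_channel = 1L) {
  if (!length(tiles)) afmi_stop("afmi_no_tiles", "no tiles to stitch")
  if (length(tiles) == 1L) return(tiles[[1]]$stack)
  if (overlap_px < 8) afmi_stop("afmi_bad_config", "overlap_px must be >= 8")
  n_ch <- dim(tiles[[1]]$stack$stack)[3]
  dims <- vapply(tiles, function(t) dim(t$stack$stack)[1:2], integer(2))
  orig <- vapply(tiles, function(t) as.integer(t$origin), integer(2))
  canvas_dim <- c(max(orig[1, ] + dims[1, ] - 1L) + overlap_px,
                  max(orig[2, ] + dims[2, ] - 1L) + overlap_px)
  acc <- array(0, c(canvas_dim, n_ch))
  wacc <- matrix(0, canvas_dim[1], canvas_dim[2])
  mask <- matrix(0L, canvas_dim[1], canvas_dim[2])
  used <- matrix(0L, 2, length(tiles)) # corrected origins

  feather <- function(nr, nc) {
    wr <- pmin(seq_len(nr), nr + 1 - seq_len(nr), overlap_px) / overlap_px
    wc <- pmin(seq_len(nc), nc + 1 - seq_len(nc), overlap_px) / overlap_px
    outer(wr, wc, pmin)
  }

  place <- function(k, origin) {
    st <- tiles[[k]]$stack
    nr <- dims[1, k]; nc <- dims[2, k]
    rr <- origin[1]:(origin[1] + nr - 1L)
    cc <- origin[2]:(origin[2] + nc - 1L)
    w <- feather(nr, nc)
    for (ch in seq_len(n_ch))
      acc[rr, cc, ch] <<- acc[rr, cc, ch] + w * st$stack[, , ch]
    wacc[rr, cc] <<- wacc[rr, cc] + w
    mpatch <- mask[rr, cc]
    mpatch[st$mask > 0L] <- st$mask[st$mask > 0L]
    mask[rr, cc] <<- mpatch
    used[, k] <<- origin
  }

  place(1L, orig[, 1])
  for (k in 2:length(tiles)) {
    o <- orig[, k]
    nr <- dims[1, k]; nc <- dims[2, k]
    rr <- o[1]:(o[1] + nr - 1L); cc <- o[2]:(o[2] + nc - 1L)
    covered <- wacc[rr, cc] > 0
    shift <- c(0L, 0L)
    if (sum(covered) >= 64) {
      # crop both to the covered bounding box: zero-masking would imprint an
      # identical mask edge on both images and pin the correlation peak at 0
      br <- range(which(rowSums(covered) > 0))
      bc <- range(which(colSums(covered) > 0))
      ref <- acc[rr, cc, ref_channel][br[1]:br[2], bc[1]:bc[2]]
      wref <- wacc[rr, cc][br[1]:br[2], bc[1]:bc[2]]
      ref <- ref / pmax(wref, 1e-12)
      tl <- tiles[[k]]$stack$stack[br[1]:br[2], bc[1]:bc[2], ref_channel]
      shift <- phase_correlate(ref - mean(ref), tl - mean(tl))
      if (max(abs(shift)) > 2L * overlap_px)
        afmi_stop("afmi_registration_failed",
                  "estimated shift (%d, %d) exceeds 2x nominal overlap",
                  shift[1], shift[2])
    }
    place(k, pmax(o + shift, 1L))
  }

  keep_r <- which(rowSums(wacc) > 0)
  keep_c <- which(colSums(wacc) > 0)
  out <- array(0, c(length(keep_r), length(keep_c), n_ch))
  wsub <- wacc[keep_r, keep_c]
  wsub[wsub == 0] <- 1
  for (ch in seq_len(n_ch))
    out[, , ch] <- acc[keep_r, keep_c, ch] / wsub
  new_patient_stack(tiles[[1]]$stack$patient_id, out,
                    mask[keep_r, keep_c], tiles[[1]]$stack$channel_table)
}
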