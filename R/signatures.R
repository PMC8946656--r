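#' Sector spectral signatures and per-patient normalization
#'
#' Images are divided into non-overlapping 16 x 16 pixel sectors anchored at
#' the image origin (partial edge sectors dropped). Each sector's spectral
#' signature SS is the vector of per-channel mean intensities over its 256
#' pixels. The fused-framework normalization converts SS to a relative
#' spectral signature
#'   RSS = (SS - Med) / Std    (elementwise, per channel)
#' where Med and Std are the per-channel median and (population) standard
#' deviation of the *same patient's normal-tissue* sector signatures. RSS is
#' invariant to any per-patient, per-channel affine intensity transform,
#' which is precisely the inter-patient confounder the framework removes.
#'
#' @name signatures
NULL

#' Tile a stack into a sector grid
#'
#' Sectors are labeled by pixel majority over the tissue mask: sectors with
#' fewer than 50% tissue pixels are `outside`; tissue sectors whose majority
#' class holds less than `mixed_threshold` of the tissue pixels are labeled
#' `mixed` (kept for mapping, excluded from training); the raw majority
#' class is always available in `majority`.
#'
#' @param stack an `afmi_patient_stack`
#' @param sector_px sector side in pixels (default 16)
#' @param mixed_threshold purity below which a tissue sector is `mixed`
#' @return data frame with sector_row/sector_col (0-based), pixel bbox
#'   (half-open, `r0:r1`/`c0:c1` with 1-based `r0`), label, majority, purity
#' @export
tile_sectors <- function(stack, sector_px = 16L, mixed_threshold = 0.8) {
  d <- dim(stack$stack)
  if (sector_px < 2 || d[1] < sector_px || d[2] < sector_px)
    afmi_stop("afmi_image_too_small",
              "image (%d x %d) smaller than one %d-px sector",
              d[1], d[2], sector_px)
  nsr <- d[1] %/% sector_px; nsc <- d[2] %/% sector_px
  sr <- rep(seq_len(nsr) - 1L, times = nsc)
  sc <- rep(seq_len(nsc) - 1L, each = nsr)
  r0 <- sr * sector_px + 1L; c0 <- sc * sector_px + 1L
  n <- length(sr)
  label <- character(n); majority <- character(n); purity <- numeric(n)
  classes <- afmi_classes()
  for (k in seq_len(n)) {
    sub <- stack$mask[r0[k]:(r0[k] + sector_px - 1L),
                      c0[k]:(c0[k] + sector_px - 1L)]
    tis <- sub[sub > 0L]
    if (length(tis) < 0.5 * sector_px^2) {
      label[k] <- "outside"; majority[k] <- "outside"; purity[k] <- 0
    } else {
      counts <- tabulate(tis, nbins = 3L)
      best <- which.max(counts)
      purity[k] <- counts[best] / length(tis)
      majority[k] <- classes[best]
      label[k] <- if (purity[k] < mixed_threshold) "mixed" else classes[best]
    }
  }
  data.frame(patient_id = stack$patient_id, sector_row = sr, sector_col = sc,
             r0 = r0, r1 = r0 + sector_px, c0 = c0, c1 = c0 + sector_px,
             label = label, majority = majority, purity = purity,
             stringsAsFactors = FALSE)
}

#' Extract per-sector spectral signatures
#'
#' `signature[ch]` is the arithmetic mean of the sector's pixels in channel
#' `ch`; the result is appended to the grid as columns `ch_1..ch_N`.
#'
#' @param stack an `afmi_patient_stack` (preprocessed)
#' @param grid sector grid from [tile_sectors()] (defaults to tiling now)
#' @param sector_px sector side used when `grid` is `NULL`
#' @return signature table (grid columns + `ch_*` columns)
#' @export
extract_signatures <- function(stack, grid = NULL, sector_px = 16L) {
  if (is.null(grid)) grid <- tile_sectors(stack, sector_px)
  sp <- grid$r1[1] - grid$r0[1]
  d <- dim(stack$stack)
  if (anyNA(stack$stack))
    afmi_stop("afmi_nan_pixels", "stack contains NaN/NA pixels")
  nsr <- d[1] %/% sp; nsc <- d[2] %/% sp
  n_ch <- d[3]
  sig <- matrix(0, nrow = nsr * nsc, ncol = n_ch)
  for (ch in seq_len(n_ch)) {
    bm <- block_means(stack$stack[, , ch], block = sp)
    sig[, ch] <- as.vector(bm$means) # column-major, matches tile_sectors
  }
  colnames(sig) <- paste0("ch_", seq_len(n_ch))
  stopifnot(nrow(sig) == nrow(grid))
  cbind(grid, as.data.frame(sig))
}

#' Extract the `ch_*` (or `rss_*`) columns of a signature table as a matrix
#' @param table signature table
#' @param prefix `"ch_"` for raw signatures, `"rss_"` for relative ones
#' @return numeric matrix, channels in index order
#' @export
signature_matrix <- function(table, prefix = "ch_") {
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(table), value = TRUE)
  cols <- cols[order(as.integer(sub(prefix, "", cols, fixed = TRUE)))]
  if (!length(cols))
    afmi_stop("afmi_no_signature_columns", "no '%s' columns found", prefix)
  as.matrix(table[, cols, drop = FALSE])
}

#' Per-patient normal reference and relative signatures
#'
#' Computes each patient's normal reference (per-channel median `med` and
#' population standard deviation `std` over that patient's pure normal
#' sectors) and the relative signature `rss = (ss - med) / std` for *all* of
#' the patient's tissue sectors. Channels whose `std` falls below
#' `1e-6 * median(med)` are floored at that epsilon and flagged.
#'
#' @param table signature table (possibly multiple patients)
#' @param min_normal minimum number of pure normal sectors per patient
#' @return list with `table` (input rows for retained patients + `rss_*`
#'   columns), `references` (per-patient list: med, std, n_normal_sectors,
#'   flagged_channels) and `excluded` (patient ids dropped, with a message)
#' @export
relative_signatures <- function(table, min_normal = 10L) {
  sig <- signature_matrix(table, "ch_")
  n_ch <- ncol(sig)
  refs <- list()
  excluded <- character(0)
  keep_rows <- list()
  for (pid in unique(table$patient_id)) {
    rows <- which(table$patient_id == pid)
    normal <- rows[table$label[rows] == "normal"]
    if (length(normal) < min_normal) {
      excluded <- c(excluded, pid)
      next
    }
    med <- apply(sig[normal, , drop = FALSE], 2, median)
    mu <- colMeans(sig[normal, , drop = FALSE])
    std <- sqrt(colMeans(sweep(sig[normal, , drop = FALSE], 2, mu)^2))
    eps <- 1e-6 * median(med)
    flagged <- which(std < eps)
    std[flagged] <- eps
    rss <- sweep(sweep(sig[rows, , drop = FALSE], 2, med), 2, std, "/")
    refs[[pid]] <- list(patient_id = pid, med = med, std = std,
                        n_normal_sectors = length(normal),
                        flagged_channels = flagged)
    block <- table[rows, , drop = FALSE]
    colnames(rss) <- paste0("rss_", seq_len(n_ch))
    keep_rows[[pid]] <- cbind(block, as.data.frame(rss))
  }
  if (!length(keep_rows))
    afmi_stop("afmi_too_few_normal",
              "no patient has >= %d pure normal sectors", min_normal)
  if (length(excluded))
    warning(sprintf("excluded patient(s) with < %d normal sectors: %s",
                    min_normal, paste(excluded, collapse = ", ")))
  out <- do.call(rbind, keep_rows)
  rownames(out) <- NULL
  list(table = out, references = refs, excluded = excluded)
}

#' Write / read a per-patient normal reference as JSON
#' @param ref reference entry from [relative_signatures()]
#' @param path JSON path
#' @export
write_normal_reference <- function(ref, path) {
  jsonlite::write_json(ref, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normal_reference
#' @export
read_normal_reference <- function(path) {
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref$med <- as.numeric(ref$med); ref$std <- as.numeric(ref$std)
  ref
}

#' Generate, preprocess and tabulate a whole phantom cohort
#'
#' Streams patients one at a time (generate, preprocess, extract sector
#' signatures, discard pixels) so memory stays flat in cohort size.
#'
#' @param spec an `afmi_phantom_spec`
#' @param cfg preprocessing config; `NULL` skips preprocessing
#' @param sector_px sector side
#' @return signature table for the whole cohort
#' @export
cohort_signature_table <- function(spec, cfg = preprocess_config(),
                                   sector_px = 16L) {
  parts <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    st <- generate_patient(spec, i)
    st$truth <- NULL
    if (!is.null(cfg)) st <- preprocess_stack(st, cfg)
    parts[[i]] <- extract_signatures(st, sector_px = sector_px)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
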