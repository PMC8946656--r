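#' Spectral channel scheme
#'
#' The imaging system records tissue autofluorescence in 59 narrow spectral
#' channels, each defined by an excitation center (+/- halfwidth, nominally
#' +/-5 nm) and an emission band. A handful of channels are tentatively
#' attributed to dominant endogenous fluorophores: channel 3 to elastin,
#' channel 12 to lipopigment (lipofuscin), channel 30 to flavins and channel
#' 52 to protoporphyrin IX (PPIX). The exact wavelengths are metadata: all
#' downstream computation indexes channels only by identity and count.
#'
#' @name channel_model
NULL

valid_hints <- c("elastin", "lipopigment", "flavins", "PPIX", "NADH",
                 "other", "none")

new_channel_table <- function(df) {
  structure(list(channels = df, n_channels = nrow(df)),
            class = "afmi_channel_table")
}

#' @export
print.afmi_channel_table <- function(x, ...) {
  hinted <- x$channels[x$channels$fluorophore_hint != "none", , drop = FALSE]
  cat(sprintf("<afmi_channel_table> %d channels, excitation %.0f-%.0f nm\n",
              x$n_channels, min(x$channels$ex_center_nm),
              max(x$channels$ex_center_nm)))
  if (nrow(hinted))
    cat("  fluorophore hints:",
        paste(sprintf("%d=%s", hinted$index, hinted$fluorophore_hint),
              collapse = ", "), "\n")
  invisible(x)
}

validate_channel_table <- function(df, strict = TRUE) {
  fail <- function(class, msg, ...) afmi_stop(class, msg, ...)
  num_cols <- c("index", "ex_center_nm", "ex_halfwidth_nm",
                "em_low_nm", "em_high_nm")
  missing <- setdiff(num_cols, names(df))
  if (length(missing))
    fail("afmi_channel_missing_column", "missing column(s): %s",
         paste(missing, collapse = ", "))
  for (cc in num_cols)
    if (!is.numeric(df[[cc]]))
      fail("afmi_channel_nonnumeric", "column '%s' is not numeric", cc)
  if (anyDuplicated(df$index))
    fail("afmi_channel_duplicate_index", "duplicate channel index: %s",
         paste(unique(df$index[duplicated(df$index)]), collapse = ", "))
  if (strict) {
    if (any(df$em_low_nm >= df$em_high_nm))
      fail("afmi_channel_band_reversed",
           "emission band reversed (em_low >= em_high) at index %s",
           paste(df$index[df$em_low_nm >= df$em_high_nm], collapse = ", "))
    if (any(df$ex_center_nm <= 0))
      fail("afmi_channel_bad_excitation", "nonpositive excitation center")
    if (!identical(sort(as.integer(df$index)), seq_len(nrow(df))))
      fail("afmi_channel_index_gap",
           "channel indices must be 1..n with no gaps")
  }
  if (is.null(df$fluorophore_hint)) df$fluorophore_hint <- "none"
  df$fluorophore_hint[is.na(df$fluorophore_hint) |
                        df$fluorophore_hint == ""] <- "none"
  bad <- setdiff(unique(df$fluorophore_hint), valid_hints)
  if (length(bad))
    fail("afmi_channel_bad_hint", "unknown fluorophore hint(s): %s",
         paste(bad, collapse = ", "))
  df <- df[order(df$index), c(num_cols, "fluorophore_hint")]
  rownames(df) <- NULL
  df
}

#' Load a spectral channel table from CSV
#'
#' @param path CSV with header columns `index, ex_center_nm, ex_halfwidth_nm,
#'   em_low_nm, em_high_nm` and optional `fluorophore_hint`.
#' @param strict abort on any invariant violation (default `TRUE`).
#' @return an `afmi_channel_table`
#' @export
load_channel_table <- function(path, strict = TRUE) {
  if (!file.exists(path))
    afmi_stop("afmi_channel_file_missing", "channel table not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  new_channel_table(validate_channel_table(df, strict = strict))
}

#' Write a channel table to CSV (round-trips with [load_channel_table()])
#' @param table an `afmi_channel_table`
#' @param path output CSV path
#' @export
write_channel_table <- function(table, path) {
  stopifnot(inherits(table, "afmi_channel_table"))
  write.csv(table$channels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled 59-channel scheme
#'
#' Five epifluorescence filter-cube groups with excitation centers between
#' 340 and 450 nm (halfwidth 5 nm) and emission windows tiling 400-700 nm.
#' Wavelengths are synthesized plausibly; fluorophore hints mark channels
#' 3 (elastin), 12 (lipopigment), 30 (flavins) and 52 (PPIX).
#'
#' @return an `afmi_channel_table` with 59 channels
#' @export
default_channel_table <- function() {
  path <- system.file("extdata", "channels_default.csv", package = "afmi")
  if (!nzchar(path)) path <- file.path("inst", "extdata",
                                       "channels_default.csv")
  load_channel_table(path)
}

# Constructs the bundled table (used once to write inst/extdata, kept so the
# provenance of the synthesized wavelengths is in code).
build_default_channel_df <- function() {
  ex_centers <- c(340, 365, 390, 420, 450) # five filter cubes
  per_cube <- c(12L, 12L, 12L, 12L, 11L)   # 59 channels total
  rows <- list()
  idx <- 1L
  for (g in seq_along(ex_centers)) {
    ex <- ex_centers[g]
    em_start <- ex + 40
    width <- 30
    step <- (700 - width - em_start) / (per_cube[g] - 1)
    for (j in seq_len(per_cube[g])) {
      lo <- round(em_start + (j - 1) * step)
      rows[[idx]] <- data.frame(index = idx, ex_center_nm = ex,
                                ex_halfwidth_nm = 5, em_low_nm = lo,
                                em_high_nm = lo + width,
                                fluorophore_hint = "none",
                                stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  df <- do.call(rbind, rows)
  df$fluorophore_hint[df$index == 3] <- "elastin"
  df$fluorophore_hint[df$index == 12] <- "lipopigment"
  df$fluorophore_hint[df$index == 30] <- "flavins"
  df$fluorophore_hint[df$index == 52] <- "PPIX"
  df
}
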