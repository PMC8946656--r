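#' Plain-text stack serialization
#'
#' Multichannel stacks are stored in a simple whitespace text format (header
#' line `afmi_stack 1 <rows> <cols> <channels> <patient_id>`, then the stack
#' values in column-major order, one channel after another). Masks are plain
#' CSV integer matrices. The format is intended for small exchange files and
#' fixtures; large cohorts are generated in memory.
#'
#' @name stack_io
NULL

#' @rdname stack_io
#' @param stack an `afmi_patient_stack`
#' @param path output file
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "afmi_patient_stack"))
  d <- dim(stack$stack)
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("afmi_stack 1 %d %d %d %s\n", d[1], d[2], d[3],
              stack$patient_id), file = con)
  write(sprintf("%.17g", as.vector(stack$stack)), file = con, ncolumns = 8)
  invisible(path)
}

#' @rdname stack_io
#' @param channel_table channel scheme to attach on read
#' @export
read_stack <- function(path, channel_table = NULL) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- strsplit(readLines(con, 1), " ")[[1]]
  if (length(hdr) < 6 || hdr[1] != "afmi_stack")
    afmi_stop("afmi_bad_stack_file", "not an afmi_stack file: %s", path)
  d <- as.integer(hdr[3:5])
  vals <- scan(con, what = double(), n = prod(d), quiet = TRUE)
  new_patient_stack(hdr[6], array(vals, d),
                    matrix(0L, d[1], d[2]),
                    channel_table %||% default_channel_table())
}

#' @rdname stack_io
#' @param mask integer label matrix
#' @export
write_mask <- function(mask, path) {
  write.table(mask, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname stack_io
#' @export
read_mask <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}

#' Write an RGB image (values in `[0,1]`) as plain-text PPM (P3)
#' @param rgb array `rows x cols x 3`
#' @param path output `.ppm` path
#' @export
write_ppm <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  q <- round(pmin(pmax(rgb, 0), 1) * 255)
  nr <- dim(q)[1]; nc <- dim(q)[2]
  # PPM is row-major, pixels left-to-right, rows top-to-bottom
  px <- matrix(NA_integer_, 3 * nc, nr)
  for (k in 1:3) px[seq(k, by = 3, length.out = nc), ] <- t(q[, , k])
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("P3\n%d %d\n255\n", nc, nr), file = con)
  write(as.integer(px), file = con, ncolumns = 12)
  invisible(path)
}
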