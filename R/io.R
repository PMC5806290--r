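# Reading and writing planes, masks and maps (NIfTI via RNifti, or a long
# CSV dialect for plain-text interchange).

#' Write / read a multi-echo series
#'
#' NIfTI output stores the plane as an `rows x cols x 1 x E` volume with the
#' echo dimension fourth, readable by any NIfTI-aware tool; echo times go
#' into a sidecar `<file>.te.txt` (one TE in ms per line). CSV output is a
#' long table `row, col, echo_index, te_ms, signal`.
#'
#' @param x an [echo_series()].
#' @param file output path; format chosen by extension (`.nii`/`.nii.gz`
#'   vs `.csv`).
#' @return `write_echo_series()` returns `file` invisibly;
#'   `read_echo_series()` returns an [echo_series()].
#' @export
write_echo_series <- function(x, file) {
  stopifnot(inherits(x, "echo_series"))
  if (grepl("\\.csv$", file)) {
    d <- dim(x$signal)
    df <- data.frame(
      row = rep(seq_len(d[1]), times = d[2] * d[3]),
      col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      echo_index = rep(seq_len(d[3]), each = d[1] * d[2]),
      te_ms = rep(x$te_ms, each = d[1] * d[2]),
      signal = as.vector(x$signal)
    )
    write.csv(df, file, row.names = FALSE)
  } else {
    d <- dim(x$signal)
    RNifti::writeNifti(array(x$signal, c(d[1], d[2], 1L, d[3])), file)
    writeLines(format(x$te_ms, digits = 10), paste0(file, ".te.txt"))
  }
  invisible(file)
}

#' @rdname write_echo_series
#' @param te_ms echo times; required for CSV-less NIfTI input only when the
#'   sidecar `<file>.te.txt` is absent.
#' @export
read_echo_series <- function(file, te_ms = NULL) {
  if (grepl("\\.csv$", file)) {
    df <- read.csv(file)
    rows <- max(df$row); cols <- max(df$col); E <- max(df$echo_index)
    sig <- array(NA_real_, c(rows, cols, E))
    sig[cbind(df$row, df$col, df$echo_index)] <- df$signal
    te <- vapply(seq_len(E), function(e) df$te_ms[df$echo_index == e][1], 0)
    return(echo_series(sig, te))
  }
  img <- RNifti::readNifti(file)
  d <- dim(img)
  sidecar <- paste0(file, ".te.txt")
  if (is.null(te_ms) && file.exists(sidecar)) {
    te_ms <- as.numeric(readLines(sidecar))
  }
  if (is.null(te_ms)) stop("echo times not found; pass `te_ms`", call. = FALSE)
  echo_series(array(as.vector(img), c(d[1], d[2], d[4])), te_ms)
}

#' Write / read an ROI mask or an R2* map
#'
#' Masks are written as 0/1 volumes (NIfTI) or `row, col, value` CSV; maps
#' likewise with R2* in s^-1 and `NA` encoded as empty CSV cells or 0 with
#' an accompanying validity volume for NIfTI.
#'
#' @param x logical matrix (mask) or `r2star_map`.
#' @param file output path (`.nii`/`.nii.gz` or `.csv`).
#' @return the path, invisibly (writers); a logical matrix or numeric matrix
#'   (readers).
#' @export
write_roi_mask <- function(x, file) {
  stopifnot(is.logical(x), is.matrix(x))
  if (grepl("\\.csv$", file)) {
    df <- data.frame(row = rep(seq_len(nrow(x)), ncol(x)),
                     col = rep(seq_len(ncol(x)), each = nrow(x)),
                     value = as.integer(as.vector(x)))
    write.csv(df, file, row.names = FALSE)
  } else {
    RNifti::writeNifti(array(as.integer(x), c(dim(x), 1L)), file)
  }
  invisible(file)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(file) {
  if (grepl("\\.csv$", file)) {
    df <- read.csv(file)
    m <- matrix(FALSE, max(df$row), max(df$col))
    m[cbind(df$row, df$col)] <- df$value > 0
    return(m)
  }
  img <- RNifti::readNifti(file)
  matrix(as.vector(img) > 0, dim(img)[1], dim(img)[2])
}

#' @rdname write_roi_mask
#' @export
write_r2star_map <- function(x, file) {
  stopifnot(inherits(x, "r2star_map"))
  if (grepl("\\.csv$", file)) {
    df <- data.frame(row = rep(seq_len(nrow(x$values)), ncol(x$values)),
                     col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
                     r2star = as.vector(ifelse(x$valid, x$values, NA_real_)))
    write.csv(df, file, row.names = FALSE)
  } else {
    v <- ifelse(x$valid, x$values, 0)
    RNifti::writeNifti(array(v, c(dim(v), 1L)), file)
  }
  invisible(file)
}
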