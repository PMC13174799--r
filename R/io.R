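#' @title Plain-text volume and table I/O
#' @description The package stores volumes in a simple self-describing text
#'   format (no binary image library is assumed): a three-line header
#'   giving format, dims `(nz ny nx)` and spacing in um, followed by the
#'   values in column-major order. Metrics tables are CSV written at full
#'   double precision so read-write-read round trips are lossless.
#' @name text_io
NULL

#' @rdname text_io
#' @param x a [voxel_grid] or [label_volume].
#' @param path output file.
#' @export
write_volume_tsv <- function(x, path) {
  is_lab <- inherits(x, "label_volume")
  if (!is_lab && !inherits(x, "voxel_grid"))
    stop("`x` must be a voxel_grid or label_volume", call. = FALSE)
  vals <- if (is_lab) x$labels else x$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# mitomorph-volume v1 type=", if (is_lab) "labels" else "intensity"),
    paste0("# dims: ", paste(dim(vals), collapse = " ")),
    paste0("# spacing: ", paste(sprintf("%.17g", x$spacing), collapse = " "))
  ), con)
  fmt <- if (is_lab) "%d" else "%.17g"
  writeLines(paste(sprintf(fmt, as.vector(vals)), collapse = " "), con)
  invisible(path)
}

#' @rdname text_io
#' @return `read_volume_tsv()` returns a [voxel_grid] or [label_volume]
#'   according to the file's type header.
#' @export
read_volume_tsv <- function(path) {
  lines <- readLines(path, n = 3L)
  if (!grepl("^# mitomorph-volume v1", lines[1]))
    stop("not a mitomorph-volume file: ", path, call. = FALSE)
  type <- sub(".*type=", "", lines[1])
  dims <- as.integer(strsplit(sub("# dims: ", "", lines[2]), " ")[[1]])
  spacing <- as.numeric(strsplit(sub("# spacing: ", "", lines[3]), " ")[[1]])
  vals <- scan(path, skip = 3L, quiet = TRUE)
  arr <- array(vals, dim = dims)
  if (type == "labels") label_volume(arr, spacing)
  else voxel_grid(arr, spacing)
}

#' @rdname text_io
#' @param df data.frame of metrics.
#' @export
write_metrics_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname text_io
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname text_io
#' @param m numeric or integer matrix (2D image / mask / label image).
#' @export
write_image_csv <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE, sep = ",")
  invisible(path)
}

#' @rdname text_io
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
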