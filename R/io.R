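#' Read / write multichannel time series as TSV
#'
#' Canonical tabular interchange: a header row of channel names, one row
#' per timepoint, tab-separated. Round-trips are lossless to at least 12
#' significant digits.
#'
#' @param path file path.
#' @param tr_seconds sampling interval recorded on the returned matrix.
#' @return `read_timeseries_tsv`: a `T x N` matrix with attribute
#'   `sampling_interval`.
#' @export
read_timeseries_tsv <- function(path, tr_seconds = 2) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(sprintf("non-numeric values in %s", path))
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in %s at row %d, column '%s'",
                 path, bad[1L], colnames(m)[bad[2L]]))
  }
  attr(m, "sampling_interval") <- tr_seconds
  m
}

#' @rdname read_timeseries_tsv
#' @param ts `T x N` matrix.
#' @export
write_timeseries_tsv <- function(ts, path) {
  df <- as.data.frame(ts)
  if (is.null(colnames(ts)))
    colnames(df) <- paste0("X", seq_len(ncol(ts)))
  out <- vapply(df, function(x) sprintf("%.12g", x), character(nrow(df)))
  utils::write.table(rbind(colnames(df), out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

DIRECTION_COMMENT <- "# direction: value[target_row, source_column] = source -> target"

#' Read / write a directed edge matrix as TSV
#'
#' `N x N` matrices with labelled rows and columns and a leading comment
#' line stating the direction convention (source = column, target = row).
#' A file without the comment is read with that convention assumed, with a
#' warning.
#'
#' @param path file path.
#' @return `read_edge_tsv`: the edge matrix.
#' @export
read_edge_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_comment <- startsWith(first, "#")
  if (!has_comment)
    warning("edge TSV lacks a direction comment; assuming source = column, target = row")
  df <- utils::read.delim(path, skip = as.integer(has_comment),
                          row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_edge_tsv
#' @param edges `N x N` matrix with dimnames.
#' @export
write_edge_tsv <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(DIRECTION_COMMENT, con)
  writeLines(paste(c("node", colnames(edges)), collapse = "\t"), con)
  for (i in seq_len(nrow(edges)))
    writeLines(paste(c(rownames(edges)[i], sprintf("%.12g", edges[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write an edge-test result as TSV
#'
#' @param result an `edge_test_result` data.frame.
#' @param path file path.
#' @export
write_edge_test_tsv <- function(result, path) {
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a 4D voxel image (or 3D map) as NIfTI
#'
#' Thin wrappers over the RNifti package. Only needed when exchanging
#' synthetic voxel data with external neuroimaging tools; the pipeline
#' itself passes images in memory.
#'
#' @param img a `voxel_image` (`T x V` matrix with `dims`) or a numeric 3D
#'   array.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_nifti_4d <- function(img, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI output")
  dims <- attr(img, "dims")
  arr <- array(t(unclass(img)), c(dims, nrow(img)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_nifti_4d
#' @export
read_nifti_4d <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI input")
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  if (length(d) != 4L) stop("expected a 4D NIfTI image")
  img <- t(matrix(arr, prod(d[1:3]), d[4L]))
  attr(img, "dims") <- d[1:3]
  class(img) <- c("voxel_image", class(img))
  img
}
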