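# Minimal uncompressed Zarr-v2 directory store.
#
# The pipeline's chunked-array container interface is a plain Zarr v2 group:
# one JSON ".zarray" per dataset plus raw C-order chunk files, no compressor.
# Only what the package needs is supported: 3D arrays, dtypes "|u1", "<i4"
# and "<f8", whole-array single chunks. Any conforming zarr reader (e.g. the
# Python zarr package) can open these stores.

zarr_dtype <- function(dtype) {
  switch(dtype,
    "|u1" = list(size = 1L, what = "integer", signed = FALSE),
    "<i4" = list(size = 4L, what = "integer", signed = TRUE),
    "<f8" = list(size = 8L, what = "double", signed = TRUE),
    stop("unsupported zarr dtype: ", dtype)
  )
}

write_zarr_array <- function(a, path, dtype) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(a)
  meta <- list(
    zarr_format = 2L,
    shape = as.integer(d),
    chunks = as.integer(d),
    dtype = dtype,
    compressor = NULL,
    fill_value = 0L,
    order = "C",
    filters = NULL
  )
  jsonlite::write_json(meta, file.path(path, ".zarray"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  info <- zarr_dtype(dtype)
  # R arrays are column-major (first axis fastest); C order wants the last
  # axis fastest, so write the axis-reversed permutation.
  v <- as.vector(aperm(a, rev(seq_along(d))))
  con <- file(file.path(path, paste(rep("0", length(d)), collapse = ".")), "wb")
  on.exit(close(con))
  if (info$what == "double") {
    writeBin(as.double(v), con, size = info$size, endian = "little")
  } else {
    writeBin(as.integer(v), con, size = info$size, endian = "little")
  }
  invisible(path)
}

read_zarr_array <- function(path) {
  meta <- jsonlite::read_json(file.path(path, ".zarray"), simplifyVector = TRUE)
  assert_that(is.null(meta$compressor), "only uncompressed zarr arrays supported")
  d <- as.integer(meta$shape)
  info <- zarr_dtype(meta$dtype)
  chunk <- file.path(path, paste(rep("0", length(d)), collapse = "."))
  con <- file(chunk, "rb")
  on.exit(close(con))
  n <- prod(d)
  v <- readBin(con, what = info$what, n = n, size = info$size,
               endian = "little", signed = if (info$size < 4) info$signed else TRUE)
  a <- array(v, dim = rev(d))
  aperm(a, rev(seq_along(d)))
}

#' Write a labeled volume as a Zarr v2 group
#'
#' Writes `raw`, `cell_labels` and `nucleus_labels` datasets (uncompressed
#' Zarr v2, C order, axis order z,y,x) plus voxel-size metadata in
#' `.zattrs`.
#'
#' @param volume a [labeled_volume()].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(zarr_format = 2L), file.path(path, ".zgroup"),
                       auto_unbox = TRUE)
  jsonlite::write_json(list(voxel_size_nm = volume$voxel_size_nm,
                            axis_order = c("z", "y", "x")),
                       file.path(path, ".zattrs"), digits = NA)
  write_zarr_array(volume$raw, file.path(path, "raw"), "|u1")
  write_zarr_array(volume$cell_labels, file.path(path, "cell_labels"), "<i4")
  write_zarr_array(volume$nucleus_labels, file.path(path, "nucleus_labels"), "<i4")
  invisible(path)
}

#' Read a labeled volume from a Zarr v2 group
#'
#' @param path directory written by [write_volume()].
#' @return A [labeled_volume()].
#' @export
read_volume <- function(path) {
  attrs <- jsonlite::read_json(file.path(path, ".zattrs"), simplifyVector = TRUE)
  labeled_volume(read_zarr_array(file.path(path, "raw")),
                 read_zarr_array(file.path(path, "cell_labels")),
                 read_zarr_array(file.path(path, "nucleus_labels")),
                 attrs$voxel_size_nm)
}
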