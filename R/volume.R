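#' Labeled intensity volume
#'
#' Container for a raw 3D intensity grid together with cell and nucleus label
#' grids and voxel-size metadata. All arrays use axis order `(z, y, x)` with
#' 1-based voxel indices; physical sizes are in nanometres per voxel, given in
#' the same `(z, y, x)` order. This is the universe object every extraction
#' stage reads.
#'
#' @param raw 3D integer array of intensities in `[0, 255]`.
#' @param cell_labels 3D non-negative integer array; 0 is background.
#' @param nucleus_labels 3D non-negative integer array; ids pair one-to-one
#'   with cell ids.
#' @param voxel_size_nm numeric length-3, nm per voxel along `(z, y, x)`.
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(raw, cell_labels, nucleus_labels, voxel_size_nm) {
  assert_that(length(dim(raw)) == 3, "raw must be a 3D array")
  assert_that(identical(dim(raw), dim(cell_labels)) &&
                identical(dim(raw), dim(nucleus_labels)),
              "raw and label grids must share dimensions")
  assert_that(length(voxel_size_nm) == 3 && all(voxel_size_nm > 0),
              "voxel_size_nm must be 3 positive reals")
  structure(list(raw = raw, cell_labels = cell_labels,
                 nucleus_labels = nucleus_labels,
                 voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$raw)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (z,y,x), %s nm/voxel\n",
              d[1], d[2], d[3], paste(x$voxel_size_nm, collapse = " x ")))
  cat(sprintf("  cells: %d, nuclei: %d\n",
              length(setdiff(unique(as.vector(x$cell_labels)), 0L)),
              length(setdiff(unique(as.vector(x$nucleus_labels)), 0L))))
  invisible(x)
}

#' Downsample a volume by local mean / label majority
#'
#' Downsamples the raw grid by block-wise local mean (anti-aliasing) and the
#' label grids by block-wise majority vote. `factors` must divide the grid
#' shape (the grid is cropped down to the nearest multiple otherwise).
#'
#' @param volume a [labeled_volume()].
#' @param factors integer length-3 downsampling factor per `(z, y, x)` axis.
#' @return A `labeled_volume` at the coarser resolution.
#' @export
downsample_volume <- function(volume, factors) {
  factors <- as.integer(factors)
  assert_that(length(factors) == 3 && all(factors >= 1), "factors must be 3 ints >= 1")
  if (all(factors == 1L)) return(volume)
  d <- dim(volume$raw)
  dn <- d %/% factors
  crop <- function(a) a[seq_len(dn[1] * factors[1]),
                        seq_len(dn[2] * factors[2]),
                        seq_len(dn[3] * factors[3]), drop = FALSE]
  raw <- block_reduce(crop(volume$raw), factors, mean)
  cl <- block_reduce_mode(crop(volume$cell_labels), factors)
  nl <- block_reduce_mode(crop(volume$nucleus_labels), factors)
  labeled_volume(raw, cl, nl, volume$voxel_size_nm * factors)
}

# Block-reduce a 3D array with an arbitrary statistic over f1 x f2 x f3 blocks.
block_reduce <- function(a, f, fun) {
  d <- dim(a)
  dn <- d %/% f
  # reshape to (f1, dn1, f2, dn2, f3, dn3) then aggregate over block axes
  b <- array(a, dim = c(f[1], dn[1], f[2], dn[2], f[3], dn[3]))
  out <- apply(b, c(2, 4, 6), fun)
  array(out, dim = dn)
}

block_reduce_mode <- function(a, f) {
  d <- dim(a)
  dn <- d %/% f
  b <- array(a, dim = c(f[1], dn[1], f[2], dn[2], f[3], dn[3]))
  b <- aperm(b, c(1, 3, 5, 2, 4, 6))
  m <- matrix(b, nrow = prod(f), ncol = prod(dn))
  out <- apply(m, 2, function(v) {
    tv <- tabulate(v + 1L)
    which.max(tv) - 1L
  })
  array(as.integer(out), dim = dn)
}

# Bounding box of a logical/positive mask; returns list(lo, hi) 1-based or NULL.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

# Centre of mass (1-based voxel coordinates) of a mask.
mask_com <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  assert_that(nrow(idx) > 0, "empty mask has no centre of mass")
  colMeans(idx)
}
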