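#' Per-compartment coarse texture crop
#'
#' Cuts a fixed-size cube around the nucleus centre of mass of one cell,
#' normalises intensities to `[0, 1]` (division by the 8-bit dtype maximum)
#' and zeroes every voxel outside the target compartment: the cytoplasm crop
#' keeps `cell \ nucleus` voxels, the nucleus crop keeps nucleus voxels.
#' Windows that exceed the volume are zero-padded so the tensor shape is
#' fixed. Default edge lengths are 144 (cytoplasm) / 104 (nucleus) voxels in
#' training mode and 320 / 160 in prediction mode, matching a whole-animal
#' SBEM working resolution of 80 x 80 x 100 nm; pass `crop_size` to work at
#' other scales.
#'
#' @param volume a [labeled_volume()] already at the coarse working
#'   resolution (use [downsample_volume()] first if needed).
#' @param cell_id cell label id.
#' @param compartment `"cytoplasm"` or `"nucleus"`.
#' @param mode `"train"` or `"predict"` (selects the default crop size).
#' @param crop_size optional edge length override (single integer).
#' @return A `coarse_crop` (3D array in `[0,1]` + metadata), or `NULL` with a
#'   warning when the cell has no nucleus voxels (skip-with-warning
#'   contract: such cells are excluded upstream).
#' @export
extract_coarse_crop <- function(volume, cell_id, compartment = c("cytoplasm", "nucleus"),
                                mode = c("train", "predict"), crop_size = NULL) {
  compartment <- match.arg(compartment)
  mode <- match.arg(mode)
  if (is.null(crop_size)) {
    crop_size <- if (mode == "train") {
      if (compartment == "cytoplasm") 144L else 104L
    } else {
      if (compartment == "cytoplasm") 320L else 160L
    }
  }
  crop_size <- as.integer(crop_size)
  nuc <- volume$nucleus_labels == cell_id
  if (!any(nuc)) {
    warning(sprintf("cell %s has no nucleus; skipped", cell_id))
    return(NULL)
  }
  com <- round(mask_com(nuc))
  d <- dim(volume$raw)
  lo <- as.integer(com) - crop_size %/% 2L
  hi <- lo + crop_size - 1L
  out <- array(0, dim = rep(crop_size, 3))
  src_lo <- pmax(lo, 1L); src_hi <- pmin(hi, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - lo + 1L; dst_hi <- src_hi - lo + 1L
    raw <- volume$raw[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3], drop = FALSE]
    cl <- volume$cell_labels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3], drop = FALSE]
    nl <- volume$nucleus_labels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3], drop = FALSE]
    keep <- if (compartment == "cytoplasm") (cl == cell_id & nl != cell_id) else (nl == cell_id)
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      (raw / 255) * keep
  }
  structure(list(values = out, compartment = compartment, mode = mode,
                 cell_id = cell_id),
            class = "coarse_crop")
}

# compartment support mask for a cell
compartment_mask <- function(volume, cell_id, compartment) {
  if (compartment == "cytoplasm") {
    volume$cell_labels == cell_id & volume$nucleus_labels != cell_id
  } else {
    volume$nucleus_labels == cell_id
  }
}

#' Fine texture patch set
#'
#' Partitions the compartment bounding box into a regular grid of
#' `patch_size`^3 cubes anchored at the box's minimum corner (no overlap;
#' trailing cubes are zero-padded) and keeps the cubes that are less than
#' 50% empty, i.e. whose compartment occupancy is strictly greater than 0.5.
#' Retained patches are normalised to `[0, 1]` with non-compartment voxels
#' masked to 0.
#'
#' @param volume a [labeled_volume()] at the fine working resolution.
#' @param cell_id cell label id.
#' @param compartment `"cytoplasm"` or `"nucleus"`.
#' @param patch_size cube edge length (default 32).
#' @param upsample integer factor(s) for nearest-neighbour upsampling of the
#'   cell's bounding region before tiling, emulating a finer acquisition
#'   grid when the volume carries only one resolution (default 1: tile the
#'   native grid).
#' @return A `fine_patch_set`: `patches` (list of arrays), `occupancy`
#'   (fraction of compartment voxels per retained patch), `cell_id`,
#'   `compartment`. The set may be empty; callers treat that as an excluded
#'   cell.
#' @export
extract_fine_patches <- function(volume, cell_id, compartment = c("cytoplasm", "nucleus"),
                                 patch_size = 32L, upsample = 1L) {
  compartment <- match.arg(compartment)
  patch_size <- as.integer(patch_size)
  f <- rep(as.integer(upsample), length.out = 3)
  mask <- compartment_mask(volume, cell_id, compartment)
  bb <- mask_bbox(mask)
  patches <- list(); occ <- numeric(0)
  if (!is.null(bb)) {
    mask <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
    raw <- volume$raw[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
    if (any(f > 1L)) {
      mask <- upsample_nearest(mask, f)
      raw <- upsample_nearest(raw, f)
    }
    d <- dim(mask)
    ncubes <- ceiling(d / patch_size)
    vol3 <- patch_size^3
    for (iz in seq_len(ncubes[1])) for (iy in seq_len(ncubes[2])) for (ix in seq_len(ncubes[3])) {
      lo <- (c(iz, iy, ix) - 1L) * patch_size + 1L
      hi <- pmin(lo + patch_size - 1L, d)
      m <- array(FALSE, dim = rep(patch_size, 3))
      r <- array(0, dim = rep(patch_size, 3))
      sz <- hi - lo + 1L
      m[seq_len(sz[1]), seq_len(sz[2]), seq_len(sz[3])] <-
        mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      o <- sum(m) / vol3
      if (o > 0.5) {
        r[seq_len(sz[1]), seq_len(sz[2]), seq_len(sz[3])] <-
          raw[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] / 255
        patches[[length(patches) + 1L]] <- r * m
        occ <- c(occ, o)
      }
    }
  }
  structure(list(patches = patches, occupancy = occ, cell_id = cell_id,
                 compartment = compartment, patch_size = patch_size),
            class = "fine_patch_set")
}

# nearest-neighbour integer upsampling of a 3D array
upsample_nearest <- function(a, f) {
  a[rep(seq_len(dim(a)[1]), each = f[1]),
    rep(seq_len(dim(a)[2]), each = f[2]),
    rep(seq_len(dim(a)[3]), each = f[3]), drop = FALSE]
}
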