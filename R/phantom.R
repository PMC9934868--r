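#' Specification of a synthetic phantom volume
#'
#' Describes a bilaterally symmetric phantom tissue: `n_cell_pairs` mirrored
#' cell pairs, each cell containing one nucleus, drawn from a catalog of
#' (shape, cytoplasm texture, chromatin texture) classes and rasterised into
#' an 8-bit intensity grid with cell and nucleus label grids. The mirror
#' plane is the mid-plane of the x (last) axis, mimicking the mediolateral
#' symmetry of a whole-animal EM volume.
#'
#' Class geometry: `sphere` (isotropic), `ellipsoid` (elongated 1.7:1:0.6),
#' `stellate` (lobed radial profile), `flat` (oblate 1.4:1.2:0.42).
#' Cytoplasm textures: `uniform` (level ~150), `speckle` (high-frequency
#' salt-and-pepper, level ~105), `vesicular` (bright field ~190 with dark
#' blob inclusions); class intensity means are separated by well over 30
#' 8-bit units so texture classes are linearly separable by construction.
#' Chromatin textures: `smooth` or `granular`.
#'
#' @param n_cell_pairs number of mirrored cell pairs (>= 1).
#' @param grid_shape integer length-3 `(z, y, x)` voxel grid; `NULL` picks a
#'   grid large enough for `n_cell_pairs` at ~5% packing density.
#' @param voxel_size_nm physical voxel size `(z, y, x)` in nm.
#' @param class_catalog tibble/data frame with columns `shape_class`,
#'   `texture_class`, `chromatin_class`; default is the 3-shape x 2-texture
#'   six-class catalog used throughout the package's simulations.
#' @param contact_fraction fraction of cell pairs (after the first) placed
#'   touching an already-placed cell, preferring one of the same class;
#'   face (6-connectivity) contact.
#' @param seed integer RNG seed; generation is bit-deterministic given it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_cell_pairs = 30, grid_shape = NULL,
                         voxel_size_nm = c(100, 80, 80),
                         class_catalog = default_class_catalog(),
                         contact_fraction = 0.5, seed = 1L) {
  assert_that(n_cell_pairs >= 1, "n_cell_pairs must be >= 1")
  assert_that(nrow(class_catalog) >= 1, "class_catalog must be non-empty")
  assert_that(contact_fraction >= 0 && contact_fraction <= 1,
              "contact_fraction must be in [0, 1]")
  ok_shapes <- c("sphere", "ellipsoid", "stellate", "flat")
  ok_tex <- c("uniform", "speckle", "vesicular")
  ok_chrom <- c("smooth", "granular")
  assert_that(all(class_catalog$shape_class %in% ok_shapes), "unknown shape class")
  assert_that(all(class_catalog$texture_class %in% ok_tex), "unknown texture class")
  assert_that(all(class_catalog$chromatin_class %in% ok_chrom), "unknown chromatin class")
  if (is.null(grid_shape)) {
    h <- max(72, ceiling((n_cell_pairs * 1300 / 0.045)^(1 / 3)))
    h <- h + (h %% 2)
    grid_shape <- c(h, h, 2L * h)
  }
  grid_shape <- as.integer(grid_shape)
  assert_that(all(grid_shape >= 24), "grid_shape too small to hold cells")
  structure(list(n_cell_pairs = as.integer(n_cell_pairs),
                 grid_shape = grid_shape,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 class_catalog = tibble::as_tibble(class_catalog),
                 contact_fraction = contact_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_class_catalog <- function() {
  tibble::tibble(
    shape_class     = c("sphere", "sphere", "ellipsoid", "ellipsoid", "stellate", "stellate"),
    texture_class   = c("uniform", "speckle", "uniform", "speckle", "uniform", "speckle"),
    chromatin_class = c("smooth", "granular", "granular", "smooth", "smooth", "granular")
  )
}

# Random rotation matrix (uniform over SO(3) up to QR convention).
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rasterise one cell solid in a local bounding box around `center`.
# Returns arr.ind matrix (z, y, x) of inside voxels, or NULL if out of grid.
rasterize_solid <- function(center, shape_class, r0, rot, lobe_phase, grid_shape) {
  hw <- ceiling(1.85 * r0) + 1L
  lo <- floor(center) - hw
  hi <- floor(center) + hw
  if (any(lo < 3) || any(hi > grid_shape - 2L)) return(NULL)
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(z = zz, y = yy, x = xx))
  u <- t(rot) %*% (t(g) - center)   # 3 x n local coords
  inside <- switch(shape_class,
    sphere = colSums(u^2) <= r0^2,
    ellipsoid = (u[1, ] / (1.7 * r0))^2 + (u[2, ] / r0)^2 +
                (u[3, ] / (0.6 * r0))^2 <= 1,
    flat = (u[1, ] / (1.4 * r0))^2 + (u[2, ] / (1.2 * r0))^2 +
           (u[3, ] / (0.42 * r0))^2 <= 1,
    stellate = {
      r <- sqrt(colSums(u^2))
      az <- atan2(u[2, ], u[1, ])
      eq <- (u[1, ]^2 + u[2, ]^2) / pmax(r^2, 1e-9)   # equatorial weight
      rad <- 0.78 * r0 * (1 + 0.48 * cos(3 * az + lobe_phase)^2 * eq)
      r <= rad
    },
    stop("unknown shape class")
  )
  g[inside, , drop = FALSE]
}

arr_to_lin <- function(ind, d) {
  (ind[, 3] - 1) * d[1] * d[2] + (ind[, 2] - 1) * d[1] + ind[, 1]
}

mirror_ind <- function(ind, nx) {
  ind[, 3] <- nx + 1L - ind[, 3]
  ind
}

# Linear indices of the 6 face neighbours (grid-boundary-safe callers only).
face_neighbours <- function(lin, d) {
  sz <- d[1] * d[2]
  c(lin - 1L, lin + 1L, lin - d[1], lin + d[1], lin - sz, lin + sz)
}

#' Generate a synthetic phantom volume
#'
#' Rasterises `n_cell_pairs` mirrored cell pairs into raw/cell/nucleus grids
#' per the [phantom_spec()]. Each left-side cell receives a random class,
#' size and orientation; its right-side partner is the exact voxel mirror
#' across the x mid-plane, so partner centroids reflect onto each other
#' within a voxel. Nuclei are spheres strictly inside their cell. Cytoplasm
#' and chromatin intensities are procedural per class.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_volume`: a [labeled_volume()] plus a `truth` tibble
#'   (`cell_id`, `class_id`, shape/texture/chromatin class, `side`,
#'   `partner_id`, centroid, `neighbour_ids` list-column) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$grid_shape
  nx <- d[3]
  mid <- nx / 2            # mirror plane x = nx/2 (between columns for even nx)
  P <- spec$n_cell_pairs
  K <- nrow(spec$class_catalog)

  cell_labels <- array(0L, dim = d)
  occ <- array(FALSE, dim = d)

  # balanced class assignment over pairs, shuffled
  class_ids <- sample(rep(seq_len(K), length.out = P))

  left <- vector("list", P)    # per pair: list(ind, center, r0, ...)
  placed_left_ids <- integer(0)

  for (p in seq_len(P)) {
    cls <- class_ids[p]
    shape <- spec$class_catalog$shape_class[cls]
    r0 <- runif(1, 5.5, 8)
    rot <- random_rotation()
    phase <- runif(1, 0, 2 * pi)
    want_contact <- (p > 1) && (runif(1) < spec$contact_fraction)

    placed <- FALSE
    ind <- NULL; center <- NULL
    for (attempt in seq_len(400)) {
      # a cell that cannot be attached after many tries may fall back to free
      # placement, unless every cell is required to touch (contact_fraction 1)
      if (want_contact && attempt > 200 && spec$contact_fraction < 1) {
        want_contact <- FALSE
      }
      if (want_contact) {
        same <- placed_left_ids[class_ids[placed_left_ids] == cls]
        pool <- if (length(same)) same else placed_left_ids
        tgt <- left[[if (length(pool) == 1) pool else sample(pool, 1)]]
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        dsum <- tgt$r_eff + r0
        hit <- FALSE
        for (dist in seq(ceiling(dsum + 3), max(4, floor(dsum - 4)), by = -1)) {
          center <- tgt$center + dist * dir
          if (center[3] + 1.85 * r0 + 1 > mid - 1) next
          cand <- rasterize_solid(center, shape, r0, rot, phase, d)
          if (is.null(cand) || nrow(cand) < 30) next
          lin <- arr_to_lin(cand, d)
          if (any(occ[lin])) break        # moving closer only overlaps more
          nb <- face_neighbours(lin, d)
          if (any(cell_labels[nb] == tgt$id)) { hit <- TRUE; ind <- cand; break }
        }
        if (hit) { placed <- TRUE; break }
      } else {
        center <- c(runif(1, 3 + 1.85 * r0, d[1] - 2 - 1.85 * r0),
                    runif(1, 3 + 1.85 * r0, d[2] - 2 - 1.85 * r0),
                    runif(1, 3 + 1.85 * r0, mid - 2 - 1.85 * r0))
        cand <- rasterize_solid(center, shape, r0, rot, phase, d)
        if (is.null(cand) || nrow(cand) < 30) next
        lin <- arr_to_lin(cand, d)
        if (any(occ[lin])) next
        nb <- face_neighbours(lin, d)
        if (any(occ[nb])) next           # keep non-contact cells separated
        ind <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("phantom placement failed for cell pair %d after bounded retries", p),
           call. = FALSE)
    }
    id_l <- 2L * p - 1L
    lin <- arr_to_lin(ind, d)
    occ[lin] <- TRUE
    cell_labels[lin] <- id_l
    ind_r <- mirror_ind(ind, nx)
    lin_r <- arr_to_lin(ind_r, d)
    occ[lin_r] <- TRUE
    cell_labels[lin_r] <- id_l + 1L
    left[[p]] <- list(id = id_l, ind = ind, center = colMeans(ind),
                      r0 = r0, r_eff = (3 * nrow(ind) / (4 * pi))^(1 / 3),
                      class = cls)
    placed_left_ids <- c(placed_left_ids, p)
  }

  # nuclei: spheres strictly inside the (1-voxel-eroded) cell support
  nucleus_labels <- array(0L, dim = d)
  for (p in seq_len(P)) {
    cell <- left[[p]]
    lin <- arr_to_lin(cell$ind, d)
    id_l <- cell$id
    # erode cell support by one voxel (6-connectivity)
    inside <- array(FALSE, dim = d); inside[lin] <- TRUE
    nbmat <- matrix(face_neighbours(lin, d), nrow = nrow(cell$ind))
    core <- lin[rowSums(matrix(inside[nbmat], nrow = nrow(cell$ind))) == 6L]
    rn <- max(2, 0.42 * cell$r0)
    off <- runif(3, -0.12, 0.12) * cell$r0
    ctr <- cell$center + off
    # nuclei are mildly eccentric ellipsoids with a per-pair pose: real nuclei
    # are not perfect spheres, and a scale-normalised shape encoder needs the
    # nuclear shape channel to carry some information
    ecc <- runif(1, 1.1, 1.6)
    rotn <- random_rotation()
    u <- t(rotn) %*% rbind(cell$ind[, 1] - ctr[1], cell$ind[, 2] - ctr[2],
                           cell$ind[, 3] - ctr[3])
    sph <- lin[(u[1, ] / (rn * ecc))^2 + (u[2, ] / rn)^2 +
                 (u[3, ] * sqrt(ecc) / rn)^2 <= 1]
    nuc <- intersect(sph, core)
    if (length(nuc) < 7) nuc <- head(core, max(7, length(core) %/% 8))
    assert_that(length(nuc) > 0, sprintf("cell %d too thin to host a nucleus", id_l))
    nucleus_labels[nuc] <- id_l
    # mirrored nucleus
    nuc_ind <- arrayInd(nuc, d)
    nucleus_labels[arr_to_lin(mirror_ind(nuc_ind, nx), d)] <- id_l + 1L
  }

  raw <- paint_textures(d, cell_labels, nucleus_labels, left, spec)

  truth <- build_truth(d, cell_labels, left, spec)
  vol <- labeled_volume(raw, cell_labels, nucleus_labels, spec$voxel_size_nm)
  structure(c(vol, list(truth = truth, spec = spec)), class = c("phantom_volume", "labeled_volume"))
}

# Procedural 8-bit textures; per-pair level jitter is shared by both partners.
paint_textures <- function(d, cell_labels, nucleus_labels, left, spec) {
  n <- prod(d)
  raw <- 30 + rnorm(n, 0, 5)
  for (p in seq_along(left)) {
    cls <- left[[p]]$class
    tex <- spec$class_catalog$texture_class[cls]
    chrom <- spec$class_catalog$chromatin_class[cls]
    jit <- runif(1, -8, 8)
    for (id in c(left[[p]]$id, left[[p]]$id + 1L)) {
      cyto <- which(cell_labels == id & nucleus_labels != id)
      nuc <- which(nucleus_labels == id)
      raw[cyto] <- switch(tex,
        uniform = 150 + jit + rnorm(length(cyto), 0, 6),
        speckle = 105 + jit + sample(c(-55, 55), length(cyto), replace = TRUE) +
                  rnorm(length(cyto), 0, 6),
        vesicular = {
          v <- 190 + jit + rnorm(length(cyto), 0, 6)
          k <- max(1L, length(cyto) %/% 40L)
          seeds <- sample(seq_along(cyto), k)
          blob <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
          blob <- blob[rowSums(blob^2) <= 2, ]
          # dark blob inclusions: seed voxels + spherical offsets, kept inside
          # this cell's cytoplasm only
          offs <- (blob[, 3]) * d[1] * d[2] + (blob[, 2]) * d[1] + blob[, 1]
          lins <- as.vector(outer(cyto[seeds], offs, "+"))
          lins <- lins[lins >= 1 & lins <= n]
          dark <- lins[cell_labels[lins] == id & nucleus_labels[lins] != id]
          m <- match(dark, cyto)
          v[m[!is.na(m)]] <- 70 + jit
          v
        })
      raw[nuc] <- switch(chrom,
        smooth = 120 + jit + rnorm(length(nuc), 0, 4),
        granular = {
          v <- 105 + jit + rnorm(length(nuc), 0, 5)
          k <- max(1L, length(nuc) %/% 12L)
          seeds <- sample(seq_along(nuc), k)
          offs <- c(0L, 1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
          lins <- as.vector(outer(nuc[seeds], offs, "+"))
          lins <- lins[lins >= 1 & lins <= n]
          bright <- lins[nucleus_labels[lins] == id]
          m <- match(bright, nuc)
          v[m[!is.na(m)]] <- 200 + jit
          v
        })
    }
  }
  array(as.integer(pmin(pmax(round(raw), 0), 255)), dim = d)
}

build_truth <- function(d, cell_labels, left, spec) {
  P <- length(left)
  ids <- integer(0); class_id <- integer(0); side <- character(0)
  partner <- integer(0); cz <- numeric(0); cy <- numeric(0); cx <- numeric(0)
  nx <- d[3]
  for (p in seq_len(P)) {
    cell <- left[[p]]
    ctr_l <- colMeans(cell$ind)
    ctr_r <- colMeans(mirror_ind(cell$ind, nx))
    ids <- c(ids, cell$id, cell$id + 1L)
    class_id <- c(class_id, cell$class, cell$class)
    side <- c(side, "left", "right")
    partner <- c(partner, cell$id + 1L, cell$id)
    cz <- c(cz, ctr_l[1], ctr_r[1]); cy <- c(cy, ctr_l[2], ctr_r[2])
    cx <- c(cx, ctr_l[3], ctr_r[3])
  }
  adj <- label_adjacency(cell_labels)
  nb <- lapply(ids, function(i) {
    sort(unique(c(adj$a[adj$b == i], adj$b[adj$a == i])))
  })
  ord <- order(ids)
  tibble::tibble(
    cell_id = ids,
    class_id = class_id,
    shape_class = spec$class_catalog$shape_class[class_id],
    texture_class = spec$class_catalog$texture_class[class_id],
    chromatin_class = spec$class_catalog$chromatin_class[class_id],
    side = side,
    partner_id = partner,
    centroid_z = cz, centroid_y = cy, centroid_x = cx,
    neighbour_ids = nb
  )[ord, ]
}

# All unordered label pairs (a < b) that share a face-adjacent voxel pair.
label_adjacency <- function(labels) {
  d <- dim(labels)
  pairs <- list()
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (s in shifts) {
    i1 <- list(seq_len(d[1] - s[1]), seq_len(d[2] - s[2]), seq_len(d[3] - s[3]))
    i2 <- list(seq_len(d[1] - s[1]) + s[1], seq_len(d[2] - s[2]) + s[2],
               seq_len(d[3] - s[3]) + s[3])
    a <- labels[i1[[1]], i1[[2]], i1[[3]]]
    b <- labels[i2[[1]], i2[[2]], i2[[3]]]
    keep <- a != b & a > 0L & b > 0L
    if (any(keep)) {
      pairs[[length(pairs) + 1L]] <- cbind(pmin(a[keep], b[keep]),
                                           pmax(a[keep], b[keep]))
    }
  }
  if (!length(pairs)) return(tibble::tibble(a = integer(0), b = integer(0)))
  m <- unique(do.call(rbind, pairs))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  tibble::tibble(a = as.integer(m[, 1]), b = as.integer(m[, 2]))
}

#' Toy per-cell gene expression table
#'
#' Builds an expression table in which every phantom class has
#' `markers_per_class` exclusive marker genes: value 1 in that class's cells,
#' 0 elsewhere, plus clipped Gaussian noise. Values live in `[0, 1]`
#' (fraction-of-cell expression overlap semantics).
#'
#' @param truth truth tibble from [generate_phantom()] (needs `cell_id`,
#'   `class_id`).
#' @param markers_per_class exclusive marker genes per class (>= 1).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed RNG seed.
#' @return Tibble: `cell_id` plus one column per gene, values in `[0, 1]`.
#' @export
make_expression_table <- function(truth, markers_per_class = 3, noise_sd = 0.05,
                                  seed = 1L) {
  assert_that(nrow(truth) > 0, "empty truth table")
  assert_that(markers_per_class >= 1, "markers_per_class must be >= 1")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  with_seed(seed, {
    classes <- sort(unique(truth$class_id))
    cols <- list(cell_id = truth$cell_id)
    for (cl in classes) {
      for (j in seq_len(markers_per_class)) {
        base <- as.numeric(truth$class_id == cl)
        val <- base + if (noise_sd > 0) rnorm(nrow(truth), 0, noise_sd) else 0
        cols[[sprintf("class%d_marker%d", cl, j)]] <- clip01(val)
      }
    }
    tibble::as_tibble(cols)
  })
}

#' Write / read phantom tables as TSV
#'
#' Plain-TSV serialisation with a header row and `cell_id` first;
#' `neighbour_ids` list-columns are comma-joined.
#'
#' @param x truth or expression tibble.
#' @param path output file.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_cell_table <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) x[[j]] <- vapply(x[[j]], paste, "", collapse = ",")
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tibble::as_tibble(read.delim(path, check.names = FALSE))
}
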