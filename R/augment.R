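#' Mesh deformation configuration
#'
#' Parameters of the morphology-preserving random mesh deformation used to
#' build contrastive views. `n_handles` surface regions (Euclidean balls of
#' radius `handle_radius` x bbox diagonal around random surface vertices)
#' are rigidly translated by `displacement_scale` x bbox diagonal along a
#' random, normal, or negative-normal direction, and the constraint is
#' propagated to the free vertices by a biharmonic field or an
#' as-rigid-as-possible (ARAP) solve. An optional rigid part (anisotropic
#' scaling, rotation, mirror across a random axis plane) follows.
#'
#' @param n_handles number of handle regions (>= 1).
#' @param handle_radius ball radius, fraction of the bbox diagonal.
#' @param displacement_scale handle displacement, fraction of bbox diagonal
#'   (>= 0; 0 gives the identity up to the rigid part).
#' @param direction_mode `"random"`, `"normal"` or `"negative_normal"`.
#' @param method `"biharmonic"` or `"arap"`.
#' @param scale_range length-2 anisotropic per-axis scale range (c(1, 1)
#'   disables scaling).
#' @param rotate apply a random rotation.
#' @param mirror apply a mirror across a random one of the three axis
#'   planes (face orientation is re-fixed so normals stay outward).
#' @param seed RNG seed.
#' @return A `deform_config`.
#' @export
deform_config <- function(n_handles = 3, handle_radius = 0.1,
                          displacement_scale = 0.05,
                          direction_mode = c("random", "normal", "negative_normal"),
                          method = c("biharmonic", "arap"),
                          scale_range = c(0.95, 1.05), rotate = TRUE,
                          mirror = FALSE, seed = NULL) {
  direction_mode <- match.arg(direction_mode)
  method <- match.arg(method)
  assert_that(n_handles >= 1, "n_handles must be >= 1")
  assert_that(displacement_scale >= 0, "displacement_scale must be >= 0")
  structure(list(n_handles = as.integer(n_handles), handle_radius = handle_radius,
                 displacement_scale = displacement_scale,
                 direction_mode = direction_mode, method = method,
                 scale_range = scale_range, rotate = rotate, mirror = mirror,
                 seed = seed),
            class = "deform_config")
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh, normalize = FALSE)   # area-weighted
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    idx <- mesh$faces[, j]
    for (c3 in 1:3) {
      acc <- rep(0, nrow(mesh$vertices))
      s <- rowsum(fn[, c3], idx)
      acc[as.integer(rownames(s))] <- s
      n[, c3] <- n[, c3] + acc
    }
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# uniform graph Laplacian (sparse)
graph_laplacian <- function(faces, n) {
  e <- unique(mesh_edges(faces))
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

# cotangent weights as a sparse symmetric matrix (clamped at 0)
cotan_weights <- function(vertices, faces) {
  n <- nrow(vertices)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (k in 1:3) {
    o <- faces[, k]                       # opposite corner
    a <- faces[, (k %% 3) + 1]; b <- faces[, ((k + 1) %% 3) + 1]
    u <- vertices[a, , drop = FALSE] - vertices[o, , drop = FALSE]
    v <- vertices[b, , drop = FALSE] - vertices[o, , drop = FALSE]
    dot <- rowSums(u * v)
    crs <- sqrt(pmax(rowSums(u^2) * rowSums(v^2) - dot^2, 1e-300))
    cot <- pmax(dot / crs, 0) / 2
    ii <- c(ii, a, b); jj <- c(jj, b, a); ww <- c(ww, cot, cot)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
}

# Solve the constrained biharmonic system: min ||L d||^2 with d fixed on
# handle vertices. Returns the full displacement matrix.
biharmonic_field <- function(vertices, faces, handle_idx, handle_disp) {
  n <- nrow(vertices)
  L <- graph_laplacian(faces, n)
  K <- L %*% L
  free <- setdiff(seq_len(n), handle_idx)
  d <- matrix(0, n, 3)
  d[handle_idx, ] <- handle_disp
  rhs <- -K[free, handle_idx, drop = FALSE] %*% handle_disp
  d[free, ] <- as.matrix(Matrix::solve(K[free, free], rhs))
  d
}

# ARAP local-global iterations with cotangent weights; handle vertices are
# hard constraints. Initialised from the biharmonic field.
arap_deform_positions <- function(vertices, faces, handle_idx, handle_disp,
                                  iters = 5) {
  n <- nrow(vertices)
  W <- cotan_weights(vertices, faces)
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  free <- setdiff(seq_len(n), handle_idx)
  P <- vertices
  Pp <- vertices + biharmonic_field(vertices, faces, handle_idx, handle_disp)
  Pp[handle_idx, ] <- vertices[handle_idx, , drop = FALSE] + handle_disp
  Wt <- as(W, "TsparseMatrix")
  ei <- Wt@i + 1L; ej <- Wt@j + 1L; ew <- Wt@x
  Lff <- L[free, free]
  Lfh <- L[free, handle_idx, drop = FALSE]
  ch <- Matrix::Cholesky(Lff + Matrix::Diagonal(length(free)) * 1e-10)
  for (it in seq_len(iters)) {
    # local step: best rotation per vertex
    E0 <- P[ei, , drop = FALSE] - P[ej, , drop = FALSE]
    E1 <- Pp[ei, , drop = FALSE] - Pp[ej, , drop = FALSE]
    R <- vector("list", n)
    Sflat <- matrix(0, n, 9)
    for (r in 1:3) for (c3 in 1:3) {
      s <- rowsum(ew * E0[, r] * E1[, c3], ei)
      Sflat[as.integer(rownames(s)), (r - 1) * 3 + c3] <- s
    }
    for (i in seq_len(n)) {
      S <- matrix(Sflat[i, ], 3, 3, byrow = TRUE)
      if (all(S == 0)) { R[[i]] <- diag(3); next }
      sv <- svd(S)
      Ri <- sv$v %*% t(sv$u)
      if (det(Ri) < 0) { sv$v[, 3] <- -sv$v[, 3]; Ri <- sv$v %*% t(sv$u) }
      R[[i]] <- Ri
    }
    # global step: solve L p' = b with b from averaged rotations
    B <- matrix(0, n, 3)
    Rm <- do.call(rbind, R)               # (3n) x 3
    # b_i = sum_j w_ij/2 (R_i + R_j) (p_i - p_j)
    rot_e <- matrix(0, length(ei), 3)
    for (r in 1:3) {
      Ri_r <- cbind(Rm[(ei - 1) * 3 + r, , drop = FALSE])
      Rj_r <- cbind(Rm[(ej - 1) * 3 + r, , drop = FALSE])
      rot_e[, r] <- rowSums((Ri_r + Rj_r) / 2 * E0)
    }
    for (c3 in 1:3) {
      s <- rowsum(ew * rot_e[, c3], ei)
      B[as.integer(rownames(s)), c3] <- s
    }
    rhs <- B[free, , drop = FALSE] - as.matrix(Lfh %*% Pp[handle_idx, , drop = FALSE])
    Pp[free, ] <- as.matrix(Matrix::solve(ch, rhs))
  }
  Pp
}

mirror_mesh <- function(mesh, axis) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  v[, axis] <- 2 * ctr[axis] - v[, axis]
  surface_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE], mesh$object_id)
}

#' Random morphology-preserving mesh deformation
#'
#' Applies the handle-based deformation described in [deform_config()]:
#' handle regions are translated and the displacement propagated to the free
#' vertices via a biharmonic field or ARAP, followed by the optional rigid
#' part. Vertex and face counts are unchanged; watertightness is preserved
#' (connectivity is untouched). Deterministic given `cfg$seed`.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param cfg a [deform_config()].
#' @return A deformed `surface_mesh`.
#' @export
deform_mesh <- function(mesh, cfg) {
  with_seed(cfg$seed, deform_mesh_impl(mesh, cfg))
}

deform_mesh_impl <- function(mesh, cfg) {
  V <- mesh$vertices
  n <- nrow(V)
  diag_len <- sqrt(sum((apply(V, 2, max) - apply(V, 2, min))^2))
  out <- mesh
  if (cfg$displacement_scale > 0) {
    centers <- sample.int(n, cfg$n_handles)
    vn <- vertex_normals(mesh)
    idx_list <- list(); disp_list <- list()
    for (h in seq_len(cfg$n_handles)) {
      ctr <- centers[h]
      d2 <- rowSums(sweep(V, 2, V[ctr, ])^2)
      region <- which(d2 <= (cfg$handle_radius * diag_len)^2)
      dir <- switch(cfg$direction_mode,
        random = { u <- rnorm(3); u / sqrt(sum(u^2)) },
        normal = vn[ctr, ],
        negative_normal = -vn[ctr, ])
      idx_list[[h]] <- region
      disp_list[[h]] <- matrix(dir * cfg$displacement_scale * diag_len,
                               length(region), 3, byrow = TRUE)
    }
    hidx <- unlist(idx_list)
    hdisp <- do.call(rbind, disp_list)
    keep <- !duplicated(hidx)
    hidx <- hidx[keep]; hdisp <- hdisp[keep, , drop = FALSE]
    assert_that(length(hidx) < n, "handle regions cover the whole mesh")
    Vnew <- if (cfg$method == "biharmonic") {
      V + biharmonic_field(V, mesh$faces, hidx, hdisp)
    } else {
      arap_deform_positions(V, mesh$faces, hidx, hdisp)
    }
    assert_that(all(is.finite(Vnew)), "deformation produced non-finite vertices")
    out <- surface_mesh(Vnew, mesh$faces, mesh$object_id)
  }
  # rigid part
  V <- out$vertices
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  if (!isTRUE(all.equal(cfg$scale_range, c(1, 1)))) {
    s <- runif(3, cfg$scale_range[1], cfg$scale_range[2])
    Vc <- sweep(Vc, 2, s, `*`)
  }
  if (isTRUE(cfg$rotate)) Vc <- Vc %*% t(random_rotation())
  out <- surface_mesh(sweep(Vc, 2, ctr, `+`), out$faces, out$object_id)
  if (isTRUE(cfg$mirror)) out <- mirror_mesh(out, sample.int(3, 1))
  out
}

#' Precompute random deformation views of a mesh
#'
#' Builds `n_views` independent deformations with per-view derived seeds
#' (so the set is reproducible), optionally caching them as PLY files named
#' `{object_id}_view{k}.ply` for reuse across training epochs.
#'
#' @param mesh a `surface_mesh`.
#' @param n_views number of views (>= 1; the reference pipeline precomputes
#'   10 per surface).
#' @param cfg a [deform_config()] whose `seed` drives the per-view seeds.
#' @param cache_dir optional directory for the PLY cache.
#' @return List of `surface_mesh` views.
#' @export
make_mesh_views <- function(mesh, n_views = 10L, cfg = deform_config(seed = 1),
                            cache_dir = NULL) {
  assert_that(n_views >= 1, "n_views must be >= 1")
  base_seed <- cfg$seed %||% 0L
  views <- vector("list", n_views)
  for (k in seq_len(n_views)) {
    path <- if (!is.null(cache_dir)) {
      file.path(cache_dir, sprintf("%s_view%d.ply", as.character(mesh$object_id), k))
    } else NULL
    if (!is.null(path) && file.exists(path)) {
      views[[k]] <- read_ply(path)
      views[[k]]$object_id <- mesh$object_id
      next
    }
    vcfg <- cfg
    vcfg$seed <- derive_seed(base_seed, k)
    views[[k]] <- deform_mesh(mesh, vcfg)
    if (!is.null(path)) {
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      write_ply(views[[k]], path)
    }
  }
  views
}

# ---- texture augmentation --------------------------------------------------

# cached full-resolution coordinate grids per shape
.grid_cache <- new.env(parent = emptyenv())

coord_grid <- function(d) {
  key <- paste(d, collapse = "x")
  got <- .grid_cache[[key]]
  if (!is.null(got)) return(got)
  g <- list(z = rep(seq_len(d[1]), times = d[2] * d[3]),
            y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
            x = rep(seq_len(d[3]), each = d[1] * d[2]))
  .grid_cache[[key]] <- g
  g
}

# trilinear sampling of 3D array `a` at fractional coords (z, y, x), clamped
trilinear_sample <- function(a, z, y, x) {
  cpp_trilinear(as.double(a), as.integer(dim(a)), z, y, x)
}

# A drawn texture transform: axis permutation/flips plus warp coordinates.
# Drawing the transform once lets a crop and its mask share it exactly.
draw_texture_transform <- function(d, elastic_cfg) {
  ax <- sort(sample.int(3, 2))
  k <- sample.int(4, 1) - 1L
  flips <- runif(3) < 0.5
  amp <- elastic_cfg$amplitude %||% 0
  warp <- NULL
  if (amp > 0) {
    grid_n <- elastic_cfg$grid %||% 4
    g <- coord_grid(d)
    zi <- 1 + (g$z - 1) * (grid_n - 1) / (d[1] - 1)
    yi <- 1 + (g$y - 1) * (grid_n - 1) / (d[2] - 1)
    xi <- 1 + (g$x - 1) * (grid_n - 1) / (d[3] - 1)
    fld <- lapply(1:3, function(i) {
      ctrl <- array(rnorm(grid_n^3, 0, amp), dim = rep(grid_n, 3))
      trilinear_sample(ctrl, zi, yi, xi)
    })
    warp <- list(z = g$z + fld[[1]], y = g$y + fld[[2]], x = g$x + fld[[3]])
  }
  list(ax = ax, k = k, flips = flips, warp = warp)
}

apply_texture_transform <- function(a, tr) {
  if (tr$k > 0) for (i in seq_len(tr$k)) {
    perm <- seq_len(3); perm[tr$ax] <- rev(tr$ax)
    a <- aperm(a, perm)
    d <- dim(a)
    if (tr$ax[1] == 1) a <- a[d[1]:1, , , drop = FALSE]
    else a <- a[, d[2]:1, , drop = FALSE]
  }
  d <- dim(a)
  if (tr$flips[1]) a <- a[d[1]:1, , , drop = FALSE]
  if (tr$flips[2]) a <- a[, d[2]:1, , drop = FALSE]
  if (tr$flips[3]) a <- a[, , d[3]:1, drop = FALSE]
  if (!is.null(tr$warp)) {
    a <- array(trilinear_sample(a, tr$warp$z, tr$warp$y, tr$warp$x), dim = d)
  }
  clip01(a)
}

#' Random texture augmentation
#'
#' Applies random axis flips, a random right-angle rotation (axis-pair
#' permutation) and a smooth random elastic warp to a 3D crop in `[0, 1]`.
#' Output shape equals input shape; values are clipped back to `[0, 1]`.
#' Intensity is never jittered: the encoders are meant to remain sensitive
#' to absolute intensity.
#'
#' @param crop 3D array in `[0, 1]`.
#' @param seed RNG seed.
#' @param elastic_cfg list with `amplitude` (voxels; 0 disables the warp)
#'   and `grid` (control-point grid edge, default 4).
#' @return Augmented 3D array, same shape.
#' @export
augment_texture <- function(crop, seed = NULL,
                            elastic_cfg = list(amplitude = 2, grid = 4)) {
  with_seed(seed, {
    tr <- draw_texture_transform(dim(crop), elastic_cfg)
    apply_texture_transform(crop, tr)
  })
}
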