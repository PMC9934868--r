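#' Surface meshes of segmented objects
#'
#' Watertight triangular membrane surfaces extracted from label masks.
#' Vertices are stored as an `n x 3` matrix of physical coordinates in nm,
#' columns in `(z, y, x)` order (the volume's axis convention); `faces` is an
#' `m x 3` integer matrix of 1-based vertex indices with consistent outward
#' orientation.
#'
#' @param vertices n x 3 numeric matrix (nm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @param object_id id of the source object.
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, object_id = NA) {
  structure(list(vertices = vertices, faces = faces, object_id = object_id),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> object %s: %d vertices, %d faces\n",
              as.character(x$object_id), nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# ---- marching tetrahedra ---------------------------------------------------

# Freudenthal 6-tetrahedra decomposition of the unit cube (corner ids 0..7,
# corner c has offset (bit0, bit1, bit2) along (z, y, x)). All tets share the
# main diagonal 0-7, which makes the induced face diagonals consistent
# between neighbouring cubes.
.tets <- rbind(c(0, 1, 3, 7), c(0, 3, 2, 7), c(0, 2, 6, 7),
               c(0, 6, 4, 7), c(0, 4, 5, 7), c(0, 5, 1, 7))

.corner_off <- cbind(z = c(0, 1, 0, 1, 0, 1, 0, 1),
                     y = c(0, 0, 1, 1, 0, 0, 1, 1),
                     x = c(0, 0, 0, 0, 1, 1, 1, 1))

# Per inside-pattern (4 bits) triangle list, each triangle a 3 x 2 matrix of
# local tet-corner index pairs (the crossing edges). Computed once at load.
mt_case_table <- function() {
  tbl <- vector("list", 16)
  for (code in 0:15) {
    ins <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) != 0L)
    outs <- setdiff(1:4, ins)
    tris <- list()
    if (length(ins) == 1) {
      p <- ins; q <- outs
      tris <- list(rbind(c(p, q[1]), c(p, q[2]), c(p, q[3])))
    } else if (length(ins) == 3) {
      q <- outs; p <- ins
      tris <- list(rbind(c(q, p[1]), c(q, p[2]), c(q, p[3])))
    } else if (length(ins) == 2) {
      p <- ins; q <- outs
      e11 <- c(p[1], q[1]); e12 <- c(p[1], q[2])
      e21 <- c(p[2], q[1]); e22 <- c(p[2], q[2])
      tris <- list(rbind(e11, e12, e22), rbind(e11, e22, e21))
    }
    tbl[[code + 1]] <- tris
  }
  tbl
}
.mt_cases <- mt_case_table()

# Isosurface of a binary mask (logical 3D array) by marching tetrahedra.
# Vertices at crossing-edge midpoints, in 1-based (z,y,x) voxel-centre
# coordinates of the input array. Orientation is fixed afterwards by
# orient_mesh(). The mask is padded with background so surfaces close.
marching_tets <- function(mask) {
  d0 <- dim(mask)
  m <- array(FALSE, dim = d0 + 2L)
  m[2:(d0[1] + 1), 2:(d0[2] + 1), 2:(d0[3] + 1)] <- mask
  d <- dim(m)
  nc <- d - 1L
  bz <- seq_len(nc[1]); by <- seq_len(nc[2]); bx <- seq_len(nc[3])
  base <- as.vector(outer(outer(bz, (by - 1L) * d[1], "+"),
                          (bx - 1L) * d[1] * d[2], "+"))
  coff <- as.integer(.corner_off %*% c(1L, d[1], d[1] * d[2]))
  Vc <- matrix(FALSE, length(base), 8)
  for (c8 in 1:8) Vc[, c8] <- m[base + coff[c8]]
  s <- rowSums(Vc)
  mixed <- which(s > 0 & s < 8)
  if (!length(mixed)) stop("mask has no surface", call. = FALSE)
  base <- base[mixed]; Vc <- Vc[mixed, , drop = FALSE]

  tri_a <- list(); tri_b <- list()   # each element: ntri x 3 matrices of endpoints
  for (t in 1:6) {
    corners <- .tets[t, ] + 1L
    code <- (Vc[, corners[1]] * 1L) + (Vc[, corners[2]] * 2L) +
            (Vc[, corners[3]] * 4L) + (Vc[, corners[4]] * 8L)
    for (cd in setdiff(unique(code), c(0L, 15L))) {
      idx <- which(code == cd)
      gl <- base[idx]
      for (tri in .mt_cases[[cd + 1]]) {
        A <- cbind(gl + coff[corners[tri[1, 1]]],
                   gl + coff[corners[tri[2, 1]]],
                   gl + coff[corners[tri[3, 1]]])
        B <- cbind(gl + coff[corners[tri[1, 2]]],
                   gl + coff[corners[tri[2, 2]]],
                   gl + coff[corners[tri[3, 2]]])
        tri_a[[length(tri_a) + 1]] <- A
        tri_b[[length(tri_b) + 1]] <- B
      }
    }
  }
  A <- do.call(rbind, tri_a); B <- do.call(rbind, tri_b)
  lo <- pmin(A, B); hi <- pmax(A, B)
  key <- paste(lo, hi)                      # canonical edge key per tri corner
  uk <- unique(as.vector(key))
  vid <- matrix(match(key, uk), nrow(A), 3)
  # vertex positions: midpoints of the two grid points, shifted back by the
  # 1-voxel padding
  klo <- as.integer(sub(" .*", "", uk)); khi <- as.integer(sub(".* ", "", uk))
  p1 <- arrayInd(klo, d); p2 <- arrayInd(khi, d)
  verts <- (p1 + p2) / 2 - 1   # undo padding offset
  list(vertices = verts, faces = vid)
}

# ---- mesh utilities --------------------------------------------------------

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and no face is degenerate.
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) return(FALSE)
  e <- mesh_edges(f)
  cnt <- table(paste(e[, 1], e[, 2]))
  all(cnt == 2)
}

#' Euler characteristic (V - E + F)
#' @param mesh a `surface_mesh`.
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  e <- unique(mesh_edges(mesh$faces))
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

#' Enclosed mesh volume
#'
#' Signed-tetrahedron (divergence theorem) volume; positive for outward
#' orientation. Units follow the vertex units (nm^3 for extracted meshes).
#' @param mesh a `surface_mesh`.
#' @return numeric volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  n
}

face_areas <- function(mesh) {
  sqrt(rowSums(face_normals(mesh, normalize = FALSE)^2)) / 2
}

# Make face windings globally consistent (BFS over the face-adjacency graph),
# then flip everything if the signed volume is negative, so normals point
# outward. Assumes a watertight orientable surface.
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  e <- mesh_edges(f)
  fid <- rep(seq_len(nf), 3)
  key <- paste(e[, 1], e[, 2])
  ord <- order(key)
  key_s <- key[ord]; fid_s <- fid[ord]
  first <- !duplicated(key_s)
  # pairs of faces sharing each edge
  i1 <- which(first); i2 <- i1 + 1L
  fa <- fid_s[i1]; fb <- fid_s[i2]
  adj <- split(c(fb, fa), c(fa, fb))
  visited <- logical(nf); flip <- logical(nf)
  directed_has <- function(face, a, b) {
    # TRUE if directed edge a->b occurs in face's (possibly flipped) winding
    w <- f[face, ]; if (flip[face]) w <- rev(w)
    (w[1] == a && w[2] == b) || (w[2] == a && w[3] == b) || (w[3] == a && w[1] == b)
  }
  queue <- integer(0)
  for (root in seq_len(nf)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      w <- f[cur, ]; if (flip[cur]) w <- rev(w)
      for (nb in adj[[as.character(cur)]]) {
        if (visited[nb]) next
        # shared edge between cur and nb
        shared <- intersect(f[cur, ], f[nb, ])
        a <- shared[1]; b <- shared[2]
        cur_dir <- directed_has(cur, a, b)
        ab <- if (cur_dir) c(a, b) else c(b, a)
        # consistent orientation: neighbour must traverse the edge oppositely
        if (directed_has(nb, ab[1], ab[2])) flip[nb] <- TRUE
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  f[flip, ] <- f[flip, c(3, 2, 1)]
  out <- surface_mesh(mesh$vertices, f, mesh$object_id)
  if (mesh_volume(out) < 0) out$faces <- out$faces[, c(3, 2, 1)]
  out
}

# Uniform-weight Laplacian smoothing: v <- v + lambda * (neighbour mean - v).
laplacian_smooth <- function(vertices, faces, iters = 10, lambda = 0.5) {
  if (iters < 1) return(vertices)
  e <- unique(mesh_edges(faces))
  n <- nrow(vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  V <- vertices
  for (i in seq_len(iters)) {
    V <- (1 - lambda) * V + lambda * as.matrix(A %*% V) / deg
  }
  V
}

# Shortest-edge-collapse simplification with link-condition checks; stops at
# target_faces or when no further safe collapse exists. Watertightness is
# re-verified per pass and the last valid state is kept.
simplify_mesh <- function(vertices, faces, target_faces) {
  V <- vertices; F0 <- faces
  repeat {
    if (nrow(F0) <= target_faces) break
    e <- unique(mesh_edges(F0))
    len <- rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2)
    ord <- order(len)
    nbr <- vector("list", nrow(V))
    for (k in seq_len(nrow(e))) {
      nbr[[e[k, 1]]] <- c(nbr[[e[k, 1]]], e[k, 2])
      nbr[[e[k, 2]]] <- c(nbr[[e[k, 2]]], e[k, 1])
    }
    touched <- logical(nrow(V))
    mapto <- seq_len(nrow(V))
    ncol_budget <- (nrow(F0) - target_faces) %/% 2 + 1
    done <- 0L
    for (k in ord) {
      if (done >= ncol_budget) break
      a <- e[k, 1]; b <- e[k, 2]
      if (touched[a] || touched[b]) next
      common <- intersect(nbr[[a]], nbr[[b]])
      if (length(common) != 2) next       # link condition (manifold edge)
      if (any(touched[common])) next
      # collapse b into a at the midpoint
      V[a, ] <- (V[a, ] + V[b, ]) / 2
      mapto[b] <- a
      touched[c(a, b, nbr[[a]], nbr[[b]])] <- TRUE
      done <- done + 1L
    }
    if (done == 0L) break
    F1 <- matrix(mapto[F0], ncol = 3)
    F1 <- F1[!(F1[, 1] == F1[, 2] | F1[, 2] == F1[, 3] | F1[, 1] == F1[, 3]), , drop = FALSE]
    # drop now-unreferenced vertices
    used <- sort(unique(as.vector(F1)))
    remap <- integer(nrow(V)); remap[used] <- seq_along(used)
    V1 <- V[used, , drop = FALSE]
    F1 <- matrix(remap[F1], ncol = 3)
    m1 <- surface_mesh(V1, F1)
    if (!is_watertight(m1)) break         # keep last valid state
    V <- V1; F0 <- F1
  }
  list(vertices = V, faces = F0)
}

#' Build a watertight surface mesh of a labelled object
#'
#' Extracts the isosurface of the object's binary mask by marching
#' tetrahedra (an ambiguity-free member of the marching-cubes family whose
#' output is watertight by construction), applies uniform Laplacian
#' smoothing, simplifies toward `target_faces` by link-condition-checked
#' shortest-edge collapse, and orients faces outward. Vertices are scaled to
#' physical nm by `voxel_size_nm`.
#'
#' @param labels 3D integer label array.
#' @param object_id label id to mesh.
#' @param smoothing_iters Laplacian smoothing iterations (default 10).
#' @param target_faces simplification target (default 5000; simplification
#'   stops early rather than break watertightness).
#' @param voxel_size_nm voxel size `(z, y, x)` in nm.
#' @return A `surface_mesh` (vertex columns `(z, y, x)` in nm).
#' @export
build_mesh <- function(labels, object_id, smoothing_iters = 10,
                       target_faces = 5000, voxel_size_nm = c(1, 1, 1)) {
  mask <- labels == object_id
  bb <- mask_bbox(mask)
  assert_that(!is.null(bb), sprintf("object %s not present in labels", object_id))
  ext <- bb$hi - bb$lo + 1L
  assert_that(all(ext >= 2), sprintf("object %s smaller than 2 voxels in some axis", object_id))
  sub <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  mt <- marching_tets(sub)
  verts <- mt$vertices
  verts <- sweep(verts, 2, as.numeric(bb$lo) - 1)   # back to global voxel coords
  verts <- laplacian_smooth(verts, mt$faces, iters = smoothing_iters)
  sm <- simplify_mesh(verts, mt$faces, target_faces)
  mesh <- surface_mesh(sweep(sm$vertices, 2, voxel_size_nm, `*`), sm$faces, object_id)
  mesh <- orient_mesh(mesh)
  assert_that(is_watertight(mesh),
              sprintf("mesh for object %s is not watertight after repair", object_id))
  mesh
}

# ---- PLY I/O ---------------------------------------------------------------

#' Write / read a mesh as PLY
#'
#' Binary little-endian PLY (or ASCII with `binary = FALSE`). On disk the
#' vertex properties are the conventional `x, y, z`, mapped from the
#' internal `(z, y, x)` columns.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path` invisibly (writer); a `surface_mesh` (reader).
#' @export
write_ply <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices[, c(3, 2, 1), drop = FALSE]   # x, y, z on disk
  f <- mesh$faces - 1L
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(v, 1, paste, collapse = " "), con)
    writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    l <- readLines(con, n = 1)
    hdr <- c(hdr, l)
    if (identical(l, "end_header")) break
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  binary <- any(grepl("binary_little_endian", hdr))
  if (binary) {
    v <- matrix(readBin(con, "numeric", n = 3 * nv, size = 4, endian = "little"),
                ncol = 3, byrow = TRUE)
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      readBin(con, "raw", n = 1)
      f[i, ] <- readBin(con, "integer", n = 3, size = 4, endian = "little")
    }
  } else {
    txt <- readLines(con)
    v <- matrix(as.numeric(unlist(strsplit(txt[seq_len(nv)], " "))), ncol = 3, byrow = TRUE)
    fl <- strsplit(txt[nv + seq_len(nf)], " ")
    f <- t(vapply(fl, function(x) as.integer(x[2:4]), integer(3)))
  }
  surface_mesh(v[, c(3, 2, 1), drop = FALSE], f + 1L)
}
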