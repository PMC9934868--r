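#' Point cloud sampled from a mesh surface
#'
#' Samples `n` points uniformly by surface area: faces are drawn with
#' probability proportional to their area and points placed by uniform
#' barycentric coordinates. Each point carries the outward unit normal of
#' its face. This is the shape-encoder input representation (the reference
#' pipeline samples 1024 points per surface).
#'
#' @param mesh a watertight `surface_mesh`.
#' @param n number of points (>= 1; default 1024).
#' @param seed RNG seed for deterministic sampling.
#' @return A `point_cloud`: `points` (n x 3, same units/axis order as the
#'   mesh), `normals` (n x 3 unit vectors), `n`.
#' @export
sample_point_cloud <- function(mesh, n = 1024L, seed = NULL) {
  assert_that(n >= 1, "n must be >= 1")
  assert_that(nrow(mesh$faces) > 0, "empty mesh")
  with_seed(seed, {
    areas <- face_areas(mesh)
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    u <- runif(n); v <- runif(n)
    over <- u + v > 1
    u[over] <- 1 - u[over]; v[over] <- 1 - v[over]
    f <- mesh$faces[fi, , drop = FALSE]
    a <- mesh$vertices[f[, 1], , drop = FALSE]
    b <- mesh$vertices[f[, 2], , drop = FALSE]
    c3 <- mesh$vertices[f[, 3], , drop = FALSE]
    pts <- a + u * (b - a) + v * (c3 - a)
    nrm <- face_normals(mesh)[fi, , drop = FALSE]
    structure(list(points = pts, normals = nrm, n = as.integer(n)),
              class = "point_cloud")
  })
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points with unit normals\n", x$n))
  invisible(x)
}
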