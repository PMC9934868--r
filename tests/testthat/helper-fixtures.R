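# Shared fixtures, built in code and cached for the test session.

.fixtures <- new.env(parent = emptyenv())

# small mirrored phantom used across modules
small_phantom <- function() {
  if (is.null(.fixtures$phantom)) {
    .fixtures$phantom <- generate_phantom(phantom_spec(n_cell_pairs = 4, seed = 7))
  }
  .fixtures$phantom
}

# voxelised ball label array
ball_labels <- function(r, n = 2 * r + 5) {
  c0 <- (n + 1) / 2
  g <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  array(as.integer((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2), dim = c(n, n, n))
}

ball_mesh <- function(r = 8, target_faces = 1200) {
  key <- sprintf("ball_%d_%d", r, target_faces)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_mesh(ball_labels(r), 1, target_faces = target_faces)
  }
  .fixtures[[key]]
}

random_point_cloud <- function(n = 12, seed = 3) {
  set.seed(seed)
  nrm <- matrix(rnorm(3 * n), n, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  structure(list(points = matrix(rnorm(3 * n), n, 3), normals = nrm, n = as.integer(n)),
            class = "point_cloud")
}

# random-weight checkpoints for the desk profile
random_checkpoints <- function(config = pipeline_config("desk"), seed = 5) {
  cks <- list()
  for (comp in c("cell", "nuc")) {
    cks[[paste0(comp, "_shape")]] <-
      list(weights = init_shape_encoder(config$shape, seed = seed),
           encoder_cfg = config$shape)
    for (gran in c("coarse", "fine")) {
      cks[[paste0(comp, "_", gran)]] <-
        list(weights = init_texture_encoder(config$texture, seed = seed + 1),
             encoder_cfg = config$texture)
    }
  }
  cks
}

# brute-force fine-patch count over the same tiling (independent oracle)
oracle_patch_count <- function(volume, id, compartment, patch_size, upsample = 1L) {
  mask <- if (compartment == "cytoplasm") {
    volume$cell_labels == id & volume$nucleus_labels != id
  } else {
    volume$nucleus_labels == id
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  f <- rep(upsample, length.out = 3)
  m <- m[rep(seq_len(dim(m)[1]), each = f[1]),
         rep(seq_len(dim(m)[2]), each = f[2]),
         rep(seq_len(dim(m)[3]), each = f[3]), drop = FALSE]
  d <- dim(m)
  cnt <- 0L
  for (iz in seq_len(ceiling(d[1] / patch_size))) {
    for (iy in seq_len(ceiling(d[2] / patch_size))) {
      for (ix in seq_len(ceiling(d[3] / patch_size))) {
        lo2 <- (c(iz, iy, ix) - 1L) * patch_size + 1L
        hi2 <- pmin(lo2 + patch_size - 1L, d)
        occ <- sum(m[lo2[1]:hi2[1], lo2[2]:hi2[2], lo2[3]:hi2[3]]) / patch_size^3
        if (occ > 0.5) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# exhaustive 6-neighbour adjacency oracle
oracle_adjacency <- function(labels) {
  d <- dim(labels)
  pairs <- character(0)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    a <- labels[z, y, x]
    if (a == 0) next
    for (s in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      p <- c(z, y, x) + s
      if (any(p > d)) next
      b <- labels[p[1], p[2], p[3]]
      if (b != 0 && b != a) pairs <- c(pairs, paste(min(a, b), max(a, b)))
    }
  }
  sort(unique(pairs))
}
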