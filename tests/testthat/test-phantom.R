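test_that("phantom construction honours counts, determinism and containment", {
  ph <- small_phantom()
  ids <- sort(setdiff(unique(as.vector(ph$cell_labels)), 0L))
  nids <- sort(setdiff(unique(as.vector(ph$nucleus_labels)), 0L))
  expect_length(ids, 8)
  expect_identical(ids, nids)                     # cell/nucleus ids paired 1:1

  # every nucleus strictly inside its own cell's support
  for (id in ids) {
    nuc <- which(ph$nucleus_labels == id)
    expect_gt(length(nuc), 0)
    expect_true(all(ph$cell_labels[nuc] == id))
  }

  # bit-identical regeneration from the same spec
  ph2 <- generate_phantom(phantom_spec(n_cell_pairs = 4, seed = 7))
  expect_identical(ph$raw, ph2$raw)
  expect_identical(ph$cell_labels, ph2$cell_labels)
  expect_identical(ph$truth, ph2$truth)
})

test_that("mirrored partner centroids agree across the mid-plane (brute force)", {
  ph <- small_phantom()
  nx <- dim(ph$raw)[3]
  for (i in seq_len(nrow(ph$truth))) {
    id <- ph$truth$cell_id[i]
    # recompute centroid by brute force over label voxels
    vox <- which(ph$cell_labels == id, arr.ind = TRUE)
    com <- colMeans(vox)
    partner <- ph$truth$partner_id[i]
    vox_p <- which(ph$cell_labels == partner, arr.ind = TRUE)
    com_p <- colMeans(vox_p)
    expect_equal(com_p[1], com[1], tolerance = 1e-8)
    expect_equal(com_p[2], com[2], tolerance = 1e-8)
    expect_lt(abs((nx + 1 - com[3]) - com_p[3]), 1)
  }
  # partner relation is a symmetric involution between sides
  tr <- ph$truth
  expect_identical(tr$partner_id[match(tr$partner_id, tr$cell_id)], tr$cell_id)
  expect_true(all(tr$side[match(tr$partner_id, tr$cell_id)] != tr$side))
})

test_that("contact_fraction 1 makes every cell touch and 0 isolates all cells", {
  p1 <- generate_phantom(phantom_spec(n_cell_pairs = 5, contact_fraction = 1, seed = 3))
  adj <- morphodesc:::label_adjacency(p1$cell_labels)
  touched <- unique(c(adj$a, adj$b))
  expect_setequal(touched, p1$truth$cell_id)
  p0 <- generate_phantom(phantom_spec(n_cell_pairs = 5, contact_fraction = 0, seed = 3))
  expect_identical(nrow(morphodesc:::label_adjacency(p0$cell_labels)), 0L)
})

test_that("texture classes are separable by construction", {
  ph <- small_phantom()
  tr <- ph$truth
  mu <- vapply(split(tr$cell_id, tr$texture_class), function(ids) {
    mean(vapply(ids, function(id) {
      mean(ph$raw[ph$cell_labels == id & ph$nucleus_labels != id])
    }, 0))
  }, 0)
  expect_gte(abs(diff(mu)), 30)

  # linear classifier on (mean intensity, voxel count) separates the classes
  stats <- t(vapply(tr$cell_id, function(id) {
    m <- ph$cell_labels == id & ph$nucleus_labels != id
    c(mean(ph$raw[m]), sum(m))
  }, numeric(2)))
  fit <- suppressWarnings(glmnet::glmnet(cbind(scale(stats), 0), factor(tr$texture_class),
                                         family = "binomial", alpha = 0, lambda = 1e-4))
  pr <- predict(fit, cbind(scale(stats), 0), type = "class")
  expect_equal(mean(pr == tr$texture_class), 1)
})

test_that("expression tables are clipped class-exclusive markers", {
  ph <- small_phantom()
  ex0 <- make_expression_table(ph$truth, markers_per_class = 2, noise_sd = 0, seed = 1)
  classes <- sort(unique(ph$truth$class_id))
  for (cl in classes) {
    col <- ex0[[sprintf("class%d_marker1", cl)]]
    expect_identical(col, as.numeric(ph$truth$class_id == cl))
  }
  ex <- make_expression_table(ph$truth, markers_per_class = 2, noise_sd = 0.2, seed = 1)
  vals <- as.matrix(ex[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_identical(ex, make_expression_table(ph$truth, 2, 0.2, seed = 1))
  expect_error(make_expression_table(ph$truth[0, ]), "empty")
})

test_that("zarr container round-trips volumes losslessly", {
  ph <- small_phantom()
  path <- withr::local_tempdir()
  write_volume(ph, file.path(path, "vol"))
  v2 <- read_volume(file.path(path, "vol"))
  expect_identical(v2$raw, unclass(ph$raw))
  expect_identical(v2$cell_labels, ph$cell_labels)
  expect_identical(v2$nucleus_labels, ph$nucleus_labels)
  expect_equal(v2$voxel_size_nm, ph$voxel_size_nm)
})

test_that("placement failure names the offending cell pair", {
  expect_error(
    generate_phantom(phantom_spec(n_cell_pairs = 100, grid_shape = c(40, 40, 80),
                                  seed = 1)),
    "placement failed")
})
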