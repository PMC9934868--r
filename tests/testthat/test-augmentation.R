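test_that("zero displacement with no rigid part is the identity", {
  mesh <- ball_mesh(8)
  cfg <- deform_config(displacement_scale = 0, scale_range = c(1, 1),
                       rotate = FALSE, mirror = FALSE, seed = 4)
  out <- deform_mesh(mesh, cfg)
  expect_lt(max(abs(out$vertices - mesh$vertices)), 1e-8)
  expect_identical(out$faces, mesh$faces)
})

test_that("deformations keep connectivity, watertightness and determinism", {
  mesh <- ball_mesh(8)
  for (method in c("biharmonic", "arap")) {
    cfg <- deform_config(method = method, seed = 5)
    out <- deform_mesh(mesh, cfg)
    expect_identical(out$faces, mesh$faces)
    expect_identical(nrow(out$vertices), nrow(mesh$vertices))
    expect_true(is_watertight(out))
    expect_true(all(is.finite(out$vertices)))
    expect_equal(deform_mesh(mesh, cfg), out)
  }
})

test_that("biharmonic handle displacement is bounded by the configured scale", {
  mesh <- ball_mesh(8)
  cfg <- deform_config(method = "biharmonic", displacement_scale = 0.05,
                       scale_range = c(1, 1), rotate = FALSE, seed = 5)
  out <- deform_mesh(mesh, cfg)
  diag_len <- sqrt(sum((apply(mesh$vertices, 2, max) -
                          apply(mesh$vertices, 2, min))^2))
  max_disp <- max(sqrt(rowSums((out$vertices - mesh$vertices)^2)))
  # slack 0.25 documented with the config: interpolation may overshoot mildly
  expect_lte(max_disp, 0.05 * diag_len * 1.25)
})

test_that("ARAP propagates a common rigid translation with no distortion", {
  mesh <- ball_mesh(8)
  V <- mesh$vertices
  hidx <- 1:40
  hdisp <- matrix(rep(c(2, 1, 0.5), each = 40), 40, 3)
  Vp <- morphodesc:::arap_deform_positions(V, mesh$faces, hidx, hdisp)
  # per-face shape distortion: singular-value spread of the deformation
  # gradient, computed by brute force per face
  f <- mesh$faces
  spread <- vapply(seq_len(nrow(f)), function(i) {
    E0 <- rbind(V[f[i, 2], ] - V[f[i, 1], ], V[f[i, 3], ] - V[f[i, 1], ])
    E1 <- rbind(Vp[f[i, 2], ] - Vp[f[i, 1], ], Vp[f[i, 3], ] - Vp[f[i, 1], ])
    s <- svd(E1 %*% MASS::ginv(E0))$d[1:2]
    abs(s[1] - 1) + abs(s[2] - 1)
  }, 0)
  expect_lt(max(spread), 1e-5)
})

test_that("mirror composed twice is the identity", {
  mesh <- ball_mesh(8)
  for (ax in 1:3) {
    mm <- morphodesc:::mirror_mesh(morphodesc:::mirror_mesh(mesh, ax), ax)
    expect_lt(max(abs(mm$vertices - mesh$vertices)), 1e-12)
    expect_identical(mm$faces, mesh$faces)
  }
})

test_that("mesh views are distinct, cached, and reproducible", {
  mesh <- ball_mesh(8)
  cfg <- deform_config(seed = 9)
  views <- make_mesh_views(mesh, 10, cfg)
  expect_length(views, 10)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_false(isTRUE(all.equal(views[[i]]$vertices, views[[j]]$vertices)))
  }
  expect_equal(make_mesh_views(mesh, 10, cfg), views)

  # n_views = 1 with no deformation reproduces the original
  cfg0 <- deform_config(displacement_scale = 0, scale_range = c(1, 1),
                        rotate = FALSE, seed = 1)
  v1 <- make_mesh_views(mesh, 1, cfg0)
  expect_lt(max(abs(v1[[1]]$vertices - mesh$vertices)), 1e-8)

  # disk cache round-trip
  dir <- withr::local_tempdir()
  mesh$object_id <- 42L
  a <- make_mesh_views(mesh, 3, cfg, cache_dir = dir)
  expect_true(file.exists(file.path(dir, "42_view1.ply")))
  b <- make_mesh_views(mesh, 3, cfg, cache_dir = dir)
  expect_equal(lapply(b, `[[`, "faces"), lapply(a, `[[`, "faces"))
})

test_that("texture augmentation permutes voxels when the warp is off", {
  set.seed(2)
  crop <- array(runif(24^3), dim = rep(24, 3))
  a <- augment_texture(crop, seed = 9, elastic_cfg = list(amplitude = 0))
  expect_equal(sort(as.vector(a)), sort(as.vector(crop)))
  expect_identical(a, augment_texture(crop, seed = 9,
                                      elastic_cfg = list(amplitude = 0)))
  expect_identical(dim(a), dim(crop))
})

test_that("mild elastic warps preserve mean intensity on smooth fields", {
  z <- seq(0, 3, length.out = 30)
  sm <- array(0.5 + 0.3 * sin(z)[slice.index(array(0, rep(30, 3)), 1)], rep(30, 3))
  for (s in 1:5) {
    a <- augment_texture(sm, seed = s, elastic_cfg = list(amplitude = 2, grid = 4))
    expect_lt(abs(mean(a) - mean(sm)) / mean(sm), 0.02)
  }
})
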