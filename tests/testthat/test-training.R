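# small cached training inputs
train_views <- function() {
  if (is.null(.fixtures$views)) {
    ph <- small_phantom()
    ids <- ph$truth$cell_id
    meshes <- lapply(ids, function(id) build_mesh(ph$cell_labels, id,
                                                  target_faces = 600,
                                                  voxel_size_nm = ph$voxel_size_nm))
    v <- lapply(meshes, function(m) make_mesh_views(m, 3, deform_config(seed = 7)))
    names(v) <- as.character(ids)
    .fixtures$views <- v
  }
  .fixtures$views
}

train_items <- function() {
  if (is.null(.fixtures$items)) {
    ph <- small_phantom()
    .fixtures$items <- lapply(ph$truth$cell_id, function(id) {
      cr <- extract_coarse_crop(ph, id, "cytoplasm", "train", crop_size = 24)
      list(crop = cr$values, mask = cr$values > 0, cell_id = id)
    })
  }
  .fixtures$items
}

test_that("contrastive batches pair the two views at i and i + B", {
  aug <- function(sample, seed) list(v = sample + seed %% 7)
  batch <- make_contrastive_batch(as.list(1:48), aug, seed = 3)
  expect_length(batch$items, 96)
  expect_length(batch$source_ids, 96)
  expect_identical(batch$source_ids[1:48], batch$source_ids[49:96])
  one <- make_contrastive_batch(list(5), aug, seed = 3)
  expect_length(one$items, 2)
  expect_identical(make_contrastive_batch(as.list(1:4), aug, seed = 9),
                   make_contrastive_batch(as.list(1:4), aug, seed = 9))
  expect_error(make_contrastive_batch(list(), aug), "non-empty")
})

test_that("shape training is deterministic and frozen at lr = 0", {
  scfg <- shape_encoder_config(k_neighbours = 4, n_graph_layers = 1,
                               hidden_width = 8, fuse_width = 8, mlp_width = 8,
                               out_dim = 8)
  tcfg <- train_config(n_iterations = 4, batch_size = 3, lr = 1e-3, seed = 11)
  ck1 <- train_shape(train_views(), tcfg, scfg, n_points = 48)
  ck2 <- train_shape(train_views(), tcfg, scfg, n_points = 48)
  expect_identical(ck1$log$loss, ck2$log$loss)
  expect_identical(ck1$weights, ck2$weights)

  init <- init_shape_encoder(scfg, seed = 2)
  tcfg0 <- train_config(n_iterations = 3, batch_size = 3, lr = 1e-12,
                        weight_decay = 0, seed = 11)
  ck0 <- train_shape(train_views(), tcfg0, scfg, n_points = 48, init_weights = init)
  for (nm in names(morphodesc:::flatten_params(init))) {
    expect_equal(morphodesc:::flatten_params(ck0$weights)[[nm]],
                 morphodesc:::flatten_params(init)[[nm]], tolerance = 1e-7)
  }
})

test_that("texture training decays the learning rate geometrically on failure", {
  xcfg <- texture_encoder_config(base_channels = 2, n_blocks = 3,
                                 convs_per_block = 1, out_dim = 8)
  # improvement_factor 0 makes improvement impossible: every evaluation fails
  tcfg <- train_config(lr = 1e-4, weight_decay = 0, n_iterations = 8,
                       batch_size = 3, eval_every = 2, lr_decay = 0.98,
                       improvement_factor = 0, seed = 5)
  ck <- suppressWarnings(train_texture(train_items(), tcfg, xcfg,
                                       elastic_cfg = list(amplitude = 0)))
  # the first evaluation sets the baseline; every later one fails and decays
  # the learning rate geometrically
  expect_equal(ck$log$lr[c(1, 3)], rep(1e-4, 2), tolerance = 1e-12)
  expect_equal(ck$log$lr[c(5, 7)], 1e-4 * 0.98^(1:2), tolerance = 1e-12)
})

test_that("zero mse/l2 weights reduce the texture objective to NT-Xent", {
  xcfg <- texture_encoder_config(base_channels = 2, n_blocks = 3,
                                 convs_per_block = 1, out_dim = 8)
  tcfg <- train_config(lr = 1e-4, loss_weights = c(1, 0, 0), n_iterations = 2,
                       batch_size = 3, eval_every = 10, seed = 5)
  ck <- train_texture(train_items(), tcfg, xcfg,
                      elastic_cfg = list(amplitude = 0))
  expect_equal(ck$log$total, ck$log$ntxent)
})

test_that("checkpoints round-trip bit-identically through disk", {
  scfg <- shape_encoder_config(k_neighbours = 4, n_graph_layers = 1,
                               hidden_width = 8, fuse_width = 8, mlp_width = 8,
                               out_dim = 8)
  tcfg <- train_config(n_iterations = 2, batch_size = 3, lr = 1e-3, seed = 11)
  ck <- train_shape(train_views(), tcfg, scfg, n_points = 48)
  path <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(ck, path)
  expect_true(file.exists(paste0(path, ".json")))
  ck2 <- load_checkpoint(path)
  cloud <- sample_point_cloud(train_views()[[1]][[1]], 48, seed = 3)
  expect_identical(encode_shape(cloud, scfg, ck$weights),
                   encode_shape(cloud, scfg, ck2$weights))
  expect_identical(ck2$weights, ck$weights)
})
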