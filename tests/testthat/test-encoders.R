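test_that("shape embeddings are 80-dimensional and point-order invariant", {
  cfg <- pipeline_config("desk")$shape
  w <- init_shape_encoder(cfg, seed = 5)
  mesh <- ball_mesh(8)
  cloud <- sample_point_cloud(mesh, 64, seed = 2)
  emb <- encode_shape(cloud, cfg, w)
  expect_length(emb, 80)
  expect_true(all(is.finite(emb)))
  set.seed(3)
  perm <- sample(64)
  cloud2 <- cloud
  cloud2$points <- cloud$points[perm, ]
  cloud2$normals <- cloud$normals[perm, ]
  expect_lt(max(abs(encode_shape(cloud2, cfg, w) - emb)), 1e-5)
  expect_error(encode_shape(random_point_cloud(5), cfg, w), "fewer points")
})

test_that("dynamic kNN edges match the brute-force distance matrix", {
  set.seed(1)
  X <- matrix(rnorm(5 * 6), 5, 6)
  idx <- morphodesc:::knn_index(X, 2)
  D <- as.matrix(dist(X))^2
  diag(D) <- Inf
  ref <- t(apply(D, 1, function(r) order(r)[1:2]))
  expect_identical(unname(idx), unname(ref))
})

test_that("shape encoder gradients match central finite differences", {
  cfg <- shape_encoder_config(k_neighbours = 3, n_graph_layers = 2,
                              hidden_width = 5, fuse_width = 6, mlp_width = 4,
                              out_dim = 3)
  p <- init_shape_encoder(cfg, seed = 5)
  cl <- random_point_cloud(10, seed = 3)
  fw <- morphodesc:::shape_forward(cl, p, cfg, cache = TRUE)
  set.seed(4)
  dout <- rnorm(3)
  g <- morphodesc:::flatten_params(morphodesc:::shape_backward(dout, fw, p, cfg))
  fl <- morphodesc:::flatten_params(p)
  err <- 0
  for (nm in names(fl)) {
    ii <- sample(length(fl[[nm]]), min(3, length(fl[[nm]])))
    for (i in ii) {
      p2 <- fl; p2[[nm]][i] <- p2[[nm]][i] + 1e-6
      f1 <- sum(morphodesc:::shape_forward(cl, morphodesc:::unflatten_into(p, p2), cfg) * dout)
      p2[[nm]][i] <- p2[[nm]][i] - 2e-6
      f0 <- sum(morphodesc:::shape_forward(cl, morphodesc:::unflatten_into(p, p2), cfg) * dout)
      err <- max(err, abs((f1 - f0) / 2e-6 - g[[nm]][i]))
    }
  }
  expect_lt(err, 1e-6)
})

test_that("texture embeddings are 80-dimensional with masked pooling", {
  cfg <- pipeline_config("desk")$texture
  w <- init_texture_encoder(cfg, seed = 4)
  set.seed(9)
  crop <- array(runif(16^3), dim = rep(16, 3))
  mask <- array(runif(16^3) > 0.3, dim = rep(16, 3))
  out <- encode_texture(crop, mask, cfg, w)
  expect_length(out$embedding, 80)
  expect_identical(dim(out$feature_maps), c(2L, 2L, 2L, 80L))

  # full mask reduces masked pooling to plain global average pooling
  full <- encode_texture(crop, array(TRUE, dim = rep(16, 3)), cfg, w)
  expect_equal(full$embedding,
               colMeans(matrix(full$feature_maps, 8, 80)))

  # all conv weights and biases zero -> ELU(0) maps and zero embedding
  w0 <- rapply(w, function(x) x * 0, how = "replace")
  out0 <- encode_texture(crop, mask, cfg, w0)
  expect_true(all(out0$embedding == 0))

  expect_error(encode_texture(crop, mask & FALSE, cfg, w), "no informative")
})

test_that("appending an empty masked-out margin leaves the embedding unchanged", {
  cfg <- pipeline_config("desk")$texture
  w <- init_texture_encoder(cfg, seed = 4)
  set.seed(10)
  crop <- array(runif(16^3), dim = rep(16, 3))
  mask <- array(TRUE, dim = rep(16, 3))
  base <- encode_texture(crop, mask, cfg, w)$embedding
  # append 8 voxels of empty, masked-out margin at the far end of each axis
  big <- array(0, dim = rep(24, 3)); big[1:16, 1:16, 1:16] <- crop
  bigmask <- array(FALSE, dim = rep(24, 3)); bigmask[1:16, 1:16, 1:16] <- TRUE
  padded <- encode_texture(big, bigmask, cfg, w)$embedding
  expect_lt(max(abs(padded - base)), 1e-10)
})

test_that("masked global pooling equals the naive loop on 100 random instances", {
  set.seed(42)
  for (i in 1:100) {
    d <- c(sample(2:4, 3, replace = TRUE), sample(1:5, 1))
    maps <- array(rnorm(prod(d)), dim = d)
    mask <- array(runif(prod(d[1:3])) > 0.5, dim = d[1:3])
    if (!any(mask)) mask[1] <- TRUE
    got <- masked_global_pool(maps, mask)
    ref <- numeric(d[4])
    cnt <- 0
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if (mask[z, y, x]) {
        ref <- ref + maps[z, y, x, ]
        cnt <- cnt + 1
      }
    }
    expect_equal(got, ref / cnt)
  }
  # hand cases
  expect_equal(masked_global_pool(array(5, c(2, 2, 1, 3)),
                                  array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))),
               rep(5, 3))
  expect_equal(masked_global_pool(array(c(1, 3), c(2, 1, 1, 1)),
                                  array(c(TRUE, FALSE), c(2, 1, 1))), 1)
  expect_error(masked_global_pool(array(1, c(2, 1, 1, 1)),
                                  array(FALSE, c(2, 1, 1))), "no informative")
})

test_that("the one-block decoder closes shapes at quarter resolution", {
  cfg <- pipeline_config("desk")$texture
  w <- init_texture_encoder(cfg, seed = 4)
  crop <- array(runif(32^3), dim = rep(32, 3))
  out <- encode_texture(crop, crop > -1, cfg, w)
  expect_identical(dim(out$feature_maps), c(4L, 4L, 4L, 80L))
  rec <- decode_texture(out$feature_maps, w)
  expect_identical(dim(rec), rep(8L, 3))
  expect_true(all(is.finite(rec)))
  tgt <- reconstruction_target(crop, dim(rec))
  expect_identical(dim(tgt), dim(rec))
  expect_equal(tgt[1, 1, 1], mean(crop[1:4, 1:4, 1:4]))
  # nearest-upsampling the reconstruction recovers the input shape
  up <- morphodesc:::upsample_nearest(rec, c(4, 4, 4))
  expect_identical(dim(up), dim(crop))

  # zero maps with zero decoder bias decode to zero
  w0 <- w
  w0$dec_conv$b <- w0$dec_conv$b * 0
  w0$dec_out$b <- w0$dec_out$b * 0
  rec0 <- decode_texture(out$feature_maps * 0, w0)
  expect_true(all(rec0 == 0))
})

test_that("texture gradients match central finite differences", {
  cfg <- texture_encoder_config(base_channels = 2, n_blocks = 2,
                                convs_per_block = 2, out_dim = 4)
  p <- init_texture_encoder(cfg, seed = 4)
  set.seed(9)
  crop <- array(runif(8^3), dim = rep(8, 3))
  mask <- array(runif(8^3) > 0.3, dim = rep(8, 3))
  fw <- morphodesc:::texture_forward(crop, mask, p, cfg, cache = TRUE)
  dec <- morphodesc:::decoder_forward(fw$feature_maps, p, cache = TRUE)
  demb <- rnorm(4)
  drec <- array(rnorm(length(dec$out)), dim = dim(dec$out))
  db <- morphodesc:::decoder_backward(drec, dec, p)
  dmaps <- db$dmaps + morphodesc:::nn_maskpool_bwd(demb, dim(fw$feature_maps), fw$mask_ds)
  g <- morphodesc:::accumulate_grads(
    morphodesc:::flatten_params(morphodesc:::texture_backward(dmaps, fw, p, cfg)),
    morphodesc:::flatten_params(db$grads))
  fl <- morphodesc:::flatten_params(p)
  sc <- function(pp) {
    f <- morphodesc:::texture_forward(crop, mask, morphodesc:::unflatten_into(p, pp), cfg)
    d <- morphodesc:::decoder_forward(f$feature_maps, morphodesc:::unflatten_into(p, pp))
    sum(demb * f$embedding) + sum(drec * d)
  }
  err <- 0
  set.seed(1)
  for (nm in names(fl)) {
    ii <- sample(length(fl[[nm]]), min(2, length(fl[[nm]])))
    for (i in ii) {
      p2 <- fl; p2[[nm]][i] <- p2[[nm]][i] + 1e-6
      f1 <- sc(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2e-6
      err <- max(err, abs((f1 - sc(p2)) / 2e-6 - g[[nm]][i]))
    }
  }
  expect_lt(err, 1e-6)
})
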