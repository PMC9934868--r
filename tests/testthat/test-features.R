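test_that("assembled descriptors are 480-dimensional in fixed component order", {
  ph <- small_phantom()
  cfg <- pipeline_config("desk")
  cks <- random_checkpoints(cfg)
  ids <- ph$truth$cell_id[1:3]
  feats <- embed_all(ph, cks, cfg, cell_ids = ids, seed = 2)
  expect_identical(ncol(feats), 481L)
  expect_identical(attr(feats, "layout"),
                   c("cell_shape", "cell_coarse", "cell_fine",
                     "nuc_shape", "nuc_coarse", "nuc_fine"))
  expect_identical(names(feats)[2], "cell_shape_00")
  expect_identical(names(feats)[481], "nuc_fine_79")
  expect_true(all(is.finite(as.matrix(feats[, -1]))))
  expect_error(embed_all(ph, cks[-1], cfg), "missing checkpoint")
})

test_that("fine component is the order-invariant mean of patch embeddings", {
  ph <- small_phantom()
  cfg <- pipeline_config("desk")
  ck <- list(weights = init_texture_encoder(cfg$texture, seed = 6),
             encoder_cfg = cfg$texture)
  id <- ph$truth$cell_id[1]
  fcfg <- cfg$fine$cytoplasm
  fp <- extract_fine_patches(ph, id, "cytoplasm", fcfg$patch_size, fcfg$upsample)
  embs <- vapply(fp$patches, function(p) {
    encode_texture(p, p > 0, cfg$texture, ck$weights)$embedding
  }, numeric(80))
  mean_fwd <- rowMeans(matrix(embs, nrow = 80))
  set.seed(1)
  mean_shuf <- rowMeans(matrix(embs[, sample(ncol(embs))], nrow = 80))
  expect_equal(mean_shuf, mean_fwd)
  # a single-patch cell's fine component is that patch's embedding
  one <- rowMeans(matrix(embs[, 1], nrow = 80))
  expect_equal(one, embs[, 1])
})

test_that("region adjacency graphs match hand geometry", {
  lab <- array(0L, c(4, 4, 8))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[2:3, 2:3, 4:5] <- 2L       # touching 1 on a face
  r <- build_rag(lab)
  expect_identical(nrow(r$edges), 1L)
  expect_identical(c(r$edges$a, r$edges$b), c(1L, 2L))
  expect_identical(r$edges$contact_area, 4L)

  lab[2:3, 2:3, 4:5] <- 0L
  lab[2:3, 2:3, 6:7] <- 2L       # separated by background
  expect_identical(nrow(build_rag(lab)$edges), 0L)
})

test_that("context features average the cell with its neighbours", {
  f <- tibble::tibble(cell_id = 1:3, a = c(1, 3, 10), b = c(2, 4, 20))
  g <- structure(list(nodes = 1:3,
                      edges = tibble::tibble(a = 1L, b = 2L, contact_area = 1L)),
                 class = "region_adjacency_graph")
  ctx <- context_features(f, g)
  expect_identical(ncol(ctx), 5L)
  expect_equal(ctx$ctx_a, c(2, 2, 10))       # isolated node 3 averages itself
  expect_equal(ctx$ctx_b, c(3, 3, 20))
  # all-equal neighbourhood collapses to the shared vector
  f2 <- tibble::tibble(cell_id = 1:3, a = c(7, 7, 7))
  expect_equal(context_features(f2, g)$ctx_a, c(7, 7, 7))
  # linearity: scaling all rows scales neighbourhood parts
  f3 <- f; f3$a <- f$a * 3; f3$b <- f$b * 3
  expect_equal(context_features(f3, g)$ctx_a, ctx$ctx_a * 3)
  # a neighbour without a feature row is an error naming both ids
  g2 <- g; g2$edges <- tibble::tibble(a = 1L, b = 9L, contact_area = 1L)
  expect_error(context_features(f, g2), "9")
})

test_that("standardisation gives zero mean, unit variance, zero for constants", {
  f <- tibble::tibble(cell_id = 1:2, a = c(1, 3), b = c(5, 5))
  s <- standardize_features(f)
  expect_equal(s$a, c(-1, 1))
  expect_equal(s$b, c(0, 0))
  # reusing the saved transform reproduces the standardised table
  tr <- attr(s, "transform")
  expect_equal(standardize_features(f, transform = tr)$a, s$a)
  expect_error(standardize_features(f[1, ]), "at least 2")

  set.seed(8)
  f2 <- tibble::tibble(cell_id = 1:20, x = rnorm(20, 5, 3), y = runif(20))
  s2 <- standardize_features(f2)
  expect_equal(mean(s2$x), 0, tolerance = 1e-12)
  expect_equal(mean(s2$x^2), 1, tolerance = 1e-12)
})

test_that("feature tables round-trip through TSV", {
  f <- tibble::tibble(cell_id = 1:3, cell_shape_00 = c(0.1, -2.5, 3))
  path <- file.path(withr::local_tempdir(), "f.tsv")
  write_feature_table(f, path)
  f2 <- read_feature_table(path)
  expect_equal(as.data.frame(f2), as.data.frame(f))
})
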