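#' End-to-end phantom study
#'
#' The package's desk-scale experiment: generate a bilaterally symmetric
#' phantom volume, train the six encoders self-supervised (contrastive
#' shape training on deformation views; combined contrastive +
#' reconstruction training for coarse and fine texture), assemble the
#' 480-dimensional descriptors with the trained and with randomly
#' initialised weights, and evaluate both with the linear-probe
#' classification protocol and the bilateral symmetric-partner rank metric.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_cell_pairs mirrored pairs in the phantom (default 30).
#' @param config a [pipeline_config()] (default desk profile).
#' @param iterations named iteration counts for `shape`, `coarse`, `fine`
#'   training.
#' @param batch_sizes named source-batch sizes per stage.
#' @param n_candidates candidate partners per cell for the bilateral
#'   metric.
#' @param verbose print stage progress.
#' @return List: `phantom`, `checkpoints`, `features` (trained),
#'   `features_random`, `probe` / `probe_random`
#'   (`morphotype_classification`), `bilateral` (`bilateral_ranking`),
#'   `timings`.
#' @export
run_phantom_study <- function(seed = 1L, n_cell_pairs = 30L,
                              config = pipeline_config("desk"),
                              iterations = c(shape = 200L, shape_nuc = 500L,
                                             coarse = 150L, fine = 100L),
                              batch_sizes = c(shape = 8L, coarse = 6L, fine = 6L),
                              n_candidates = 10L, verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function() Sys.time()
  timings <- list()

  t0 <- tick()
  phantom <- generate_phantom(phantom_spec(n_cell_pairs = n_cell_pairs,
                                           seed = derive_seed(seed, 1)))
  ids <- phantom$truth$cell_id
  timings$phantom <- tick() - t0
  say("phantom: %d cells", length(ids))

  t0 <- tick()
  meshes <- list(cell = list(), nucleus = list())
  for (id in ids) {
    meshes$cell[[as.character(id)]] <-
      build_mesh(phantom$cell_labels, id, config$mesh$smoothing_iters,
                 config$mesh$target_faces, phantom$voxel_size_nm)
    meshes$nucleus[[as.character(id)]] <-
      build_mesh(phantom$nucleus_labels, id, config$mesh$smoothing_iters,
                 config$mesh$target_faces, phantom$voxel_size_nm)
  }
  timings$meshes <- tick() - t0
  say("meshes built")

  t0 <- tick()
  checkpoints <- list()
  for (comp in c("cell", "nuc")) {
    mlist <- if (comp == "cell") meshes$cell else meshes$nucleus
    dcfg <- config$deform[[if (comp == "cell") "cytoplasm" else "nucleus"]]
    views <- lapply(mlist, function(m) {
      vcfg <- dcfg
      vcfg$seed <- derive_seed(seed, 10 + m$object_id)
      make_mesh_views(m, config$n_views, vcfg)
    })
    n_it <- if (comp == "nuc" && "shape_nuc" %in% names(iterations)) {
      iterations[["shape_nuc"]]
    } else iterations[["shape"]]
    tcfg <- train_config(n_iterations = n_it,
                         batch_size = batch_sizes[["shape"]],
                         lr = config$shape_train$lr,
                         weight_decay = config$shape_train$weight_decay,
                         temperature = config$shape_train$temperature,
                         seed = derive_seed(seed, if (comp == "cell") 21 else 22))
    checkpoints[[paste0(comp, "_shape")]] <-
      train_shape(views, tcfg, config$shape, n_points = config$n_points)
    say("%s shape encoder trained", comp)
  }
  timings$shape_training <- tick() - t0

  t0 <- tick()
  compartment <- c(cell = "cytoplasm", nuc = "nucleus")
  for (comp in c("cell", "nuc")) {
    crops <- lapply(ids, function(id) {
      cr <- extract_coarse_crop(phantom, id, compartment[[comp]], "train",
                                crop_size = config$crop_size[[compartment[[comp]]]])
      list(crop = cr$values, mask = cr$values > 0, cell_id = id)
    })
    tcfg <- train_config(n_iterations = iterations[["coarse"]],
                         batch_size = batch_sizes[["coarse"]],
                         lr = config$texture_train$lr,
                         weight_decay = config$texture_train$weight_decay,
                         eval_every = 50L,
                         seed = derive_seed(seed, if (comp == "cell") 23 else 24))
    checkpoints[[paste0(comp, "_coarse")]] <- train_texture(crops, tcfg, config$texture)
    say("%s coarse texture trained", comp)
  }
  timings$coarse_training <- tick() - t0

  t0 <- tick()
  for (comp in c("cell", "nuc")) {
    patches <- list()
    fcfg <- config$fine[[compartment[[comp]]]]
    for (id in ids) {
      fp <- extract_fine_patches(phantom, id, compartment[[comp]], fcfg$patch_size,
                                 upsample = fcfg$upsample)
      for (p in fp$patches) {
        patches[[length(patches) + 1L]] <- list(crop = p, mask = p > 0, cell_id = id)
      }
    }
    tcfg <- train_config(n_iterations = iterations[["fine"]],
                         batch_size = batch_sizes[["fine"]],
                         lr = config$texture_train$lr,
                         weight_decay = config$texture_train$weight_decay,
                         eval_every = 50L,
                         seed = derive_seed(seed, if (comp == "cell") 25 else 26))
    checkpoints[[paste0(comp, "_fine")]] <- train_texture(patches, tcfg, config$texture)
    say("%s fine texture trained", comp)
  }
  timings$fine_training <- tick() - t0

  random_checkpoints <- list()
  for (comp in c("cell", "nuc")) {
    random_checkpoints[[paste0(comp, "_shape")]] <-
      list(weights = init_shape_encoder(config$shape, seed = derive_seed(seed, 31)),
           encoder_cfg = config$shape)
    for (gran in c("coarse", "fine")) {
      random_checkpoints[[paste0(comp, "_", gran)]] <-
        list(weights = init_texture_encoder(config$texture, seed = derive_seed(seed, 32)),
             encoder_cfg = config$texture)
    }
  }

  t0 <- tick()
  features <- embed_all(phantom, checkpoints, config, meshes = meshes,
                        seed = derive_seed(seed, 41))
  features_random <- embed_all(phantom, random_checkpoints, config, meshes = meshes,
                               seed = derive_seed(seed, 41))
  timings$embedding <- tick() - t0
  excl <- attr(features, "excluded")
  say("embeddings assembled: %d x %d (%d excluded)", nrow(features),
      ncol(features) - 1, nrow(excl))

  t0 <- tick()
  truth <- phantom$truth[phantom$truth$cell_id %in% features$cell_id, ]
  labels <- tibble::tibble(cell_id = truth$cell_id,
                           label = paste0("class", truth$class_id))
  probe <- classify_morphotypes(features, labels, seed = derive_seed(seed, 51))
  probe_random <- classify_morphotypes(features_random[
    features_random$cell_id %in% features$cell_id, ], labels,
    seed = derive_seed(seed, 51))
  cands <- bilateral_candidates(truth, dim(phantom$raw), n_candidates)
  bilateral <- bilateral_distance(standardize_features(features), cands)
  bilateral_random <- bilateral_distance(standardize_features(features_random), cands)
  timings$evaluation <- tick() - t0

  list(phantom = phantom, checkpoints = checkpoints, features = features,
       features_random = features_random, probe = probe,
       probe_random = probe_random, bilateral = bilateral,
       bilateral_random = bilateral_random, timings = timings)
}
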