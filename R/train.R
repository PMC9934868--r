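#' Training configuration
#'
#' Optimisation settings for the contrastive (shape) and combined
#' (texture) objectives. Defaults follow the reference schedule: Adam with
#' learning rate 2e-4 / weight decay 4e-4 for shape encoders and 1e-4 /
#' 5e-5 for texture models; validation every `eval_every` iterations with
#' best-checkpoint keeping; a validation score counts as improved only if
#' it drops below `improvement_factor` x best-so-far, otherwise the
#' learning rate is multiplied by `lr_decay`.
#'
#' @param temperature NT-Xent temperature (> 0).
#' @param loss_weights `(w_ntxent, w_mse, w_l2)` for the texture objective.
#' @param lr Adam learning rate.
#' @param weight_decay additive L2 weight decay.
#' @param n_iterations training iterations.
#' @param batch_size source samples per iteration (the augmented batch is
#'   twice this size).
#' @param eval_every validation cadence in iterations.
#' @param lr_decay multiplicative LR decay on a failed evaluation.
#' @param improvement_factor relative-improvement threshold.
#' @param val_fraction fraction of samples held out for validation.
#' @param seed RNG seed for the whole run.
#' @return A `train_config`.
#' @export
train_config <- function(temperature = 0.5, loss_weights = c(1, 1, 1e-4),
                         lr = 2e-4, weight_decay = 4e-4,
                         n_iterations = 300L, batch_size = 48L,
                         eval_every = 100L, lr_decay = 0.98,
                         improvement_factor = 0.95, val_fraction = 0.1,
                         seed = 1L) {
  assert_that(temperature > 0, "temperature must be > 0")
  assert_that(lr > 0, "lr must be > 0")
  structure(list(temperature = temperature, loss_weights = loss_weights,
                 lr = lr, weight_decay = weight_decay,
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 eval_every = as.integer(eval_every), lr_decay = lr_decay,
                 improvement_factor = improvement_factor,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Build a contrastive batch
#'
#' Creates two independent augmented views per source sample and orders the
#' result so items `i` and `i + B` are the views of source `i` (B = number
#' of sources): 48 source cells therefore yield a 96-item batch.
#'
#' @param samples non-empty list of source samples.
#' @param augmenter `function(sample, seed)` returning one augmented item.
#' @param seed RNG seed; item seeds are derived from it.
#' @return `list(items, source_ids)` with `length(items) == 2 * length(samples)`.
#' @export
make_contrastive_batch <- function(samples, augmenter, seed = 1L) {
  assert_that(length(samples) > 0, "samples must be non-empty")
  B <- length(samples)
  items <- vector("list", 2L * B)
  for (i in seq_len(B)) {
    items[[i]] <- augmenter(samples[[i]], derive_seed(seed, 2L * i - 1L))
    items[[i + B]] <- augmenter(samples[[i]], derive_seed(seed, 2L * i))
  }
  ids <- names(samples) %||% as.character(seq_len(B))
  list(items = items, source_ids = c(ids, ids))
}

# rigid on-the-fly augmentation of a point cloud (rotation + mild
# anisotropic scaling); normals are rotated with the points
rigid_augment_cloud <- function(cloud, scale_range = c(0.95, 1.05)) {
  R <- random_rotation()
  s <- runif(3, scale_range[1], scale_range[2])
  pts <- sweep(cloud$points, 2, colMeans(cloud$points))
  pts <- sweep(pts, 2, s, `*`) %*% t(R)
  nrm <- cloud$normals %*% t(R)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  structure(list(points = pts, normals = nrm, n = cloud$n), class = "point_cloud")
}

#' Train a shape encoder contrastively
#'
#' Pure NT-Xent optimisation of the point-cloud encoder. Each iteration
#' samples `batch_size` objects, draws two distinct cached deformation
#' views per object, samples a point cloud from each view, applies an
#' independent rigid augmentation, and updates the encoder with Adam.
#' Cell and nucleus encoders are trained independently with this routine.
#'
#' @param views named list: object id -> list of `surface_mesh` views (from
#'   [make_mesh_views()]); at least 2 views per object.
#' @param cfg a [train_config()] (reference shape settings: lr 2e-4, weight
#'   decay 4e-4, 48 sources -> 96-item batches).
#' @param encoder_cfg a [shape_encoder_config()].
#' @param n_points points sampled per view.
#' @param init_weights optional warm-start parameters.
#' @return A checkpoint: `list(weights, encoder_cfg, train_cfg, log)` with a
#'   per-iteration loss tibble.
#' @export
train_shape <- function(views, cfg = train_config(), encoder_cfg = shape_encoder_config(),
                        n_points = 1024L, init_weights = NULL) {
  assert_that(length(views) >= 2, "need at least 2 objects for contrastive training")
  with_seed(cfg$seed, {
    params <- init_weights %||% init_shape_encoder(encoder_cfg)
    flat <- flatten_params(params)
    state <- adam_init(flat)
    lr <- cfg$lr
    log <- vector("list", cfg$n_iterations)
    nobj <- length(views)
    for (it in seq_len(cfg$n_iterations)) {
      B <- min(cfg$batch_size, nobj)
      pick <- sample.int(nobj, B)
      clouds <- vector("list", 2L * B)
      for (b in seq_len(B)) {
        vs <- views[[pick[b]]]
        vi <- sample.int(length(vs), 2)          # two distinct cached views
        clouds[[b]] <- rigid_augment_cloud(sample_point_cloud(vs[[vi[1]]], n_points))
        clouds[[b + B]] <- rigid_augment_cloud(sample_point_cloud(vs[[vi[2]]], n_points))
      }
      fws <- lapply(clouds, shape_forward, params = params, cfg = encoder_cfg, cache = TRUE)
      Z <- do.call(rbind, lapply(fws, `[[`, "out"))
      ls <- nt_xent_loss(Z, cfg$temperature, grad = TRUE)
      if (!is.finite(ls$value)) stop("NaN loss in shape training", call. = FALSE)
      acc <- NULL
      for (m in seq_along(fws)) {
        g <- shape_backward(ls$grad[m, ], fws[[m]], params, encoder_cfg)
        acc <- accumulate_grads(acc, flatten_params(g))
      }
      st <- adam_step(flat, acc, state, lr, cfg$weight_decay)
      flat <- st$params; state <- st$state
      params <- unflatten_into(params, flat)
      log[[it]] <- c(iteration = it, loss = ls$value, lr = lr)
    }
    list(weights = params, encoder_cfg = encoder_cfg, train_cfg = cfg,
         log = tibble::as_tibble(do.call(rbind, log)))
  })
}

# paired crop+mask augmentation sharing one seed so the mask warps with the
# intensities
augment_crop_pair <- function(crop, mask, seed, elastic_cfg) {
  with_seed(seed, {
    tr <- draw_texture_transform(dim(crop), elastic_cfg)
    a <- apply_texture_transform(crop, tr)
    m <- apply_texture_transform(mask * 1, tr) > 0.5
    if (!any(m)) m <- array(TRUE, dim = dim(a))   # degenerate warp: keep all
    list(crop = a, mask = m)
  })
}

#' Train a texture model (encoder + decoder)
#'
#' Optimises the combined objective: NT-Xent on pooled embeddings + MSE
#' between the one-block decoder reconstruction and the local-mean
#' downsampled input + L2 penalty on the bottleneck maps. Every
#' `eval_every` iterations the total loss on a held-out validation split is
#' computed; the best parameters are kept, and the learning rate is
#' multiplied by `lr_decay` whenever the score fails the relative
#' improvement criterion (new < `improvement_factor` x best).
#'
#' @param items list of `list(crop, mask, cell_id)` at one granularity
#'   (coarse crops or fine patches).
#' @param cfg a [train_config()] (reference texture settings: lr 1e-4,
#'   weight decay 5e-5; batches of 12/16 coarse, 32 fine).
#' @param encoder_cfg a [texture_encoder_config()].
#' @param elastic_cfg elastic augmentation settings (see
#'   [augment_texture()]).
#' @param init_weights optional warm-start parameters.
#' @return A checkpoint: `list(weights, encoder_cfg, train_cfg, log)`;
#'   `weights` are the best-validation parameters.
#' @export
train_texture <- function(items, cfg = train_config(lr = 1e-4, weight_decay = 5e-5,
                                                    batch_size = 12L),
                          encoder_cfg = texture_encoder_config(),
                          elastic_cfg = list(amplitude = 1.5, grid = 4),
                          init_weights = NULL) {
  assert_that(length(items) >= 2, "need at least 2 items")
  with_seed(cfg$seed, {
    params <- init_weights %||% init_texture_encoder(encoder_cfg)
    flat <- flatten_params(params)
    state <- adam_init(flat)
    lr <- cfg$lr
    nval <- max(1L, floor(length(items) * cfg$val_fraction))
    vidx <- sample.int(length(items), nval)
    tidx <- setdiff(seq_along(items), vidx)
    assert_that(length(tidx) >= 2, "too few training items after validation split")
    best <- Inf; best_params <- params
    log <- list()
    for (it in seq_len(cfg$n_iterations)) {
      B <- min(cfg$batch_size, length(tidx))
      pick <- sample(tidx, B)
      seeds <- sample.int(1e8, 2L * B)
      fb <- texture_batch_step(items, pick, seeds, params, encoder_cfg, cfg,
                               elastic_cfg, grad = TRUE)
      if (!is.finite(fb$loss$total)) stop("NaN loss in texture training", call. = FALSE)
      st <- adam_step(flat, fb$grads, state, lr, cfg$weight_decay)
      flat <- st$params; state <- st$state
      params <- unflatten_into(params, flat)
      entry <- c(iteration = it, total = fb$loss$total, fb$loss$parts, lr = lr)
      if (it %% cfg$eval_every == 0L) {
        vseeds <- vapply(seq_len(2L * length(vidx)), function(k) derive_seed(cfg$seed, k), 0L)
        vl <- texture_batch_step(items, vidx, vseeds, params, encoder_cfg, cfg,
                                 elastic_cfg, grad = FALSE)$loss$total
        improved <- if (is.finite(best)) vl < cfg$improvement_factor * best else TRUE
        if (improved) {
          best <- vl; best_params <- params
        } else {
          lr <- lr * cfg$lr_decay
        }
        entry <- c(entry, val = vl)
      }
      log[[length(log) + 1L]] <- entry
    }
    if (!is.finite(best)) best_params <- params
    log_tbl <- dplyr::bind_rows(lapply(log, function(e) tibble::as_tibble(as.list(e))))
    list(weights = best_params, encoder_cfg = encoder_cfg, train_cfg = cfg,
         log = log_tbl)
  })
}

# one forward (and optionally backward) pass over a texture batch
texture_batch_step <- function(items, pick, seeds, params, encoder_cfg, cfg,
                               elastic_cfg, grad = TRUE) {
  B <- length(pick)
  aug <- vector("list", 2L * B)
  for (b in seq_len(B)) {
    it0 <- items[[pick[b]]]
    aug[[b]] <- augment_crop_pair(it0$crop, it0$mask, seeds[2 * b - 1], elastic_cfg)
    aug[[b + B]] <- augment_crop_pair(it0$crop, it0$mask, seeds[2 * b], elastic_cfg)
  }
  fws <- lapply(aug, function(a) texture_forward(a$crop, a$mask, params, encoder_cfg,
                                                 cache = grad))
  Z <- do.call(rbind, lapply(fws, `[[`, "embedding"))
  decs <- lapply(fws, function(f) decoder_forward(f$feature_maps, params, cache = grad))
  recs <- lapply(decs, function(d) if (grad) d$out else d)
  tgts <- lapply(seq_along(aug), function(m) {
    reconstruction_target(aug[[m]]$crop, dim(recs[[m]]))
  })
  maps <- lapply(fws, `[[`, "feature_maps")
  loss <- combined_texture_loss(Z, recs, tgts, maps, cfg$loss_weights, cfg$temperature)
  if (!grad) return(list(loss = loss))
  ntx <- nt_xent_loss(Z, cfg$temperature, grad = TRUE)
  w <- cfg$loss_weights
  acc <- NULL
  M <- length(fws)
  for (m in seq_len(M)) {
    drec <- 2 * (recs[[m]] - tgts[[m]]) / length(recs[[m]]) / M * w[2]
    db <- decoder_backward(drec, decs[[m]], params)
    dmaps <- db$dmaps
    dmaps <- dmaps + 2 * maps[[m]] / length(maps[[m]]) / M * w[3]
    demb <- ntx$grad[m, ] * w[1]
    dmaps <- dmaps + nn_maskpool_bwd(demb, dim(maps[[m]]), fws[[m]]$mask_ds)
    g <- texture_backward(dmaps, fws[[m]], params, encoder_cfg)
    acc <- accumulate_grads(acc, flatten_params(g))
    acc <- accumulate_grads(acc, flatten_params(db$grads))
  }
  list(loss = loss, grads = acc)
}

#' Save / load a model checkpoint
#'
#' Single-file RDS archive with a JSON sidecar recording the configs and
#' package version.
#'
#' @param checkpoint a checkpoint list from [train_shape()] /
#'   [train_texture()].
#' @param path file path (`.rds`; the sidecar adds `.json`).
#' @return `path` invisibly (save); the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  meta <- list(encoder_cfg = unclass(checkpoint$encoder_cfg),
               train_cfg = unclass(checkpoint$train_cfg),
               package_version = as.character(utils::packageVersion("morphodesc")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
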