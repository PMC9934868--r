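#' Texture encoder configuration
#'
#' A fully convolutional 3D encoder in the U-Net-encoder style: `n_blocks`
#' blocks of 3x3x3 convolutions with ELU activations separated by 2x2x2 max
#' pooling; channel count starts at `base_channels` and doubles per block.
#' A final 1x1x1 convolution + ELU reduces the channels to `out_dim` (80),
#' and a masked global average pool over the informative positions yields
#' the embedding. The pre-pool 80-channel maps are the autoencoder
#' bottleneck consumed by [decode_texture()].
#'
#' @param base_channels channels of the first block (reference width 64;
#'   smaller widths are used for desk-scale training).
#' @param n_blocks number of conv+pool blocks (default 3).
#' @param convs_per_block 3x3x3 convolutions per block (default 2).
#' @param out_dim embedding length (default 80).
#' @return A `texture_encoder_config`.
#' @export
texture_encoder_config <- function(base_channels = 64L, n_blocks = 3L,
                                   convs_per_block = 2L, out_dim = 80L) {
  assert_that(base_channels >= 1 && n_blocks >= 1, "invalid texture config")
  structure(list(base_channels = as.integer(base_channels),
                 n_blocks = as.integer(n_blocks),
                 convs_per_block = as.integer(convs_per_block),
                 out_dim = as.integer(out_dim)),
            class = "texture_encoder_config")
}

#' Initialise texture-model parameters (encoder + decoder)
#'
#' @param cfg a [texture_encoder_config()].
#' @param seed RNG seed.
#' @return Nested parameter list (encoder blocks, head, decoder).
#' @export
init_texture_encoder <- function(cfg, seed = NULL) {
  with_seed(seed, {
    blocks <- vector("list", cfg$n_blocks)
    cin <- 1L
    for (b in seq_len(cfg$n_blocks)) {
      cout <- cfg$base_channels * 2L^(b - 1L)    # channels double per block
      convs <- vector("list", cfg$convs_per_block)
      for (j in seq_len(cfg$convs_per_block)) {
        convs[[j]] <- nn_conv3_init(cin, cout)
        cin <- cout
      }
      blocks[[b]] <- convs
    }
    list(blocks = blocks,
         head = nn_linear_init(cin, cfg$out_dim),
         dec_conv = nn_conv3_init(cfg$out_dim, cfg$base_channels),
         dec_out = nn_linear_init(cfg$base_channels, 1L, gain = 1))
  })
}

texture_forward <- function(crop, mask, params, cfg, cache = FALSE) {
  d0 <- dim(crop)
  X <- array(crop, dim = c(d0, 1L))
  caches <- list()
  stage_mask <- mask
  for (b in seq_along(params$blocks)) {
    for (j in seq_along(params$blocks[[b]])) {
      cv <- nn_conv3_fwd(X, params$blocks[[b]][[j]])
      ac <- nn_elu_fwd(cv$out)
      if (cache) caches[[length(caches) + 1L]] <- list(type = "conv", b = b, j = j,
                                                       cv = cv, ac = ac)
      X <- ac$out
    }
    mp <- nn_maxpool_fwd(X)
    # zero activations outside the (conservatively downsampled) support so
    # empty regions can never leak into the informative positions of deeper
    # layers: the embedding is then invariant to appended empty margins
    stage_mask <- mask_downsample(stage_mask, 1L)
    if (cache) caches[[length(caches) + 1L]] <- list(type = "pool", mp = mp,
                                                     m = stage_mask)
    X <- mp$out * as.vector(stage_mask)
  }
  hd <- nn_conv1_fwd(X, params$head)
  ha <- nn_elu_fwd(hd$out)
  maps <- ha$out
  mds <- stage_mask
  assert_that(any(mds), "mask has no informative positions")
  emb <- masked_global_pool(maps, mds)
  if (!cache) return(list(embedding = emb, feature_maps = maps, mask_ds = mds))
  list(embedding = emb, feature_maps = maps, mask_ds = mds,
       cache = list(caches = caches, hd = hd, ha = ha, d0 = d0))
}

# dmaps: gradient wrt the 80-channel maps (decoder + L2 + pooled-embedding
# contributions already summed by the caller)
texture_backward <- function(dmaps, fw, params, cfg) {
  cc <- fw$cache
  g <- list(blocks = lapply(params$blocks, function(bl) vector("list", length(bl))))
  dha <- nn_elu_bwd(dmaps, cc$ha$cache)
  bh <- nn_conv1_bwd(dha, params$head, cc$hd$cache)
  g$head <- list(W = bh$dW, b = bh$db)
  dX <- bh$dX
  for (k in rev(seq_along(cc$caches))) {
    e <- cc$caches[[k]]
    if (e$type == "pool") {
      dX <- nn_maxpool_bwd(dX * as.vector(e$m), e$mp$cache)
    } else {
      dac <- nn_elu_bwd(dX, e$ac$cache)
      bc <- nn_conv3_bwd(dac, params$blocks[[e$b]][[e$j]], e$cv$cache)
      g$blocks[[e$b]][[e$j]] <- list(W = bc$dW, b = bc$db)
      dX <- bc$dX
    }
  }
  g
}

#' Encode a texture crop
#'
#' Runs the convolutional texture encoder on a `[0, 1]` crop with its
#' compartment support mask and returns the 80-dimensional embedding along
#' with the pre-pool feature maps (the autoencoder bottleneck).
#'
#' @param crop 3D array in `[0, 1]`.
#' @param mask logical array of the crop's informative voxels (compartment
#'   support); must contain at least one `TRUE`.
#' @param cfg a [texture_encoder_config()].
#' @param weights parameters from [init_texture_encoder()] or a checkpoint.
#' @return List with `embedding` (length `out_dim`), `feature_maps`
#'   (channels-last array) and `mask_ds` (mask at feature-map resolution).
#' @export
encode_texture <- function(crop, mask, cfg, weights) {
  fw <- texture_forward(crop, mask, weights, cfg, cache = FALSE)
  fw[c("embedding", "feature_maps", "mask_ds")]
}

decoder_forward <- function(maps, params, cache = FALSE) {
  up <- nn_upsample_fwd(maps)
  cv <- nn_conv3_fwd(up$out, params$dec_conv)
  ac <- nn_elu_fwd(cv$out)
  ot <- nn_conv1_fwd(ac$out, params$dec_out)
  out <- ot$out[, , , 1]
  if (!cache) return(out)
  list(out = out, cache = list(up = up, cv = cv, ac = ac, ot = ot))
}

decoder_backward <- function(drec, fw, params) {
  cc <- fw$cache
  dot <- array(drec, dim = c(dim(drec), 1L))
  bo <- nn_conv1_bwd(dot, params$dec_out, cc$ot$cache)
  dac <- nn_elu_bwd(bo$dX, cc$ac$cache)
  bc <- nn_conv3_bwd(dac, params$dec_conv, cc$cv$cache)
  dmaps <- nn_upsample_bwd(bc$dX, cc$up$cache)
  list(grads = list(dec_out = list(W = bo$dW, b = bo$db),
                    dec_conv = list(W = bc$dW, b = bc$db)),
       dmaps = dmaps)
}

#' Decode texture feature maps
#'
#' One upsampling block mirroring the last encoder block (nearest x2
#' upsample, 3x3x3 convolution + ELU, 1x1x1 projection to one channel).
#' Because the encoder pools three times and the decoder upsamples once, the
#' reconstruction lives at 1/4 of the input resolution; the matching loss
#' target is the input downsampled by local mean ([reconstruction_target()]).
#'
#' @param feature_maps pre-pool maps from [encode_texture()].
#' @param weights texture-model parameters (the `dec_*` entries are used).
#' @return 3D reconstruction array.
#' @export
decode_texture <- function(feature_maps, weights) {
  decoder_forward(feature_maps, weights, cache = FALSE)
}

#' @rdname decode_texture
#' @param crop the encoder input crop.
#' @param out_shape spatial shape of the decoder output.
#' @export
reconstruction_target <- function(crop, out_shape) {
  f <- dim(crop) %/% out_shape
  block_reduce(crop[seq_len(out_shape[1] * f[1]),
                    seq_len(out_shape[2] * f[2]),
                    seq_len(out_shape[3] * f[3]), drop = FALSE], f, mean)
}
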