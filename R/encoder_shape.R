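#' Shape encoder configuration
#'
#' A dynamic-graph convolutional point-cloud encoder: per-point features are
#' initialised from centred, unit-bbox-scaled coordinates plus unit normals;
#' `n_graph_layers` edge-convolution rounds rebuild a k-nearest-neighbour
#' graph in the current feature space, transform edge features
#' `[x_i, x_j - x_i]` through a linear+ELU map and max-aggregate over
#' neighbours; a per-point fuse layer followed by max pooling over points
#' condenses the cloud into a latent vector, and an MLP head emits the
#' `out_dim`-dimensional shape embedding (80 throughout the pipeline).
#'
#' @param k_neighbours neighbours per point in the dynamic graph.
#' @param n_graph_layers edge-convolution rounds.
#' @param hidden_width channels of each edge convolution.
#' @param fuse_width width of the pre-pooling fuse layer.
#' @param mlp_width width of the MLP head's hidden layer.
#' @param out_dim embedding length (default 80).
#' @return A `shape_encoder_config`.
#' @export
shape_encoder_config <- function(k_neighbours = 16L, n_graph_layers = 3L,
                                 hidden_width = 64L, fuse_width = 128L,
                                 mlp_width = 128L, out_dim = 80L) {
  assert_that(k_neighbours >= 1, "k_neighbours must be >= 1")
  assert_that(out_dim >= 1, "out_dim must be >= 1")
  structure(list(k_neighbours = as.integer(k_neighbours),
                 n_graph_layers = as.integer(n_graph_layers),
                 hidden_width = as.integer(hidden_width),
                 fuse_width = as.integer(fuse_width),
                 mlp_width = as.integer(mlp_width),
                 out_dim = as.integer(out_dim)),
            class = "shape_encoder_config")
}

#' Initialise shape-encoder parameters
#'
#' He-style random initialisation of all layer weights; used both as the
#' training start and as the random-weights baseline in evaluations.
#' @param cfg a [shape_encoder_config()].
#' @param seed RNG seed.
#' @return Nested parameter list.
#' @export
init_shape_encoder <- function(cfg, seed = NULL) {
  with_seed(seed, {
    layers <- vector("list", cfg$n_graph_layers)
    fin <- 6L
    for (l in seq_len(cfg$n_graph_layers)) {
      layers[[l]] <- nn_linear_init(2L * fin, cfg$hidden_width)
      fin <- cfg$hidden_width
    }
    list(layers = layers,
         fuse = nn_linear_init(fin, cfg$fuse_width),
         mlp1 = nn_linear_init(cfg$fuse_width, cfg$mlp_width),
         mlp2 = nn_linear_init(cfg$mlp_width, cfg$out_dim, gain = 1))
  })
}

# exact kNN (excluding self) on row vectors of X
knn_index <- function(X, k) {
  n <- nrow(X)
  assert_that(n >= k + 1, "fewer points than k_neighbours + 1")
  sq <- rowSums(X^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  cpp_row_kmin(D, as.integer(k))
}

shape_forward <- function(cloud, params, cfg, cache = FALSE) {
  pts <- cloud$points
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  scale <- max(apply(pc, 2, function(v) diff(range(v))))
  if (scale <= 0) scale <- 1
  X <- cbind(pc / scale, cloud$normals)
  n <- nrow(X); k <- cfg$k_neighbours
  caches <- list()
  for (l in seq_along(params$layers)) {
    idx <- knn_index(X, k)
    icenter <- rep(seq_len(n), each = k)
    j <- as.vector(t(idx))
    E <- cbind(X[icenter, , drop = FALSE],
               X[j, , drop = FALSE] - X[icenter, , drop = FALSE])
    lin <- nn_linear_fwd(E, params$layers[[l]])
    act <- nn_elu_fwd(lin$out)
    # max over each point's k neighbours
    H <- ncol(act$out)
    # act$out rows are i-major blocks of k neighbours; reshape to (H, k, n)
    A <- array(t(act$out), dim = c(H, k, n))
    Xn <- matrix(0, n, H)
    amax <- matrix(0L, n, H)
    for (h in seq_len(H)) {
      M <- A[h, , , drop = TRUE]                 # k x n
      w <- max.col(t(M), ties.method = "first")
      amax[, h] <- w
      Xn[, h] <- M[cbind(w, seq_len(n))]
    }
    if (cache) caches[[l]] <- list(icenter = icenter, j = j, lin = lin,
                                   act = act, amax = amax, Fin = ncol(X))
    X <- Xn
  }
  fuse <- nn_linear_fwd(X, params$fuse)
  factv <- nn_elu_fwd(fuse$out)
  pmaxi <- max.col(t(factv$out), ties.method = "first")   # argmax point per channel
  v <- factv$out[cbind(pmaxi, seq_len(ncol(factv$out)))]
  m1 <- nn_linear_fwd(matrix(v, 1), params$mlp1)
  a1 <- nn_elu_fwd(m1$out)
  m2 <- nn_linear_fwd(a1$out, params$mlp2)
  out <- as.vector(m2$out)
  if (!cache) return(out)
  list(out = out,
       cache = list(layers = caches, fuse = fuse, factv = factv, pmaxi = pmaxi,
                    v = v, m1 = m1, a1 = a1, m2 = m2, n = n, k = k))
}

shape_backward <- function(dout, fw, params, cfg) {
  cc <- fw$cache
  g <- list(layers = vector("list", length(params$layers)))
  b2 <- nn_linear_bwd(matrix(dout, 1), params$mlp2, cc$m2$cache)
  g$mlp2 <- list(W = b2$dW, b = b2$db)
  da1 <- nn_elu_bwd(b2$dX, cc$a1$cache)
  b1 <- nn_linear_bwd(da1, params$mlp1, cc$m1$cache)
  g$mlp1 <- list(W = b1$dW, b = b1$db)
  dv <- as.vector(b1$dX)
  # route through max-over-points
  dfact <- matrix(0, cc$n, length(dv))
  dfact[cbind(cc$pmaxi, seq_along(dv))] <- dv
  dfuse <- nn_elu_bwd(dfact, cc$factv$cache)
  bf <- nn_linear_bwd(dfuse, params$fuse, cc$fuse$cache)
  g$fuse <- list(W = bf$dW, b = bf$db)
  dX <- bf$dX
  for (l in rev(seq_along(params$layers))) {
    lc <- cc$layers[[l]]
    n <- cc$n; k <- cc$k
    H <- ncol(dX)
    # route through max-over-neighbours: row of E is (i-1)*k + which
    dact <- matrix(0, n * k, H)
    rows <- (seq_len(n) - 1L) * k
    for (h in seq_len(H)) {
      dact[rows + lc$amax[, h], h] <- dX[, h]
    }
    dlin <- nn_elu_bwd(dact, lc$act$cache)
    bl <- nn_linear_bwd(dlin, params$layers[[l]], lc$lin$cache)
    g$layers[[l]] <- list(W = bl$dW, b = bl$db)
    Fin <- lc$Fin
    dE <- bl$dX
    dXi <- dE[, seq_len(Fin), drop = FALSE] - dE[, Fin + seq_len(Fin), drop = FALSE]
    dXj <- dE[, Fin + seq_len(Fin), drop = FALSE]
    dX <- matrix(0, n, Fin)
    si <- rowsum(dXi, lc$icenter)
    dX[as.integer(rownames(si)), ] <- si
    sj <- rowsum(dXj, lc$j)
    dX[as.integer(rownames(sj)), ] <- dX[as.integer(rownames(sj)), , drop = FALSE] + sj
  }
  g
}

#' Encode a point cloud into a shape embedding
#'
#' Runs the dynamic-graph encoder in evaluation mode (no stochastic layers)
#' and returns the fixed-length embedding. Output is invariant to point
#' order by construction (neighbour and point aggregations are max pools).
#'
#' @param cloud a `point_cloud` from [sample_point_cloud()].
#' @param cfg a [shape_encoder_config()].
#' @param weights parameters from [init_shape_encoder()] or a trained
#'   checkpoint.
#' @return Numeric embedding of length `cfg$out_dim`.
#' @export
encode_shape <- function(cloud, cfg, weights) {
  shape_forward(cloud, weights, cfg, cache = FALSE)
}
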