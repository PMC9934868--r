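# Minimal neural-network primitives with hand-written backpropagation.
#
# The encoders are small enough that an explicit forward/backward per layer,
# with im2col convolutions running on BLAS, is both fast and auditable. All
# layers operate on channels-last arrays; every backward is verified against
# central finite differences in the test suite.

nn_linear_init <- function(fan_in, fan_out, gain = sqrt(2)) {
  list(W = matrix(rnorm(fan_in * fan_out, 0, gain / sqrt(fan_in)), fan_in, fan_out),
       b = rep(0, fan_out))
}

nn_linear_fwd <- function(X, p) {
  # X: n x fan_in
  list(out = sweep(X %*% p$W, 2, p$b, `+`), cache = X)
}

nn_linear_bwd <- function(dY, p, cache) {
  list(dX = dY %*% t(p$W),
       dW = crossprod(cache, dY),
       db = colSums(dY))
}

nn_elu_fwd <- function(X) {
  out <- X
  neg <- X <= 0
  out[neg] <- exp(X[neg]) - 1
  list(out = out, cache = out)
}

nn_elu_bwd <- function(dY, cache) {
  s <- cache
  pos <- s > 0
  s[pos] <- 1
  s[!pos] <- s[!pos] + 1
  dY * s
}

# ---- 3D convolution (3x3x3, stride 1, zero pad 1) --------------------------

im2col3 <- function(X) {
  d <- dim(X)
  Xp <- array(0, dim = c(d[1:3] + 2L, d[4]))
  Xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- X
  cpp_im2col3(Xp, as.integer(d))
}

col2im3 <- function(dcol, d) {
  dXp <- array(cpp_col2im3(dcol, as.integer(d)), dim = c(d[1:3] + 2L, d[4]))
  dXp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), , drop = FALSE]
}

nn_conv3_init <- function(cin, cout) nn_linear_init(27 * cin, cout)

nn_conv3_fwd <- function(X, p) {
  d <- dim(X)
  col <- im2col3(X)
  Y <- sweep(col %*% p$W, 2, p$b, `+`)
  list(out = array(Y, dim = c(d[1:3], ncol(p$W))), cache = list(col = col, d = d))
}

nn_conv3_bwd <- function(dY, p, cache) {
  d <- cache$d
  n <- d[1] * d[2] * d[3]
  dYm <- matrix(dY, n, ncol(p$W))
  list(dX = col2im3(dYm %*% t(p$W), d),
       dW = crossprod(cache$col, dYm),
       db = colSums(dYm))
}

# 1x1x1 convolution = per-position linear map over channels
nn_conv1_fwd <- function(X, p) {
  d <- dim(X)
  n <- prod(d[1:3])
  Xm <- matrix(X, n, d[4])
  Y <- sweep(Xm %*% p$W, 2, p$b, `+`)
  list(out = array(Y, dim = c(d[1:3], ncol(p$W))), cache = list(Xm = Xm, d = d))
}

nn_conv1_bwd <- function(dY, p, cache) {
  d <- cache$d
  n <- prod(d[1:3])
  dYm <- matrix(dY, n, ncol(p$W))
  list(dX = array(dYm %*% t(p$W), dim = d),
       dW = crossprod(cache$Xm, dYm),
       db = colSums(dYm))
}

# ---- 2x2x2 max pooling (stride 2) ------------------------------------------

nn_maxpool_fwd <- function(X) {
  d <- dim(X)
  dh <- d[1:3] %/% 2L
  X <- X[seq_len(2 * dh[1]), seq_len(2 * dh[2]), seq_len(2 * dh[3]), , drop = FALSE]
  b <- array(X, dim = c(2, dh[1], 2, dh[2], 2, dh[3], d[4]))
  b <- aperm(b, c(1, 3, 5, 2, 4, 6, 7))
  m <- matrix(b, nrow = 8)
  amax <- max.col(t(m), ties.method = "first")
  out <- array(m[cbind(amax, seq_len(ncol(m)))], dim = c(dh, d[4]))
  list(out = out, cache = list(amax = amax, d = d, dh = dh))
}

nn_maxpool_bwd <- function(dY, cache) {
  d <- cache$d; dh <- cache$dh
  m <- matrix(0, 8, prod(dh) * d[4])
  m[cbind(cache$amax, seq_len(ncol(m)))] <- as.vector(dY)
  b <- array(m, dim = c(2, 2, 2, dh[1], dh[2], dh[3], d[4]))
  b <- aperm(b, c(1, 4, 2, 5, 3, 6, 7))
  dX <- array(0, dim = d)
  dX[seq_len(2 * dh[1]), seq_len(2 * dh[2]), seq_len(2 * dh[3]), ] <-
    array(b, dim = c(2 * dh, d[4]))
  dX
}

# ---- nearest-neighbour x2 upsampling ---------------------------------------

nn_upsample_fwd <- function(X) {
  d <- dim(X)
  iz <- rep(seq_len(d[1]), each = 2)
  iy <- rep(seq_len(d[2]), each = 2)
  ix <- rep(seq_len(d[3]), each = 2)
  list(out = X[iz, iy, ix, , drop = FALSE], cache = d)
}

nn_upsample_bwd <- function(dY, cache) {
  d <- cache
  b <- array(dY, dim = c(2, d[1], 2, d[2], 2, d[3], d[4]))
  out <- b[1, , 1, , 1, , , drop = FALSE] + b[2, , 1, , 1, , , drop = FALSE] +
         b[1, , 2, , 1, , , drop = FALSE] + b[2, , 2, , 1, , , drop = FALSE] +
         b[1, , 1, , 2, , , drop = FALSE] + b[2, , 1, , 2, , , drop = FALSE] +
         b[1, , 2, , 2, , , drop = FALSE] + b[2, , 2, , 2, , , drop = FALSE]
  array(out, dim = d)
}

# ---- masked global average pooling -----------------------------------------

#' Masked global average pooling
#'
#' Per-channel mean of a channels-last feature map over the informative
#' spatial positions only, so empty (out-of-compartment) regions do not
#' dilute the embedding.
#'
#' @param feature_maps array `(d1, d2, d3, C)` (or any shape with channels
#'   last).
#' @param mask logical array matching the spatial shape; at least one
#'   position must be informative.
#' @return Numeric vector of length `C`.
#' @export
masked_global_pool <- function(feature_maps, mask) {
  d <- dim(feature_maps)
  C <- d[length(d)]
  n <- prod(d[-length(d)])
  assert_that(length(mask) == n, "mask shape must match feature-map spatial shape")
  keep <- which(as.vector(mask))
  assert_that(length(keep) > 0, "mask has no informative positions")
  m <- matrix(feature_maps, n, C)
  colMeans(m[keep, , drop = FALSE])
}

nn_maskpool_bwd <- function(dY, d, mask) {
  n <- prod(d[-length(d)])
  keep <- which(as.vector(mask))
  m <- matrix(0, n, length(dY))
  m[keep, ] <- matrix(dY, length(keep), length(dY), byrow = TRUE) / length(keep)
  array(m, dim = d)
}

# downsample a logical mask by factor-2 max pooling ("any informative voxel
# in the window makes the window informative"), repeated `times`
mask_downsample <- function(mask, times) {
  for (i in seq_len(times)) {
    d <- dim(mask)
    dh <- d %/% 2L
    m <- mask[seq_len(2 * dh[1]), seq_len(2 * dh[2]), seq_len(2 * dh[3]), drop = FALSE]
    b <- array(m, dim = c(2, dh[1], 2, dh[2], 2, dh[3]))
    mask <- array(apply(b, c(2, 4, 6), any), dim = dh)
  }
  mask
}

# ---- parameter plumbing ----------------------------------------------------

flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) out <- c(out, flatten_params(p, paste0(prefix, nm, ".")))
    else out[[paste0(prefix, nm)]] <- p
  }
  out
}

unflatten_into <- function(params, flat, prefix = "") {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) params[[nm]] <- unflatten_into(p, flat, paste0(prefix, nm, "."))
    else params[[nm]] <- flat[[paste0(prefix, nm)]]
  }
  params
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

# Adam with additive L2 weight decay on the gradient (the convention of the
# reference deep-learning stack's Adam).
adam_step <- function(flat, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = flat, state = state)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
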