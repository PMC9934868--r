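#' Normalised-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' Embeddings are row-normalised and scored by cosine similarity divided by
#' the temperature; for each of the 2B anchors the loss is the cross-entropy
#' of identifying its positive (the other augmented view of the same source)
#' among all 2B-1 other items, averaged over anchors. Rows are ordered so
#' that items `i` and `i + B` are the two views of source `i`
#' (the [make_contrastive_batch()] convention).
#'
#' With B = 1 there are no negatives and the softmax is a single term; the
#' loss is 0 by convention and a warning is raised.
#'
#' @param embeddings numeric matrix `2B x D`, finite, no zero rows.
#' @param tau temperature (> 0; default 0.5).
#' @param grad also return the gradient with respect to `embeddings`.
#' @return Loss value, or `list(value, grad)` when `grad = TRUE`.
#' @export
nt_xent_loss <- function(embeddings, tau = 0.5, grad = FALSE) {
  Z <- as.matrix(embeddings)
  n <- nrow(Z)
  assert_that(n %% 2 == 0 && n >= 2, "embeddings must have an even number of rows")
  assert_that(all(is.finite(Z)), "non-finite embedding")
  assert_that(tau > 0, "tau must be > 0")
  B <- n %/% 2L
  norms <- sqrt(rowSums(Z^2))
  assert_that(all(norms > 0), "zero-norm embedding: cosine similarity undefined")
  if (B == 1L) {
    warning("contrastive batch with a single source sample: no negatives, loss is 0")
    if (grad) return(list(value = 0, grad = Z * 0))
    return(0)
  }
  Zn <- Z / norms
  S <- (Zn %*% t(Zn)) / tau
  pos <- c(seq_len(B) + B, seq_len(B))          # positive index per anchor
  E <- exp(S)
  diag(E) <- 0
  denom <- rowSums(E)
  li <- -S[cbind(seq_len(n), pos)] + log(denom)
  value <- mean(li)
  if (!grad) return(value)
  G <- E / denom                                 # softmax over j != i
  G[cbind(seq_len(n), pos)] <- G[cbind(seq_len(n), pos)] - 1
  G <- G / n
  dZn <- (G + t(G)) %*% Zn / tau
  # through row normalisation
  proj <- rowSums(dZn * Zn)
  dZ <- (dZn - proj * Zn) / norms
  list(value = value, grad = dZ)
}

#' Combined texture objective
#'
#' Weighted sum of the NT-Xent loss on the pooled embeddings, the mean
#' squared error between the decoder reconstruction and its target, and the
#' mean squared norm of the flattened bottleneck features (an L2 range
#' penalty).
#'
#' @param embeddings `2B x D` embedding matrix.
#' @param reconstruction decoder output (array or list of arrays, one per
#'   batch item).
#' @param target matching reconstruction target(s).
#' @param bottleneck bottleneck maps (array or list of arrays).
#' @param weights numeric length 3: `(w_ntxent, w_mse, w_l2)`.
#' @param tau NT-Xent temperature.
#' @return `list(total, parts)` with parts `ntxent`, `mse`, `l2`.
#' @export
combined_texture_loss <- function(embeddings, reconstruction, target, bottleneck,
                                  weights = c(1, 1, 1e-4), tau = 0.5) {
  if (!is.list(reconstruction)) reconstruction <- list(reconstruction)
  if (!is.list(target)) target <- list(target)
  if (!is.list(bottleneck)) bottleneck <- list(bottleneck)
  ntx <- nt_xent_loss(embeddings, tau)
  mse <- mean(vapply(seq_along(reconstruction), function(i) {
    mean((reconstruction[[i]] - target[[i]])^2)
  }, 0))
  l2 <- mean(vapply(bottleneck, function(b) mean(b^2), 0))
  parts <- c(ntxent = ntx, mse = mse, l2 = l2)
  total <- sum(weights * parts)
  assert_that(all(is.finite(parts)), "non-finite loss part")
  list(total = total, parts = parts)
}
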