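#' Morphotype classification protocol
#'
#' Evaluates how well a feature table separates annotated morphotypes:
#' features are standardised across the dataset, agglomerated to at most
#' `n_feature_clusters` merged columns (Ward hierarchical merging of
#' similar features, applied only when the table is wider than the target),
#' and an L2-regularised multinomial logistic regression (regularisation
#' strength `C`, ridge solved by glmnet) is scored by stratified k-fold
#' cross-validation. The confusion matrix has true labels as rows and
#' predictions as columns, summed over folds.
#'
#' @param features tibble `cell_id` + feature columns.
#' @param labels factor/character labels, one per feature row (or a tibble
#'   with `cell_id` + `label`).
#' @param n_folds stratified folds (default 5).
#' @param n_feature_clusters agglomeration target (default 100).
#' @param C inverse regularisation strength (default 1).
#' @param seed RNG seed for fold assignment.
#' @return A `morphotype_classification`: fold accuracies, mean accuracy,
#'   confusion matrix, settings.
#' @export
classify_morphotypes <- function(features, labels, n_folds = 5L,
                                 n_feature_clusters = 100L, C = 1, seed = 1L) {
  if (is.data.frame(labels)) {
    labels <- labels$label[match(features$cell_id, labels$cell_id)]
  }
  y <- factor(labels)
  assert_that(nlevels(y) >= 2, "need at least 2 classes")
  tab <- table(y)
  if (any(tab < n_folds)) {
    stop(sprintf("class '%s' has fewer than %d members",
                 names(tab)[which(tab < n_folds)[1]], n_folds), call. = FALSE)
  }
  X <- as.matrix(standardize_features(features)[, -1])
  if (ncol(X) > n_feature_clusters) {
    X <- agglomerate_features(X, n_feature_clusters)
  }
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    lev <- levels(y)
    conf <- matrix(0L, nlevels(y), nlevels(y), dimnames = list(lev, lev))
    acc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "multinomial",
                            alpha = 0, lambda = 1 / (C * sum(tr)),
                            standardize = FALSE)
      pr <- predict(fit, X[te, , drop = FALSE], type = "class")
      pr <- factor(pr[, 1], levels = lev)
      acc[f] <- mean(pr == y[te])
      conf <- conf + unclass(table(y[te], pr))
    }
    structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                   confusion = conf,
                   settings = list(n_folds = n_folds, C = C,
                                   n_feature_clusters = n_feature_clusters,
                                   seed = seed)),
              class = "morphotype_classification")
  })
}

# Ward hierarchical merging of similar feature columns: cluster the columns
# and replace each cluster by its mean (guards against overfitting very wide
# tables).
agglomerate_features <- function(X, k) {
  hc <- stats::hclust(stats::dist(t(X)), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  out <- vapply(seq_len(k), function(g) {
    rowMeans(X[, grp == g, drop = FALSE])
  }, numeric(nrow(X)))
  colnames(out) <- paste0("agg", seq_len(k))
  out
}

#' @export
print.morphotype_classification <- function(x, ...) {
  cat(sprintf("<morphotype_classification> mean accuracy %.3f over %d folds\n",
              x$mean_accuracy, length(x$fold_accuracy)))
  invisible(x)
}

#' Candidate symmetric partners by mirror reflection
#'
#' For every cell, reflects its centroid across the volume's x mid-plane
#' and returns the `n_candidates` nearest cells of the opposite side by
#' physical distance — the candidate set for [bilateral_distance()] when no
#' ground-truth pairing is available.
#'
#' @param truth tibble with `cell_id`, `side` and `centroid_z/y/x` columns
#'   (the phantom truth table layout).
#' @param grid_shape `(z, y, x)` grid extent (to place the mirror plane).
#' @param n_candidates candidates per cell (default 10).
#' @return Named list: cell id -> integer vector of candidate ids.
#' @export
bilateral_candidates <- function(truth, grid_shape, n_candidates = 10L) {
  ctr <- as.matrix(truth[, c("centroid_z", "centroid_y", "centroid_x")])
  nx <- grid_shape[3]
  out <- vector("list", nrow(truth))
  names(out) <- as.character(truth$cell_id)
  for (i in seq_len(nrow(truth))) {
    refl <- ctr[i, ]
    refl[3] <- nx + 1 - refl[3]
    opp <- which(truth$side != truth$side[i])
    if (!length(opp)) { out[[i]] <- integer(0); next }
    d2 <- rowSums(sweep(ctr[opp, , drop = FALSE], 2, refl)^2)
    out[[i]] <- truth$cell_id[opp[order(d2)[seq_len(min(n_candidates, length(opp)))]]]
  }
  out
}

#' Bilateral symmetric-partner rank metric
#'
#' For each cell `c` with candidate partners, the nearest candidate in
#' feature space (Euclidean) is chosen; its rank is the position of that
#' candidate when all other cells are sorted by distance from `c` (rank 1 =
#' nearest other cell; distance ties broken by smaller cell id). The
#' summary is the median of these ranks over all evaluated cells — low
#' values mean the features co-locate mirror-image cells.
#'
#' @param features tibble `cell_id` + feature columns.
#' @param candidates named list: cell id -> candidate partner ids (e.g.
#'   [bilateral_candidates()], or ground-truth partners).
#' @return A `bilateral_ranking`: per-cell tibble (`cell_id`,
#'   `chosen_partner`, `rank`), `median_rank`, and the ids skipped for lack
#'   of candidates.
#' @export
bilateral_distance <- function(features, candidates) {
  assert_that(length(candidates) > 0, "candidate map is empty")
  ids <- features$cell_id
  X <- as.matrix(features[, setdiff(names(features), "cell_id")])
  rows <- list(); skipped <- integer(0)
  for (nm in names(candidates)) {
    cid <- as.integer(nm)
    cand <- as.integer(candidates[[nm]])
    if (!length(cand)) { skipped <- c(skipped, cid); next }
    i <- match(cid, ids)
    assert_that(!is.na(i), sprintf("cell %d absent from features", cid))
    ci <- match(cand, ids)
    if (anyNA(ci)) {
      stop(sprintf("candidate %d of cell %d absent from features",
                   cand[which(is.na(ci))[1]], cid), call. = FALSE)
    }
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    others <- setdiff(seq_along(ids), i)
    ord <- others[order(d[others], ids[others])]
    chosen <- ci[order(d[ci], ids[ci])][1]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = cid, chosen_partner = ids[chosen],
      rank = match(chosen, ord))
  }
  assert_that(length(rows) > 0, "no cell had candidates")
  percell <- dplyr::bind_rows(rows)
  structure(list(per_cell = percell, median_rank = median(percell$rank),
                 skipped = skipped),
            class = "bilateral_ranking")
}

#' @export
print.bilateral_ranking <- function(x, ...) {
  cat(sprintf("<bilateral_ranking> median rank %.1f over %d cells (%d skipped)\n",
              x$median_rank, nrow(x$per_cell), length(x$skipped)))
  invisible(x)
}

# ---- clustering ------------------------------------------------------------

# UMAP-style fuzzy simplicial-set k-NN graph: per-point smooth kernel widths
# by binary search (target sum = log2(k)), fuzzy-union symmetrisation.
fuzzy_knn_graph <- function(X, n_neighbours = 20L) {
  n <- nrow(X)
  assert_that(n >= n_neighbours + 1, "fewer rows than n_neighbours + 1")
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  idx <- cpp_row_kmin(D2, as.integer(n_neighbours))
  target <- log2(n_neighbours)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (i in seq_len(n)) {
    d <- sqrt(pmax(D2[i, idx[i, ]], 0))
    rho <- d[1]
    dd <- pmax(d - rho, 0)
    lo <- 1e-6; hi <- max(dd) + 1
    if (max(dd) <= 0) {
      sigma <- 1
    } else {
      for (it in 1:64) {
        mid <- (lo + hi) / 2
        s <- sum(exp(-dd / mid))
        if (s > target) hi <- mid else lo <- mid
      }
      sigma <- (lo + hi) / 2
    }
    w <- exp(-dd / sigma)
    ii <- c(ii, rep(i, n_neighbours)); jj <- c(jj, idx[i, ]); ww <- c(ww, w)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  S <- A + Matrix::t(A) - A * Matrix::t(A)     # fuzzy union
  S
}

#' Cluster cells on a fuzzy k-NN graph with Leiden/CPM
#'
#' Builds the weighted k-neighbour graph of the (standardised) feature
#' rows using the fuzzy-simplicial-set construction (the graph, not any 2D
#' layout) and partitions it with the Leiden algorithm under the constant
#' Potts model at resolution `resolution`. Deterministic given `seed`.
#'
#' @param features tibble `cell_id` + standardised feature columns.
#' @param n_neighbours k for the graph (default 20).
#' @param resolution CPM resolution (the reference whole-animal run used
#'   0.004; subclustering used 0.005-0.2).
#' @param seed RNG seed.
#' @return A `cluster_assignment`: tibble (`cell_id`, `cluster`) plus the
#'   parameters.
#' @export
cluster_cells <- function(features, n_neighbours = 20L, resolution = 0.004,
                          seed = 1L) {
  X <- as.matrix(features[, setdiff(names(features), "cell_id")])
  S <- fuzzy_knn_graph(X, n_neighbours)
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected", weighted = TRUE)
  memb <- with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "CPM",
                           resolution = resolution,
                           weights = igraph::E(g)$weight,
                           n_iterations = 5)$membership
  })
  structure(list(assignment = tibble::tibble(cell_id = features$cell_id,
                                             cluster = as.integer(memb)),
                 params = list(n_neighbours = n_neighbours,
                               metric = "euclidean",
                               resolution = resolution, seed = seed)),
            class = "cluster_assignment")
}

#' @rdname cluster_cells
#' @param assignment an existing `cluster_assignment`.
#' @param cluster cluster id to split.
#' @export
subcluster_cells <- function(features, assignment, cluster, n_neighbours = 20L,
                             resolution = 0.1, seed = 1L) {
  keep <- assignment$assignment$cell_id[assignment$assignment$cluster == cluster]
  assert_that(length(keep) > 0, "empty cluster")
  cluster_cells(features[features$cell_id %in% keep, ],
                n_neighbours = min(n_neighbours, length(keep) - 1L),
                resolution = resolution, seed = seed)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells in %d clusters (resolution %g)\n",
              nrow(x$assignment), length(unique(x$assignment$cluster)),
              x$params$resolution))
  invisible(x)
}

# ---- specificity statistics ------------------------------------------------

specificity_c <- function(A, B) ifelse(A + B == 0, 0, 2 * A * B / (A + B))

#' Gene-expression specificity per cluster
#'
#' For every (cluster, gene): `A` = mean expression in the cluster, `B` =
#' in-cluster share of total expression (sum in cluster / sum over the
#' scope cells), `C = 2AB/(A+B)` (0 when `A + B = 0`). With expression in
#' `[0, 1]`, all three are in `[0, 1]`, and `C = A` when `A = B`. Dot plots
#' keep genes with `C` above `threshold`; for two-cluster comparisons the
#' pairwise filter additionally drops genes whose `C` exceeds the threshold
#' in both clusters while differing by less than `pair_diff`.
#'
#' @param expression tibble `cell_id` + gene columns, values in `[0, 1]`.
#' @param clusters `cluster_assignment` or tibble (`cell_id`, `cluster`).
#' @param scope_cells cells defining "total" expression (default: all
#'   expression rows).
#' @param binarize treat any positive expression as 1 before computing `A`
#'   and `B` (default `FALSE`: raw overlap fractions).
#' @return Tibble of `SpecificityRecord`s: `cluster`, `variable`, `A`,
#'   `B`, `C`.
#' @export
gene_specificity <- function(expression, clusters, scope_cells = NULL,
                             binarize = FALSE) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$assignment else clusters
  if (is.null(scope_cells)) scope_cells <- expression$cell_id
  ex <- expression[expression$cell_id %in% scope_cells, ]
  genes <- setdiff(names(ex), "cell_id")
  M <- as.matrix(ex[, genes])
  assert_that(all(M >= 0), "negative expression values")
  if (binarize) M <- (M > 0) * 1
  memb <- cl$cluster[match(ex$cell_id, cl$cell_id)]
  assert_that(!anyNA(memb), "clusters do not cover all expression rows in scope")
  tot <- colSums(M)
  out <- list()
  for (k in sort(unique(memb))) {
    rows <- memb == k
    A <- unname(colMeans(M[rows, , drop = FALSE]))
    B <- unname(ifelse(tot > 0, colSums(M[rows, , drop = FALSE]) / tot, 0))
    out[[length(out) + 1L]] <- tibble::tibble(
      cluster = k, variable = genes, A = A, B = B, C = specificity_c(A, B))
  }
  dplyr::bind_rows(out)
}

#' @rdname gene_specificity
#' @param records specificity tibble.
#' @param threshold keep variables with `C` above this value in at least
#'   one cluster (genes: 0.15; standardised features: 1).
#' @param pair_diff optional two-cluster difference filter: drop variables
#'   with `C > threshold` in both clusters but `|dC| < pair_diff` (the
#'   reference protocol used 0.4).
#' @export
select_specific <- function(records, threshold = 0.15, pair_diff = NULL) {
  keep <- unique(records$variable[records$C > threshold])
  out <- records[records$variable %in% keep, ]
  if (!is.null(pair_diff)) {
    cls <- unique(records$cluster)
    assert_that(length(cls) == 2, "pairwise filter needs exactly 2 clusters")
    wide <- tidyr::pivot_wider(out[, c("cluster", "variable", "C")],
                               names_from = "cluster", values_from = "C")
    c1 <- wide[[2]]; c2 <- wide[[3]]
    drop <- wide$variable[c1 > threshold & c2 > threshold &
                          abs(c1 - c2) < pair_diff]
    out <- out[!out$variable %in% drop, ]
  }
  out
}

#' Feature specificity per cluster
#'
#' The feature analogue of [gene_specificity()] for standardised feature
#' tables: values are clipped to `[-2, 2]` and min-max rescaled to `[0, 1]`
#' per feature across cells; `A` and `B` are computed as for genes, and `B`
#' is additionally divided by the relative cluster size (smaller clusters
#' would otherwise hold a smaller share of any feature). The dot-plot
#' selection threshold is `C > 1`.
#'
#' @param features standardised feature tibble (`cell_id` + columns).
#' @param clusters `cluster_assignment` or tibble (`cell_id`, `cluster`).
#' @return Tibble `cluster`, `variable`, `A`, `B`, `C`.
#' @export
feature_specificity <- function(features, clusters) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$assignment else clusters
  cols <- setdiff(names(features), "cell_id")
  M <- as.matrix(features[, cols])
  M <- pmin(pmax(M, -2), 2)
  rng <- apply(M, 2, range)
  span <- rng[2, ] - rng[1, ]
  M <- sweep(sweep(M, 2, rng[1, ]), 2, pmax(span, 1e-300), `/`)
  # a feature constant across cells carries no ordering information: map it
  # to the midpoint so shares reduce to cluster sizes (normalised B = 1)
  M[, span == 0] <- 0.5
  memb <- cl$cluster[match(features$cell_id, cl$cell_id)]
  assert_that(!anyNA(memb), "clusters do not cover the feature rows")
  tot <- colSums(M)
  n <- nrow(M)
  out <- list()
  for (k in sort(unique(memb))) {
    rows <- memb == k
    assert_that(sum(rows) > 0, "empty cluster")
    A <- unname(colMeans(M[rows, , drop = FALSE]))
    B <- unname(ifelse(tot > 0, colSums(M[rows, , drop = FALSE]) / tot, 0))
    B <- B / (sum(rows) / n)                 # cluster-size normalisation
    out[[length(out) + 1L]] <- tibble::tibble(
      cluster = k, variable = cols, A = A, B = B, C = specificity_c(A, B))
  }
  dplyr::bind_rows(out)
}

# ---- representative / extreme cells ----------------------------------------

#' Representative (average) cell of a cluster
#'
#' Coordinate-wise median feature vector of the cluster; returns the member
#' cell whose features are closest (Euclidean) to it, ties broken by
#' smaller id.
#'
#' @param features tibble `cell_id` + feature columns.
#' @param members cell ids of the cluster.
#' @return A single cell id.
#' @export
representative_cell <- function(features, members) {
  assert_that(length(members) > 0, "cluster is empty")
  idx <- match(members, features$cell_id)
  assert_that(!anyNA(idx), "member without feature row")
  X <- as.matrix(features[idx, setdiff(names(features), "cell_id")])
  med <- apply(X, 2, median)
  d <- sqrt(colSums((t(X) - med)^2))
  ord <- order(d, members)
  members[ord[1]]
}

#' Cells at the extremes of one feature
#'
#' @param features tibble `cell_id` + feature columns.
#' @param feature column name or index (into the feature columns).
#' @param k cells per extreme (1 <= k <= cell count).
#' @param exclude cell ids to ignore (e.g. known segmentation errors).
#' @return `list(lowest, highest)` of k cell ids each, sorted from the
#'   extreme inwards.
#' @export
feature_extremes <- function(features, feature, k = 4L, exclude = NULL) {
  cols <- setdiff(names(features), "cell_id")
  if (is.numeric(feature)) {
    assert_that(feature >= 1 && feature <= length(cols), "invalid feature index")
    feature <- cols[feature]
  }
  assert_that(feature %in% cols, sprintf("unknown feature '%s'", feature))
  tb <- features[!features$cell_id %in% exclude, c("cell_id", feature)]
  assert_that(k >= 1 && k <= nrow(tb), "k out of range")
  v <- tb[[feature]]
  ord <- order(v, tb$cell_id)
  list(lowest = tb$cell_id[ord[seq_len(k)]],
       highest = tb$cell_id[rev(ord)[seq_len(k)]])
}
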