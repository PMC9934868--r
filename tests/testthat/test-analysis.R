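make_blob_features <- function(n_per_class, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    matrix(rnorm(n_per_class * ncol(centers), 0, sd), n_per_class) +
      matrix(centers[k, ], n_per_class, ncol(centers), byrow = TRUE)
  }))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  list(features = dplyr::bind_cols(tibble::tibble(cell_id = seq_len(nrow(X))),
                                   tibble::as_tibble(X)),
       labels = rep(paste0("c", seq_len(nrow(centers))), each = n_per_class))
}

test_that("classification is perfect on separable classes and chance on shuffles", {
  centers <- matrix(c(0, 0, 0, 8, 0, 0, 0, 8, 0, 0, 0, 8), 4, 3, byrow = TRUE)
  blob <- make_blob_features(12, centers, sd = 0.3, seed = 2)
  fit <- suppressWarnings(classify_morphotypes(blob$features, blob$labels, seed = 1))
  expect_equal(fit$mean_accuracy, 1)
  expect_identical(sum(fit$confusion), 48L)
  expect_identical(rownames(fit$confusion), colnames(fit$confusion))
  expect_true(all(fit$confusion[lower.tri(fit$confusion)] == 0))

  # permuted labels on a balanced 4-class problem: accuracy ~ 0.25
  accs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    suppressWarnings(classify_morphotypes(blob$features, sample(blob$labels),
                                          seed = s)$mean_accuracy)
  }, 0)
  # binomial null: 48 draws at p = 0.25 per run, averaged over 5 runs
  expect_lt(abs(mean(accs) - 0.25), qnorm(0.995) * sqrt(0.25 * 0.75 / (48 * 5)) + 0.05)

  expect_error(classify_morphotypes(blob$features, c(blob$labels[-1], "rare")),
               "fewer than")
  # broom accessors
  td <- tidy(fit)
  expect_identical(nrow(td), 5L)
  expect_equal(glance(fit)$mean_accuracy, 1)
})

test_that("feature agglomeration merges duplicate columns and keeps the signal", {
  set.seed(5)
  base_cols <- matrix(rnorm(40 * 100), 40, 100)
  # 120 columns built from 100 underlying ones: 20 duplicated with tiny noise
  X <- cbind(base_cols, base_cols[, 1:20] + rnorm(40 * 20, 0, 1e-4))
  colnames(X) <- paste0("f", 1:120)
  agg <- morphodesc:::agglomerate_features(scale(X), 100)
  expect_identical(ncol(agg), 100L)
  # every original column pattern survives (up to the duplicate averaging)
  cors <- vapply(seq_len(100), function(j) {
    max(abs(cor(base_cols[, j], agg)))
  }, 0)
  expect_true(all(cors > 0.999))

  # and the wide-table classification path still separates labelled classes
  y <- rep(c("a", "b"), each = 20)
  f <- dplyr::bind_cols(tibble::tibble(cell_id = 1:40), tibble::as_tibble(X))
  base_sig <- ifelse(y == "a", 3, -3)
  for (j in 1:10) f[[paste0("f", j)]] <- base_sig + rnorm(40, 0, 0.1)
  acc <- suppressWarnings(classify_morphotypes(f, y, seed = 2))$mean_accuracy
  expect_gte(acc, 0.7)      # wide, mostly-noise table: well above chance
})

test_that("bilateral ranking matches the O(n^2) sort-and-rank oracle", {
  for (trial in 1:20) {
    set.seed(trial)
    n <- 50
    X <- matrix(rnorm(n * 6), n, 6)
    colnames(X) <- paste0("f", 1:6)
    feats <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(n)),
                              tibble::as_tibble(X))
    cands <- lapply(seq_len(n), function(i) sample(setdiff(seq_len(n), i),
                                                   sample(1:8, 1)))
    names(cands) <- as.character(seq_len(n))
    got <- bilateral_distance(feats, cands)

    ranks <- vapply(seq_len(n), function(i) {
      d <- sqrt(colSums((t(X) - X[i, ])^2))
      others <- setdiff(seq_len(n), i)
      ord <- others[order(d[others], others)]
      cn <- cands[[i]][order(d[cands[[i]]], cands[[i]])][1]
      which(ord == cn)
    }, 0L)
    expect_identical(got$per_cell$rank, as.integer(ranks))
    expect_identical(got$median_rank, median(ranks))
  }
})

test_that("bilateral ranking handles exact duplicates and missing candidates", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 0), c(5, 0), c(9, 9), c(2, 7))
  colnames(X) <- c("f1", "f2")
  feats <- dplyr::bind_cols(tibble::tibble(cell_id = 1:6), tibble::as_tibble(X))
  cands <- list("1" = 2L, "2" = 1L, "3" = 4L, "4" = 3L, "5" = integer(0))
  br <- bilateral_distance(feats, cands)
  expect_identical(br$median_rank, 1)          # true partners are duplicates
  expect_identical(br$skipped, 5L)             # no-candidate cell excluded
  expect_identical(nrow(br$per_cell), 4L)
  expect_error(bilateral_distance(feats, list("1" = 99L)), "absent")
  expect_identical(glance(br)$n_skipped, 1L)
})

test_that("bilateral summary is invariant under feature-space isometries", {
  set.seed(9)
  n <- 30
  X <- matrix(rnorm(n * 4), n, 4)
  colnames(X) <- paste0("f", 1:4)
  feats <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(n)), tibble::as_tibble(X))
  cands <- lapply(seq_len(n), function(i) setdiff(sample(n, 5), i)[1:3])
  names(cands) <- seq_len(n)
  base <- bilateral_distance(feats, cands)$median_rank
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  X2 <- X %*% Q + matrix(rnorm(4), n, 4, byrow = TRUE) * 0 + 3
  colnames(X2) <- colnames(X)
  feats2 <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(n)), tibble::as_tibble(X2))
  expect_identical(bilateral_distance(feats2, cands)$median_rank, base)
})

test_that("two well-separated blobs are recovered at some resolution", {
  blob <- make_blob_features(60, matrix(c(0, 0, 0, 8, 8, 8), 2, 3, byrow = TRUE),
                             sd = 0.5, seed = 4)
  feats <- standardize_features(blob$features)
  found <- FALSE
  for (g in c(0.001, 0.003, 0.01, 0.03)) {
    ca <- cluster_cells(feats, n_neighbours = 15, resolution = g, seed = 2)
    k <- length(unique(ca$assignment$cluster))
    if (k == 2) {
      agree <- mean((ca$assignment$cluster == ca$assignment$cluster[1]) ==
                      (blob$labels == blob$labels[1]))
      expect_gte(agree, 0.99)
      found <- TRUE
      # same seed, same input: bit-identical partition
      expect_identical(cluster_cells(feats, 15, g, seed = 2)$assignment,
                       ca$assignment)
      break
    }
  }
  expect_true(found)
})

test_that("CPM cluster counts do not decrease with resolution", {
  blob <- make_blob_features(40, matrix(c(0, 0, 6, 6), 2, 2, byrow = TRUE),
                             sd = 1, seed = 6)
  feats <- standardize_features(blob$features)
  ks <- vapply(c(0.001, 0.05, 0.5), function(g) {
    length(unique(cluster_cells(feats, 10, g, seed = 1)$assignment$cluster))
  }, 0L)
  expect_true(all(diff(ks) >= 0))
  expect_error(cluster_cells(feats[1:5, ], n_neighbours = 10), "fewer rows")
})

test_that("subclustering splits one cluster at higher resolution", {
  # two overlapping blobs close together plus one far blob: a coarse
  # resolution merges the near pair, a finer re-run on that cluster splits it
  centers <- matrix(c(0, 0, 20, 20, 20, 23), 3, 2, byrow = TRUE)
  blob <- make_blob_features(30, centers, sd = 1.2, seed = 3)
  feats <- standardize_features(blob$features)
  ca <- cluster_cells(feats, 15, 0.002, seed = 1)
  expect_identical(length(unique(ca$assignment$cluster)), 2L)
  big <- as.integer(names(which.max(table(ca$assignment$cluster))))
  sub <- subcluster_cells(feats, ca, big, n_neighbours = 15, resolution = 0.05, seed = 1)
  expect_gte(length(unique(sub$assignment$cluster)), 2L)
})

test_that("gene specificity reproduces its defining algebra", {
  expr <- tibble::tibble(cell_id = 1:6,
                         g_exclusive = c(1, 1, 0, 0, 0, 0),
                         g_flat = rep(0.5, 6))
  cl <- tibble::tibble(cell_id = 1:6, cluster = rep(1:3, each = 2))
  rec <- gene_specificity(expr, cl)
  ex <- rec[rec$variable == "g_exclusive" & rec$cluster == 1, ]
  expect_equal(c(ex$A, ex$B, ex$C), c(1, 1, 1))
  expect_true(all(rec$C >= 0 & rec$C <= 1))
  # C = A when A = B; direct evaluations
  expect_equal(morphodesc:::specificity_c(0.5, 0.5), 0.5)
  expect_equal(morphodesc:::specificity_c(0.2, 0.8), 0.32)
  expect_equal(morphodesc:::specificity_c(0, 0), 0)
  expect_error(gene_specificity(dplyr::mutate(expr, g_flat = -g_flat - 1), cl),
               "negative")
  # selection threshold and two-cluster difference filter
  rec2 <- gene_specificity(expr[1:4, ], cl[1:4, ])
  kept <- select_specific(rec2, threshold = 0.15, pair_diff = 0.4)
  wide <- tidyr::pivot_wider(rec2[, c("cluster", "variable", "C")],
                             names_from = "cluster", values_from = "C")
  both_high_close <- wide$variable[wide[[2]] > 0.15 & wide[[3]] > 0.15 &
                                     abs(wide[[2]] - wide[[3]]) < 0.4]
  expect_true(!any(kept$variable %in% both_high_close))
})

test_that("feature specificity applies clipping and cluster-size normalisation", {
  cl <- tibble::tibble(cell_id = 1:6, cluster = c(1, 1, 2, 2, 2, 2))
  # exclusive feature: after clip/scale it is 1 in cluster 1, 0 elsewhere
  ft <- tibble::tibble(cell_id = 1:6, f_ex = c(5, 5, -3, -3, -3, -3),
                       f_const = rep(1.2, 6))
  rec <- feature_specificity(ft, cl)
  s <- 2 / 6
  ex1 <- rec[rec$variable == "f_ex" & rec$cluster == 1, ]
  expect_equal(ex1$A, 1)
  expect_equal(ex1$B, 1 / s)                  # raw share 1 over relative size
  expect_equal(ex1$C, 2 * (1 / s) / (1 + 1 / s))
  # constant feature: normalised B is 1 everywhere, C identical across clusters
  cst <- rec[rec$variable == "f_const", ]
  expect_equal(cst$B, rep(1, 2))
  expect_equal(cst$C[1], cst$C[2])
  # clipping: a value of 5 in a standardised table contributes as 2
  ft2 <- tibble::tibble(cell_id = 1:6, f = c(5, 2, 0, 0, 0, 0))
  M <- pmin(pmax(ft2$f, -2), 2)
  expect_equal(max(M), 2)
  rec2 <- feature_specificity(ft2, cl)
  expect_equal(rec2$A[rec2$cluster == 1], 1)  # 5 clipped to 2, the scale max
})

test_that("representative cells and feature extremes match brute force", {
  for (trial in 1:20) {
    set.seed(trial + 40)
    n <- 15
    X <- matrix(rnorm(n * 4), n, 4)
    colnames(X) <- paste0("f", 1:4)
    feats <- dplyr::bind_cols(tibble::tibble(cell_id = sample(100, n)),
                              tibble::as_tibble(X))
    members <- sample(feats$cell_id, 8)
    got <- representative_cell(feats, members)
    # naive median-then-argmin loop
    sub <- feats[match(members, feats$cell_id), ]
    med <- apply(as.matrix(sub[, -1]), 2, median)
    dd <- apply(as.matrix(sub[, -1]), 1, function(r) sqrt(sum((r - med)^2)))
    best <- min(sub$cell_id[dd == min(dd)])
    expect_identical(got, best)

    ex <- feature_extremes(feats, "f2", k = 3)
    ord <- order(feats$f2, feats$cell_id)
    expect_identical(ex$lowest, feats$cell_id[ord[1:3]])
    expect_identical(ex$highest, feats$cell_id[rev(ord)[1:3]])
  }
  # hand cases
  f <- tibble::tibble(cell_id = c(10, 11, 12), v = c(3, 1, 2))
  ex <- feature_extremes(f, "v", 1)
  expect_identical(ex$lowest, 11)
  expect_identical(ex$highest, 10)
  ex_all <- feature_extremes(f, "v", 3)
  expect_setequal(ex_all$lowest, f$cell_id)
  expect_identical(representative_cell(f[1, ], 10), 10)
  tie <- tibble::tibble(cell_id = c(7, 3), v = c(1, 1))
  expect_identical(representative_cell(tie, tie$cell_id), 3)
  expect_error(feature_extremes(f, 99L), "invalid feature index")
})
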