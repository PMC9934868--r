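component_names <- c("cell_shape", "cell_coarse", "cell_fine",
                     "nuc_shape", "nuc_coarse", "nuc_fine")

feature_colnames <- function(out_dim = 80L) {
  unlist(lapply(component_names, function(cn) sprintf("%s_%02d", cn, 0:(out_dim - 1))))
}

#' Pipeline configuration
#'
#' Bundles the extraction and encoder settings used by [embed_all()] and the
#' training helpers. The `"reference"` profile mirrors the whole-animal SBEM
#' setup (144/104 train crops, 1024-point clouds, 64-channel encoders); the
#' `"desk"` profile is the package's scaled-down study condition for
#' phantom-volume experiments on one CPU (small crops matched to phantom
#' cell sizes, 192-point clouds, narrow encoders), used by the test suite
#' and the acceptance script.
#'
#' @param profile `"desk"` or `"reference"`.
#' @return A named list of configuration blocks.
#' @export
pipeline_config <- function(profile = c("desk", "reference")) {
  profile <- match.arg(profile)
  if (profile == "reference") {
    list(profile = profile,
         crop_size = c(cytoplasm = NA_integer_, nucleus = NA_integer_),  # mode defaults
         fine = list(cytoplasm = list(patch_size = 32L, upsample = 1L),
                     nucleus = list(patch_size = 32L, upsample = 1L)),
         n_points = 1024L,
         mesh = list(target_faces = 5000L, smoothing_iters = 10L),
         n_views = 10L,
         shape = shape_encoder_config(),
         texture = texture_encoder_config(),
         shape_train = list(lr = 2e-4, weight_decay = 4e-4, temperature = 0.5),
         texture_train = list(lr = 1e-4, weight_decay = 5e-5),
         deform = list(cytoplasm = deform_config(), nucleus = deform_config()))
  } else {
    list(profile = profile,
         crop_size = c(cytoplasm = 24L, nucleus = 16L),
         fine = list(cytoplasm = list(patch_size = 16L, upsample = 3L),
                     nucleus = list(patch_size = 16L, upsample = 4L)),
         n_points = 192L,
         mesh = list(target_faces = 800L, smoothing_iters = 10L),
         n_views = 6L,
         shape = shape_encoder_config(k_neighbours = 8L, n_graph_layers = 2L,
                                      hidden_width = 24L, fuse_width = 48L,
                                      mlp_width = 48L),
         texture = texture_encoder_config(base_channels = 4L, convs_per_block = 1L),
         # the narrow desk encoders with 8-cell batches barely move at the
         # reference rates within a few hundred iterations; the desk profile
         # trains shape hotter and sharper
         shape_train = list(lr = 1e-3, weight_decay = 4e-4, temperature = 0.2),
         texture_train = list(lr = 1e-4, weight_decay = 5e-5),
         # nuclear identity is subtle at phantom scale: deform nucleus views
         # more gently than cell views
         deform = list(cytoplasm = deform_config(),
                       nucleus = deform_config(displacement_scale = 0.03,
                                               handle_radius = 0.08,
                                               scale_range = c(0.97, 1.03))))
  }
}

#' Assemble per-cell morphology descriptors
#'
#' Runs all six trained encoders over every cell of a volume and
#' concatenates the six 80-dimensional embeddings in the fixed component
#' order `cell_shape, cell_coarse, cell_fine, nuc_shape, nuc_coarse,
#' nuc_fine` into a 480-dimensional descriptor per cell. Fine-texture patch
#' embeddings are averaged into one vector per cell and compartment. Cells
#' that fail any extraction stage (no nucleus, no retained fine patch, mesh
#' failure) receive no row and are listed in the `excluded` attribute.
#'
#' @param volume a [labeled_volume()].
#' @param checkpoints named list with entries `cell_shape`, `cell_coarse`,
#'   `cell_fine`, `nuc_shape`, `nuc_coarse`, `nuc_fine`, each a checkpoint
#'   (`weights` + `encoder_cfg`) from training or `init_*` weights.
#' @param config a [pipeline_config()].
#' @param cell_ids cells to process (default: all nonzero labels).
#' @param meshes optional precomputed list with `cell` and `nucleus` named
#'   mesh lists (skips re-meshing).
#' @param seed RNG seed for point-cloud sampling.
#' @return Tibble `cell_id` + 480 feature columns; attributes `layout`
#'   (component order) and `excluded` (tibble of cell_id, reason).
#' @export
embed_all <- function(volume, checkpoints, config = pipeline_config("desk"),
                      cell_ids = NULL, meshes = NULL, seed = 1L) {
  for (nm in component_names) {
    assert_that(!is.null(checkpoints[[nm]]), sprintf("missing checkpoint: %s", nm))
  }
  if (is.null(cell_ids)) {
    cell_ids <- sort(setdiff(unique(as.vector(volume$cell_labels)), 0L))
  }
  rows <- list(); excluded <- list()
  for (id in cell_ids) {
    row <- tryCatch(
      embed_one(volume, id, checkpoints, config, meshes, seed),
      error = function(e) conditionMessage(e))
    if (is.character(row)) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(cell_id = id, reason = row)
    } else {
      rows[[length(rows) + 1L]] <- c(cell_id = id, row)
    }
  }
  assert_that(length(rows) > 0, "no cell could be embedded")
  m <- do.call(rbind, rows)
  colnames(m) <- c("cell_id", feature_colnames())
  out <- tibble::as_tibble(m)
  attr(out, "layout") <- component_names
  attr(out, "excluded") <- if (length(excluded)) dplyr::bind_rows(excluded) else
    tibble::tibble(cell_id = integer(0), reason = character(0))
  out
}

embed_one <- function(volume, id, checkpoints, config, meshes, seed) {
  out <- numeric(0)
  for (comp in c("cell", "nuc")) {
    labels <- if (comp == "cell") volume$cell_labels else volume$nucleus_labels
    compartment <- if (comp == "cell") "cytoplasm" else "nucleus"
    # shape
    mesh <- if (!is.null(meshes)) {
      meshes[[if (comp == "cell") "cell" else "nucleus"]][[as.character(id)]]
    } else NULL
    if (is.null(mesh)) {
      mesh <- build_mesh(labels, id,
                         smoothing_iters = config$mesh$smoothing_iters,
                         target_faces = config$mesh$target_faces,
                         voxel_size_nm = volume$voxel_size_nm)
    }
    cloud <- sample_point_cloud(mesh, config$n_points, seed = derive_seed(seed, id))
    ck <- checkpoints[[paste0(comp, "_shape")]]
    emb_shape <- encode_shape(cloud, ck$encoder_cfg, ck$weights)
    # coarse texture
    cs <- config$crop_size[[compartment]]
    crop <- extract_coarse_crop(volume, id, compartment, "train",
                                crop_size = if (is.na(cs)) NULL else cs)
    assert_that(!is.null(crop), sprintf("cell %d: no nucleus", id))
    mask <- crop$values > 0
    assert_that(any(mask), sprintf("cell %d: empty %s crop", id, compartment))
    ck <- checkpoints[[paste0(comp, "_coarse")]]
    emb_coarse <- encode_texture(crop$values, mask, ck$encoder_cfg, ck$weights)$embedding
    # fine texture: average patch embeddings
    fcfg <- config$fine[[compartment]]
    fp <- extract_fine_patches(volume, id, compartment, fcfg$patch_size,
                               upsample = fcfg$upsample)
    assert_that(length(fp$patches) > 0,
                sprintf("cell %d: no fine patch retained (%s)", id, compartment))
    ck <- checkpoints[[paste0(comp, "_fine")]]
    pe <- vapply(fp$patches, function(p) {
      encode_texture(p, p > 0, ck$encoder_cfg, ck$weights)$embedding
    }, numeric(ck$encoder_cfg$out_dim))
    emb_fine <- rowMeans(matrix(pe, nrow = ck$encoder_cfg$out_dim))
    out <- c(out, emb_shape, emb_coarse, emb_fine)
  }
  out
}

#' Region adjacency graph of a cell segmentation
#'
#' Two cells are adjacent iff some face-adjacent (6-connectivity) voxel pair
#' carries their two labels; background (0) is never a node. Edges carry the
#' contact area in voxel faces.
#'
#' @param cell_labels 3D integer label array.
#' @return A `region_adjacency_graph`: `nodes` (ids) and `edges` tibble
#'   (`a`, `b`, `contact_area`).
#' @export
build_rag <- function(cell_labels) {
  d <- dim(cell_labels)
  counts <- list()
  for (ax in 1:3) {
    s <- c(0L, 0L, 0L); s[ax] <- 1L
    i1 <- lapply(1:3, function(j) seq_len(d[j] - s[j]))
    i2 <- lapply(1:3, function(j) seq_len(d[j] - s[j]) + s[j])
    a <- cell_labels[i1[[1]], i1[[2]], i1[[3]]]
    b <- cell_labels[i2[[1]], i2[[2]], i2[[3]]]
    keep <- a != b & a > 0L & b > 0L
    if (any(keep)) {
      counts[[length(counts) + 1L]] <-
        data.frame(a = pmin(a[keep], b[keep]), b = pmax(a[keep], b[keep]))
    }
  }
  nodes <- sort(setdiff(unique(as.vector(cell_labels)), 0L))
  edges <- if (length(counts)) {
    df <- do.call(rbind, counts)
    ag <- stats::aggregate(list(contact_area = rep(1L, nrow(df))), df, sum)
    tibble::as_tibble(ag[order(ag$a, ag$b), ])
  } else {
    tibble::tibble(a = integer(0), b = integer(0), contact_area = integer(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "region_adjacency_graph")
}

#' @export
print.region_adjacency_graph <- function(x, ...) {
  cat(sprintf("<region_adjacency_graph> %d cells, %d contact edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Neighbourhood context features
#'
#' For every cell, the neighbourhood part is the mean of its own descriptor
#' and the descriptors of its region-adjacency neighbours (the mean includes
#' the cell itself); it is concatenated after the cell's own features,
#' doubling the descriptor to 960 dimensions.
#'
#' @param features tibble `cell_id` + feature columns (from [embed_all()]).
#' @param graph a [build_rag()] result.
#' @return Tibble `cell_id`, original columns, then `ctx_`-prefixed
#'   neighbourhood-mean columns.
#' @export
context_features <- function(features, graph) {
  ids <- features$cell_id
  X <- as.matrix(features[, setdiff(names(features), "cell_id")])
  nb <- lapply(ids, function(i) {
    c(graph$edges$b[graph$edges$a == i], graph$edges$a[graph$edges$b == i])
  })
  ctx <- matrix(0, nrow(X), ncol(X))
  for (r in seq_along(ids)) {
    group <- c(ids[r], nb[[r]])
    ridx <- match(group, ids)
    if (anyNA(ridx)) {
      stop(sprintf("no feature row for neighbour %d of cell %d",
                   group[which(is.na(ridx))[1]], ids[r]), call. = FALSE)
    }
    ctx[r, ] <- colMeans(X[ridx, , drop = FALSE])
  }
  colnames(ctx) <- paste0("ctx_", colnames(X))
  dplyr::bind_cols(features, tibble::as_tibble(ctx))
}

#' Standardise feature columns
#'
#' Centres every feature column to zero mean and scales to unit variance
#' across cells; zero-variance columns map to all-zeros. The transform
#' parameters are attached so the same scaling can be reapplied to new rows.
#'
#' @param features tibble `cell_id` + numeric feature columns.
#' @param transform optional transform (from a previous call) to reuse.
#' @return Standardised tibble with attribute `transform` (`center`, `scale`).
#' @export
standardize_features <- function(features, transform = NULL) {
  assert_that(nrow(features) >= 2, "need at least 2 rows to standardise")
  cols <- setdiff(names(features), "cell_id")
  X <- as.matrix(features[, cols])
  if (is.null(transform)) {
    ctr <- colMeans(X)
    # population variance (n divisor), as in the usual standard scaler
    scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
    transform <- list(center = ctr, scale = scl)
  }
  Xs <- sweep(X, 2, transform$center)
  nz <- transform$scale > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, transform$scale[nz], `/`)
  Xs[, !nz] <- 0
  out <- dplyr::bind_cols(features["cell_id"], tibble::as_tibble(Xs))
  attr(out, "transform") <- transform
  out
}

#' Write / read a feature table as TSV
#'
#' First column `cell_id`, then named feature columns; compatible with
#' atlas-browser table conventions.
#'
#' @param features feature tibble.
#' @param path file path.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_feature_table <- function(features, path) {
  write.table(as.data.frame(features), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(read.delim(path, check.names = FALSE))
}
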