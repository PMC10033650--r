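# Tile embedding and the block rearrangement between the k x d bag matrix
# and its image-like square form.
#
# A backbone is any function mapping a [side, side, 3] tile to a length-d
# numeric vector, with attributes `d` (output length) and `id`. The study
# design uses global-average-pooled DenseNet-121 features (d = 1024); the
# backbones shipped here are deterministic stand-ins so that the full
# pipeline runs without pretrained weights.

#' Mean-RGB stub backbone
#'
#' Embeds a tile as its three channel means recycled to length `d`.
#' Useful as an analytic oracle: the embedding is a closed-form function
#' of the tile.
#'
#' @param d embedding length.
#' @return a backbone function.
#' @export
backbone_mean_rgb <- function(d = 1024L) {
  f <- function(tile) {
    m <- c(mean(tile[, , 1]), mean(tile[, , 2]), mean(tile[, , 3]))
    rep_len(m, d)
  }
  attr(f, "d") <- as.integer(d)
  attr(f, "id") <- sprintf("mean_rgb_%d", d)
  f
}

#' Seeded random-projection backbone
#'
#' Mean-pools the tile to `pool_to` x `pool_to` per channel and applies a
#' fixed random linear map to a `d`-vector. Deterministic given `seed`;
#' stands in for a CNN feature extractor in tests and demos.
#'
#' @param d embedding length.
#' @param pool_to pooled side length per channel before projection.
#' @param seed seed for the projection matrix.
#' @return a backbone function.
#' @export
backbone_random_projection <- function(d = 1024L, pool_to = 8L, seed = 7L) {
  p <- 3L * pool_to^2
  W <- with_seed(seed, matrix(stats::rnorm(p * d, sd = 1 / sqrt(p)), p, d))
  f <- function(tile) {
    pooled <- vapply(1:3, function(ch)
      as.vector(pool_matrix(tile[, , ch], pool_to)), numeric(pool_to^2))
    as.vector(c(pooled) %*% W)
  }
  attr(f, "d") <- as.integer(d)
  attr(f, "id") <- sprintf("random_projection_%d_seed%d", d, seed)
  f
}

# Mean-pool a matrix to target x target (sides need not divide evenly;
# bins are as equal as possible).
pool_matrix <- function(m, target) {
  rb <- as.integer(cut(seq_len(nrow(m)), target))
  cb <- as.integer(cut(seq_len(ncol(m)), target))
  out <- matrix(0, target, target)
  for (i in seq_len(target))
    for (j in seq_len(target))
      out[i, j] <- mean(m[rb == i, cb == j])
  out
}

#' Embed the tiles of a bag into a k x d matrix
#'
#' Row `i` is the backbone embedding of the tile in slot `i` (the tile
#' drawn from the i-th spatially sorted cluster); cluster sort order is
#' preserved.
#'
#' @param bag a `wsi_bag` from [sample_bags()].
#' @param reader a slide reader serving high-magnification tiles.
#' @param backbone a backbone function (see [backbone_random_projection()]).
#' @param tile_side_hi tile side in high-magnification pixels.
#' @param tile_side_thumb,pixel_size_factor grid geometry used to map grid
#'   coordinates to pixel origins.
#' @return numeric matrix `k x d`.
#' @export
embed_tiles <- function(bag, reader, backbone, tile_side_hi = 224L,
                        tile_side_thumb = 14L, pixel_size_factor = 16L) {
  d <- attr(backbone, "d")
  k <- nrow(bag$tiles)
  out <- matrix(0, k, d)
  for (i in seq_len(k)) {
    x <- bag$tiles$grid_col[i] * tile_side_thumb * pixel_size_factor
    y <- bag$tiles$grid_row[i] * tile_side_thumb * pixel_size_factor
    v <- backbone(read_tile(reader, x, y, tile_side_hi))
    if (length(v) != d)
      stop_mf("backbone returned length %d, expected d=%d", length(v), d,
              class = "mf_shape_error")
    out[i, ] <- v
  }
  out
}

grid_block_sides <- function(k, d) {
  g <- sqrt(k); b <- sqrt(d)
  if (abs(g - round(g)) > 1e-9 || abs(b - round(b)) > 1e-9)
    stop_mf(paste0("rearrangement needs k = g^2 and d = b^2 ",
                   "(got k=%d, d=%d); the image side is g*b"), k, d,
            class = "mf_shape_error")
  c(g = as.integer(round(g)), b = as.integer(round(b)))
}

#' Rearrange a k x d bag matrix into its square image form
#'
#' The k tile embeddings (k = g^2, d = b^2) are laid out on a g x g grid of
#' b x b blocks: block (r, c), row-major, holds embedding `g*r + c`
#' reshaped row-major to b x b. With k = 49, d = 1024 this is the 224 x 224
#' matrix consumed by the stride-32 patch projection. The map is an exact
#' bijection; see [inverse_rearrange()].
#'
#' @param bag_matrix numeric k x d matrix.
#' @return numeric (g*b) x (g*b) matrix.
#' @export
rearrange_to_image <- function(bag_matrix) {
  gb <- grid_block_sides(nrow(bag_matrix), ncol(bag_matrix))
  g <- gb["g"]; b <- gb["b"]
  img <- matrix(0, g * b, g * b)
  for (r in seq_len(g) - 1L) {
    for (cc in seq_len(g) - 1L) {
      block <- matrix(bag_matrix[g * r + cc + 1L, ], b, b, byrow = TRUE)
      img[r * b + seq_len(b), cc * b + seq_len(b)] <- block
    }
  }
  img
}

#' Invert the block rearrangement
#'
#' Exact inverse of [rearrange_to_image()] (bit-equal round trip).
#'
#' @param image_form square matrix of side g*b.
#' @param grid g, the tile grid side (7 for k = 49).
#' @return numeric k x d matrix.
#' @export
inverse_rearrange <- function(image_form, grid = NULL) {
  side <- nrow(image_form)
  if (ncol(image_form) != side)
    stop_mf("image form must be square, got %dx%d", nrow(image_form),
            ncol(image_form), class = "mf_shape_error")
  if (is.null(grid)) {
    # infer: largest g with g*b = side, b = side/g, both integer and g^2*b^2
    # matching; default study geometry has g < b, try g from 2..side
    g <- integer(0)
    for (cand in 2:(side - 1))
      if (side %% cand == 0L) { g <- cand; break }
    if (side == 1L) g <- 1L
    if (length(g) == 0L)
      stop_mf("cannot infer grid side from image side %d; pass `grid`",
              side, class = "mf_shape_error")
  } else g <- as.integer(grid)
  if (side %% g != 0L)
    stop_mf("image side %d not divisible by grid %d", side, g,
            class = "mf_shape_error")
  b <- side %/% g
  M <- matrix(0, g * g, b * b)
  for (r in seq_len(g) - 1L) {
    for (cc in seq_len(g) - 1L) {
      block <- image_form[r * b + seq_len(b), cc * b + seq_len(b)]
      M[g * r + cc + 1L, ] <- as.vector(t(block))
    }
  }
  M
}

#' Write bag embeddings for one slide to a delimited-text store
#'
#' One directory per store; per slide a TSV of `n_bags * k` rows
#' (`bag_index`, `tile_index`, then the d embedding dimensions) plus a JSON
#' manifest recording `d`, `k`, the backbone id and the seed.
#'
#' @param dir store directory (created if needed).
#' @param slide_id slide identifier (file stem).
#' @param embeddings array `n_bags x k x d` or a list of k x d matrices.
#' @param backbone_id,seed provenance recorded in the manifest.
#' @return invisibly, the path of the written TSV.
#' @export
write_embedding_store <- function(dir, slide_id, embeddings,
                                  backbone_id = "unknown", seed = NA) {
  if (is.list(embeddings)) {
    k <- nrow(embeddings[[1]]); d <- ncol(embeddings[[1]])
    arr <- array(0, c(length(embeddings), k, d))
    for (i in seq_along(embeddings)) arr[i, , ] <- embeddings[[i]]
    embeddings <- arr
  }
  dims <- dim(embeddings)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- matrix(aperm(embeddings, c(3, 2, 1)), ncol = dims[3],
                 byrow = TRUE)
  df <- data.frame(bag_index = rep(seq_len(dims[1]), each = dims[2]),
                   tile_index = rep(seq_len(dims[2]), dims[1]))
  df <- cbind(df, as.data.frame(flat))
  path <- file.path(dir, paste0(slide_id, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- file.path(dir, paste0(slide_id, ".json"))
  jsonlite::write_json(list(slide_id = slide_id, n_bags = dims[1],
                            k = dims[2], d = dims[3],
                            backbone = backbone_id, seed = seed),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read one slide's bag embeddings back from a store
#' @param dir store directory.
#' @param slide_id slide identifier.
#' @return array `n_bags x k x d`.
#' @export
read_embedding_store <- function(dir, slide_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(slide_id, ".json")),
                              simplifyVector = TRUE)
  df <- utils::read.delim(file.path(dir, paste0(slide_id, ".tsv")))
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  arr <- array(0, c(meta$n_bags, meta$k, meta$d))
  for (b in seq_len(meta$n_bags))
    arr[b, , ] <- vals[df$bag_index == b, , drop = FALSE]
  arr
}
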