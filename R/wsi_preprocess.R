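# Tissue masking, tile selection, spatial clustering and bag sampling.
#
# All images are plain R arrays indexed [row, col, channel] with values in
# [0, 1], matching png::readPNG(). Tile grids are 0-based, row-major, with
# the origin at the top-left corner and half-open tile footprints.

#' Compute a binary tissue mask from a low-magnification thumbnail
#'
#' Segments tissue on a 1.25x-style RGB thumbnail. Pixels are converted to
#' HSV; tissue pixels are those whose saturation exceeds an Otsu threshold
#' and whose value lies below a near-white cutoff. Saturated marker-pen
#' pixels (hue inside `marker_hues`) are removed, as are connected
#' components smaller than `min_area` pixels.
#'
#' @param image RGB array `[row, col, 3]`, values in `[0, 1]`, min side
#'   >= 14 px.
#' @param value_max near-white cutoff on HSV value; pixels at or above it
#'   are background.
#' @param marker_hues length-2 hue interval (in `[0, 1]`, blue/green band by
#'   default) treated as marker ink when saturated.
#' @param marker_sat_min minimum saturation for a pixel to count as marker.
#' @param min_area connected components smaller than this many pixels are
#'   dropped (area opening).
#' @param pixel_size_factor integer scale between this thumbnail and the
#'   high-magnification level (16 for 20x vs 1.25x).
#' @return An object of class `tissue_mask`: list with `mask` (integer 0/1
#'   matrix of the thumbnail's size) and `pixel_size_factor`. An
#'   all-background image yields a valid all-zero mask.
#' @export
compute_tissue_mask <- function(image, value_max = 0.9,
                                marker_hues = c(0.45, 0.75),
                                marker_sat_min = 0.5,
                                min_area = 64L,
                                pixel_size_factor = 16L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_mf("compute_tissue_mask() needs an RGB array [row, col, 3], got dims %s",
            paste(dim(image), collapse = "x"), class = "mf_format_error")
  if (min(dim(image)[1:2]) < 14L)
    stop_mf("thumbnail too small: min side is %d px, need >= 14",
            min(dim(image)[1:2]), class = "mf_format_error")
  nr <- dim(image)[1]; nc <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- matrix(hsv[1L, ], nr, nc)
  s <- matrix(hsv[2L, ], nr, nc)
  v <- matrix(hsv[3L, ], nr, nc)

  thr <- EBImage::otsu(EBImage::Image(s), range = c(0, 1))
  tissue <- s > thr & v < value_max
  marker <- h >= marker_hues[1] & h <= marker_hues[2] & s >= marker_sat_min
  mask <- tissue & !marker

  if (any(mask) && min_area > 1L) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    areas <- tabulate(as.integer(EBImage::imageData(lab)))
    keep <- which(areas >= min_area)
    mask <- matrix(as.integer(EBImage::imageData(lab)) %in% keep, nr, nc)
  }

  structure(list(mask = matrix(as.integer(mask), nr, nc),
                 pixel_size_factor = as.integer(pixel_size_factor)),
            class = "tissue_mask")
}

#' Thumbnail-scale tile side equivalent to a high-magnification tile
#'
#' A 224 px tile at 20x covers the same tissue area as a 14 px tile at
#' 1.25x; this computes `tile_side_hi * mag_thumb / mag_hi` and insists on
#' an integer result so that grids at the two levels stay aligned.
#'
#' @param tile_side_hi tile side in pixels at the high-magnification level.
#' @param mag_hi,mag_thumb the two magnifications, `mag_hi > mag_thumb > 0`.
#' @return integer tile side at thumbnail scale.
#' @examples
#' thumb_tile_side(224, 20, 1.25)  # 14
#' @export
thumb_tile_side <- function(tile_side_hi = 224L, mag_hi = 20, mag_thumb = 1.25) {
  if (!(mag_hi >= mag_thumb && mag_thumb > 0))
    stop_mf("need mag_hi >= mag_thumb > 0 (got mag_hi=%g, mag_thumb=%g)",
            mag_hi, mag_thumb, class = "mf_config_error")
  side <- tile_side_hi * mag_thumb / mag_hi
  if (abs(side - round(side)) > 1e-9)
    stop_mf(paste0("tile_side_hi=%g at mag_hi=%g does not map to an integer ",
                   "pixel count at mag_thumb=%g (got %g)"),
            tile_side_hi, mag_hi, mag_thumb, side, class = "mf_config_error")
  as.integer(round(side))
}

#' Select tile positions with sufficient tissue
#'
#' Scans a non-overlapping tile grid over the mask row-major from the
#' top-left and keeps tiles whose tissue fraction is at least
#' `min_tissue_frac` (a tile at exactly the threshold is kept; the rule
#' discards tiles with *less* than 50% tissue). Partial tiles at the right
#' and bottom edges are dropped.
#'
#' @param mask a [compute_tissue_mask()] result, or a plain 0/1 matrix.
#' @param tile_side_thumb tile side in thumbnail pixels (14).
#' @param min_tissue_frac minimum tissue fraction to keep a tile.
#' @param tile_side_hi tile side at the high-magnification level (224).
#' @param slide_id carried into error messages and the coordinate table.
#' @return data.frame with 0-based `grid_col`, `grid_row` plus attributes
#'   `tile_side_thumb`, `tile_side_hi`, `pixel_size_factor`.
#' @export
select_tile_positions <- function(mask, tile_side_thumb = 14L,
                                  min_tissue_frac = 0.5,
                                  tile_side_hi = 224L,
                                  slide_id = "slide") {
  psf <- 16L
  if (inherits(mask, "tissue_mask")) {
    psf <- mask$pixel_size_factor
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask), tile_side_thumb >= 1)
  n_rows <- nrow(mask) %/% tile_side_thumb
  n_cols <- ncol(mask) %/% tile_side_thumb
  keep_col <- integer(0); keep_row <- integer(0)
  for (gr in seq_len(n_rows) - 1L) {
    rows <- gr * tile_side_thumb + seq_len(tile_side_thumb)
    for (gc in seq_len(n_cols) - 1L) {
      cols <- gc * tile_side_thumb + seq_len(tile_side_thumb)
      if (mean(mask[rows, cols]) >= min_tissue_frac) {
        keep_col <- c(keep_col, gc); keep_row <- c(keep_row, gr)
      }
    }
  }
  if (length(keep_col) == 0L)
    stop_mf("no tissue tiles found in slide '%s' (mask %dx%d, tile side %d)",
            slide_id, nrow(mask), ncol(mask), tile_side_thumb,
            class = "mf_no_tissue_error")
  out <- data.frame(grid_col = keep_col, grid_row = keep_row)
  attr(out, "tile_side_thumb") <- as.integer(tile_side_thumb)
  attr(out, "tile_side_hi") <- as.integer(tile_side_hi)
  attr(out, "pixel_size_factor") <- as.integer(psf)
  attr(out, "slide_id") <- slide_id
  out
}

#' Map tile grid coordinates to high-magnification pixel origins
#'
#' @param coords data.frame from [select_tile_positions()].
#' @return data.frame with `x_hi`, `y_hi` pixel origins (0-based).
#' @export
tile_origin_hi <- function(coords) {
  side <- attr(coords, "tile_side_thumb") %||% 14L
  psf <- attr(coords, "pixel_size_factor") %||% 16L
  data.frame(x_hi = coords$grid_col * side * psf,
             y_hi = coords$grid_row * side * psf)
}

#' Map high-magnification pixel origins back to the thumbnail tile grid
#'
#' Inverse of [tile_origin_hi()]; together they are the identity on tile
#' coordinates.
#'
#' @param origins data.frame with `x_hi`, `y_hi`.
#' @param tile_side_thumb,pixel_size_factor grid geometry.
#' @return data.frame with `grid_col`, `grid_row`.
#' @export
tile_grid_from_hi <- function(origins, tile_side_thumb = 14L,
                              pixel_size_factor = 16L) {
  data.frame(grid_col = origins$x_hi %/% (tile_side_thumb * pixel_size_factor),
             grid_row = origins$y_hi %/% (tile_side_thumb * pixel_size_factor))
}

# k-means++ seeding on a point matrix; returns k row indices.
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((pts - matrix(pts[centers[1L], ], n, 2, byrow = TRUE))^2)
  for (i in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[i] <- sample.int(n, 1L)
    } else {
      centers[i] <- sample.int(n, 1L, prob = d2)
    }
    di <- rowSums((pts - matrix(pts[centers[i], ], n, 2, byrow = TRUE))^2)
    d2 <- pmin(d2, di)
  }
  centers
}

# Split the largest cluster to refill empty ones, then refit.
repair_empty_clusters <- function(pts, labels, centers, k, iter_max) {
  for (attempt in 1:10) {
    sizes <- tabulate(labels, nbins = k)
    if (all(sizes > 0L)) break
    for (empty in which(sizes == 0L)) {
      sizes <- tabulate(labels, nbins = k)
      big <- which.max(sizes)
      members <- which(labels == big)
      ctr <- colMeans(pts[members, , drop = FALSE])
      far <- members[which.max(rowSums(
        (pts[members, , drop = FALSE] -
           matrix(ctr, length(members), 2, byrow = TRUE))^2))]
      centers[empty, ] <- pts[far, ]
      labels[far] <- empty
    }
    fit <- suppressWarnings(
      stats::kmeans(pts, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"))
    labels <- fit$cluster
    centers <- fit$centers
  }
  list(labels = labels, centers = centers)
}

#' Cluster tile positions spatially with k-means
#'
#' Runs k-means (k-means++ seeding, several restarts, Lloyd iterations) on
#' the `(grid_col, grid_row)` coordinates of the selected tiles, then sorts
#' the cluster centers by ascending Euclidean norm (ties broken by x, then
#' y) so that cluster index encodes a stable spatial order. Empty clusters
#' are repaired by splitting the largest cluster. With exactly `k` points,
#' every point becomes its own cluster.
#'
#' @param coords data.frame from [select_tile_positions()].
#' @param k number of clusters (49 by default: one tile per cluster gives
#'   a 7x7 grid of embeddings).
#' @param seed RNG seed; the assignment is deterministic given
#'   `(coords, k, seed)`.
#' @param nstart restarts, best fit by total within-cluster sum of squares.
#' @param iter_max Lloyd iteration cap per restart.
#' @return An object of class `cluster_assignment`: list with `coords`,
#'   `labels` (1..k, in sorted-center numbering), `centers` (k x 2, sorted),
#'   `order` (permutation applied to the fit's centers), `k`,
#'   `tot_withinss`.
#' @export
cluster_tiles <- function(coords, k = 49L, seed = 1L, nstart = 10L,
                          iter_max = 100L) {
  pts <- cbind(x = coords$grid_col, y = coords$grid_row)
  n <- nrow(pts)
  if (n < k)
    stop_mf(paste0("only %d tile positions for k=%d clusters; lower k or ",
                   "reject the slide"), n, k, class = "mf_too_few_tiles_error")
  if (n == k) {
    labels <- seq_len(n)
    centers <- pts * 1.0
    tot <- 0
  } else {
    best <- NULL
    with_seed(seed, {
      for (r in seq_len(nstart)) {
        init <- pts[kmeanspp_init(pts, k), , drop = FALSE]
        # jitter exact duplicates among initial centers (distinct pts, so rare)
        fit <- suppressWarnings(
          stats::kmeans(pts, centers = init, iter.max = iter_max,
                        algorithm = "Lloyd"))
        rep <- repair_empty_clusters(pts, fit$cluster, fit$centers, k, iter_max)
        wss <- sum((pts - rep$centers[rep$labels, , drop = FALSE])^2)
        if (is.null(best) || wss < best$wss - 1e-12)
          best <- list(labels = rep$labels, centers = rep$centers, wss = wss)
      }
    })
    labels <- best$labels
    centers <- best$centers
    tot <- best$wss
  }
  ord <- order(sqrt(rowSums(centers^2)), centers[, 1], centers[, 2])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(coords = coords,
                 labels = relabel[labels],
                 centers = centers[ord, , drop = FALSE],
                 order = ord,
                 k = as.integer(k),
                 tot_withinss = tot),
            class = "cluster_assignment")
}

#' Sample bags of tiles from a cluster assignment
#'
#' Each bag draws exactly one tile uniformly at random from each of the `k`
#' spatially sorted clusters, independently across bags (with replacement
#' across bags). Tile order inside a bag follows the cluster sort order, so
#' slot `i` always holds a tile of cluster `i`.
#'
#' @param assignment a [cluster_tiles()] result.
#' @param n_bags number of bags (100 in the study protocol).
#' @param seed RNG seed.
#' @param slide_id,patient_id identifiers carried on every bag.
#' @param label optional integer class id.
#' @param gene_target optional numeric gene vector (log10(1+a) space).
#' @return list of `wsi_bag` objects; each has `slide_id`, `patient_id`,
#'   `bag_index`, `tiles` (data.frame cluster/grid_col/grid_row), `label`,
#'   `gene_target`.
#' @export
sample_bags <- function(assignment, n_bags = 100L, seed = 1L,
                        slide_id = "slide", patient_id = slide_id,
                        label = NA_integer_, gene_target = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (n_bags < 1L)
    stop_mf("n_bags must be >= 1, got %s", format(n_bags),
            class = "mf_argument_error")
  k <- assignment$k
  members <- split(seq_len(nrow(assignment$coords)), assignment$labels)
  if (length(members) != k || any(lengths(members) == 0L))
    stop_mf("assignment must have %d non-empty clusters", k,
            class = "mf_argument_error")
  with_seed(seed, {
    lapply(seq_len(n_bags), function(b) {
      idx <- vapply(members, function(m)
        if (length(m) == 1L) m else m[sample.int(length(m), 1L)], integer(1))
      tiles <- data.frame(cluster = seq_len(k),
                          grid_col = assignment$coords$grid_col[idx],
                          grid_row = assignment$coords$grid_row[idx])
      structure(list(slide_id = slide_id, patient_id = patient_id,
                     bag_index = b, tiles = tiles, label = label,
                     gene_target = gene_target),
                class = "wsi_bag")
    })
  })
}

#' Flatten bags into a delimited-text manifest
#'
#' @param bags list of `wsi_bag` objects.
#' @return data.frame with one row per (bag, cluster slot): `slide_id`,
#'   `patient_id`, `bag_index`, `cluster_index`, `grid_col`, `grid_row`.
#' @export
bag_manifest <- function(bags) {
  do.call(rbind, lapply(bags, function(b) {
    data.frame(slide_id = b$slide_id, patient_id = b$patient_id,
               bag_index = b$bag_index, cluster_index = b$tiles$cluster,
               grid_col = b$tiles$grid_col, grid_row = b$tiles$grid_row)
  }))
}

#' Serialize a cluster assignment to JSON
#' @param assignment a [cluster_tiles()] result.
#' @param path file to write; omitted returns the JSON string.
#' @export
write_cluster_assignment <- function(assignment, path = NULL) {
  obj <- list(k = assignment$k,
              labels = assignment$labels,
              centers = unname(apply(assignment$centers, 1, as.numeric,
                                     simplify = FALSE)),
              order = assignment$order,
              coords = assignment$coords,
              tot_withinss = assignment$tot_withinss)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
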