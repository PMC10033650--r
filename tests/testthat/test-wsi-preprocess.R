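# Tissue masking, tile selection, spatial clustering and bag sampling.

test_that("tissue mask removes background and marker ink, keeps blobs", {
  white <- array(1, c(32, 32, 3))
  expect_equal(sum(compute_tissue_mask(white)$mask), 0)

  th <- generate_thumbnail(140, 140, n_blobs = 2, marker = FALSE, seed = 5)
  mask <- compute_tissue_mask(th$image)
  expect_true(jaccard(mask$mask == 1, th$tissue_mask == 1) >= 0.9)

  thm <- generate_thumbnail(140, 140, n_blobs = 2, marker = TRUE, seed = 9)
  maskm <- compute_tissue_mask(thm$image)
  expect_equal(sum(maskm$mask == 1 & thm$marker_mask == 1), 0)
  expect_true(jaccard(maskm$mask == 1, thm$tissue_mask == 1) >= 0.9)

  expect_error(compute_tissue_mask(matrix(1, 20, 20)), "RGB",
               class = "mf_format_error")
})

test_that("thumbnail tile side follows the magnification ratio", {
  expect_identical(thumb_tile_side(224, 20, 1.25), 14L)
  expect_identical(thumb_tile_side(224, 20, 20), 224L)
  expect_identical(thumb_tile_side(512, 40, 2.5), 32L)
  err <- tryCatch(thumb_tile_side(100, 20, 1.25), error = identity)
  expect_s3_class(err, "mf_config_error")
  # the error names all three inputs
  expect_match(conditionMessage(err), "100")
  expect_match(conditionMessage(err), "20")
  expect_match(conditionMessage(err), "1.25")
})

test_that("tile selection keeps tiles at the 50% boundary and matches a
          per-pixel counting oracle", {
  full <- matrix(1L, 28, 28)
  sel <- select_tile_positions(full, tile_side_thumb = 14)
  expect_equal(nrow(sel), 4)
  expect_setequal(paste(sel$grid_col, sel$grid_row),
                  c("0 0", "1 0", "0 1", "1 1"))

  # exactly half tissue (98 of 196 px) is kept
  half <- matrix(0L, 14, 14); half[seq_len(98)] <- 1L
  expect_equal(nrow(select_tile_positions(half, tile_side_thumb = 14)), 1)
  # one pixel less is dropped
  under <- matrix(0L, 14, 14); under[seq_len(97)] <- 1L
  expect_error(select_tile_positions(under, tile_side_thumb = 14,
                                     slide_id = "sl-7"),
               "sl-7", class = "mf_no_tissue_error")

  for (seed in 1:3) {
    m <- withr::with_seed(seed, matrix(rbinom(70 * 70, 1, 0.5), 70, 70))
    got <- select_tile_positions(m, tile_side_thumb = 14)
    want <- brute_tile_filter(m, 14L, 0.5)
    expect_equal(got$grid_col, want$grid_col)
    expect_equal(got$grid_row, want$grid_row)
  }
})

test_that("grid-to-pixel mapping round-trips exactly", {
  m <- matrix(1L, 70, 70)
  coords <- select_tile_positions(m, tile_side_thumb = 14)
  back <- tile_grid_from_hi(tile_origin_hi(coords))
  expect_equal(back$grid_col, coords$grid_col)
  expect_equal(back$grid_row, coords$grid_row)
})

test_that("k-means clustering partitions tiles and recovers blobs", {
  # n == k: every tile its own cluster, zero within-cluster variance
  coords <- expand.grid(grid_col = 0:6, grid_row = 0:6)
  asg <- cluster_tiles(coords, k = 49, seed = 1)
  expect_equal(sort(tabulate(asg$labels, 49)), rep(1L, 49))
  expect_equal(asg$tot_withinss, 0)

  # 9 tight, well-separated blobs of 10 points -> perfect recovery
  blob_centers <- expand.grid(x = c(0, 60, 120), y = c(0, 60, 120))
  pts <- withr::with_seed(4, do.call(rbind, lapply(seq_len(9), function(b)
    data.frame(grid_col = blob_centers$x[b] + sample(0:3, 10, TRUE),
               grid_row = blob_centers$y[b] + sample(0:3, 10, TRUE),
               blob = b))))
  asg2 <- cluster_tiles(pts[, 1:2], k = 9, seed = 2)
  expect_equal(rand_index_adjusted(asg2$labels, pts$blob), 1)

  # partition property + center ordering by ascending norm
  expect_equal(sum(tabulate(asg2$labels, 9)), nrow(pts))
  norms <- sqrt(rowSums(asg2$centers^2))
  expect_true(all(diff(norms) >= 0))

  expect_error(cluster_tiles(coords[1:10, ], k = 49),
               class = "mf_too_few_tiles_error")
})

test_that("clustering and bag sampling are deterministic under a seed", {
  coords <- withr::with_seed(3, data.frame(grid_col = sample(0:40, 120, TRUE),
                                           grid_row = sample(0:40, 120, TRUE)))
  coords <- unique(coords)
  a1 <- cluster_tiles(coords, k = 12, seed = 99)
  a2 <- cluster_tiles(coords, k = 12, seed = 99)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$centers, a2$centers)
  b1 <- sample_bags(a1, n_bags = 20, seed = 5, slide_id = "s")
  b2 <- sample_bags(a2, n_bags = 20, seed = 5, slide_id = "s")
  expect_identical(bag_manifest(b1), bag_manifest(b2))
})

test_that("bags draw one tile per sorted cluster", {
  coords <- expand.grid(grid_col = 0:9, grid_row = 0:9)
  asg <- cluster_tiles(coords, k = 10, seed = 1)
  bags <- sample_bags(asg, n_bags = 30, seed = 2, slide_id = "s1",
                      patient_id = "p1", label = 2L)
  expect_length(bags, 30)
  members <- split(seq_len(nrow(coords)), asg$labels)
  for (bag in bags) {
    expect_equal(bag$tiles$cluster, 1:10)
    for (i in 1:10) {
      row <- which(coords$grid_col == bag$tiles$grid_col[i] &
                     coords$grid_row == bag$tiles$grid_row[i])
      expect_true(row %in% members[[i]])
    }
  }

  # degenerate: singleton clusters make all bags identical
  single <- expand.grid(grid_col = c(0, 50), grid_row = c(0, 50))
  asg1 <- cluster_tiles(single, k = 4, seed = 1)
  bb <- sample_bags(asg1, n_bags = 5, seed = 3)
  for (b in bb[-1]) expect_identical(b$tiles, bb[[1]]$tiles)

  expect_error(sample_bags(asg, n_bags = 0), class = "mf_argument_error")
})

test_that("cluster assignments serialize to JSON faithfully", {
  coords <- expand.grid(grid_col = 0:6, grid_row = 0:6)
  asg <- cluster_tiles(coords, k = 7, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_assignment(asg, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$k, 7)
  expect_equal(got$labels, asg$labels)
})

test_that("slide readers serve consistent thumbnails and tiles", {
  hi <- withr::with_seed(8, array(runif(64 * 64 * 3), c(64, 64, 3)))
  rd <- slide_reader_array(hi, mag_hi = 20, mag_thumb = 5)
  th <- read_thumbnail(rd)
  expect_equal(dim(th), c(16, 16, 3))
  expect_equal(th[1, 1, 1], mean(hi[1:4, 1:4, 1]))
  tile <- read_tile(rd, 8, 4, 16)
  expect_equal(tile, hi[5:20, 9:24, , drop = FALSE])

  # image-backed reader replicates thumbnail pixels
  rd2 <- slide_reader_image(th, mag_thumb = 5, mag_hi = 20)
  t2 <- read_tile(rd2, 0, 0, 8)
  expect_equal(dim(t2), c(8, 8, 3))
  expect_equal(t2[1, 1, ], t2[4, 4, ])  # same source pixel replicated 4x
})
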