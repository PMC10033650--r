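# The transformer, the conv-MLP baseline, aggregation and the loss.

test_that("forward output shapes and eval-mode determinism", {
  cf <- tiny_config()
  m <- init_transformer(cf, seed = 1)
  X <- withr::with_seed(2, matrix(rnorm(4 * 9), 4, 9))
  out <- model_forward(m, X)
  expect_length(out$c, cf$D)
  expect_length(out$logits, cf$n_classes)
  expect_equal(dim(out$tile_gene), c(cf$d_g, cf$k))

  out2 <- model_forward(m, X)
  expect_identical(out$c, out2$c)
  expect_identical(out$tile_gene, out2$tile_gene)

  expect_error(model_forward(m, X[1:3, ]), class = "mf_shape_error")
  # finite representation even for large-magnitude inputs
  big <- model_forward(m, X * 1e3)
  expect_true(all(is.finite(big$c)) && all(is.finite(big$tile_gene)))
})

test_that("permuting bag rows with matching position rows leaves outputs
          unchanged", {
  cf <- tiny_config()
  m <- init_transformer(cf, seed = 3)
  X <- withr::with_seed(4, matrix(rnorm(4 * 9), 4, 9))
  perm <- c(3, 1, 4, 2)
  m2 <- m
  m2$params$E_pos <- m$params$E_pos[c(1, perm + 1), ]
  a <- model_forward(m, X)
  b <- model_forward(m2, X[perm, ])
  expect_equal(a$c, b$c, tolerance = 1e-5)
  expect_equal(a$logits, b$logits, tolerance = 1e-5)
  expect_equal(a$tile_gene[, perm], b$tile_gene, tolerance = 1e-5)
})

test_that("patch projection equals the dense per-tile map", {
  cf <- model_config(L = 1, D = 12, heads = 2, k = 49, d = 1024, d_g = 4,
                     n_classes = 2, topn_choices = c(1, 5, 49))
  m <- init_transformer(cf, seed = 2)
  M <- withr::with_seed(3, matrix(rnorm(49 * 1024), 49, 1024))
  tok_conv <- patch_project(rearrange_to_image(M), m)
  tok_dense <- M %*% m$params$E +
    matrix(m$params$E_b, 49, 12, byrow = TRUE)
  expect_equal(tok_conv, tok_dense, tolerance = 1e-5)

  # constructed identity weights copy the first D embedding entries
  m$params$E <- rbind(diag(12), matrix(0, 1024 - 12, 12))
  m$params$E_b <- rep(0, 12)
  tok <- patch_project(rearrange_to_image(M), m)
  expect_equal(tok, M[, 1:12], tolerance = 1e-12)

  # zero input leaves bias-only tokens, identical across tiles
  m2 <- init_transformer(cf, seed = 5)
  m2$params$E_b <- runif(12)
  tok0 <- patch_project(matrix(0, 224, 224), m2)
  for (i in 2:49) expect_equal(tok0[i, ], tok0[1, ])
})

test_that("top-n aggregation matches brute force and its analytic limits", {
  s <- matrix(c(3, 1, 2), 1, 3)
  expect_equal(aggregate_topn(s, 2), 2.5)

  S <- withr::with_seed(6, matrix(rnorm(5 * 9), 5, 9))
  for (n in 1:9)
    expect_equal(aggregate_topn(S, n), brute_topn(S, n))
  expect_equal(aggregate_topn(S, 9), rowMeans(S))
  expect_equal(aggregate_topn(S, 1), apply(S, 1, max))

  # permutation invariance over tile columns
  perm <- withr::with_seed(7, sample(9))
  expect_equal(aggregate_topn(S[, perm], 4), aggregate_topn(S, 4))

  # monotone non-increasing in n
  for (rep in 1:20) {
    Sr <- matrix(rnorm(3 * 7), 3, 7)
    vals <- sapply(1:7, function(n) aggregate_topn(Sr, n))
    expect_true(all(apply(vals, 1, function(v) all(diff(v) <= 1e-12))))
  }

  expect_error(aggregate_topn(S, 0), class = "mf_argument_error")
  expect_error(aggregate_topn(S, 10), class = "mf_argument_error")
})

test_that("test-time aggregation: mean mode and literal harmonic mode", {
  sc <- matrix(5, 4, 49)
  expect_equal(aggregate_test(sc, "mean"), rep(5, 4))
  H49 <- sum(1 / (1:49))
  expect_equal(aggregate_test(sc, "literal"), rep(5 * H49, 4))

  s2 <- matrix(c(4, 2), 1, 2)
  expect_equal(aggregate_test(s2, "mean"), 3.5)   # (S(1)+S(2))/2 = (4+3)/2
  expect_equal(aggregate_test(s2, "literal"), 4 + 3 / 2)

  S <- withr::with_seed(8, matrix(rnorm(4 * 6), 4, 6))
  perm <- c(5, 2, 6, 1, 3, 4)
  expect_equal(aggregate_test(S[, perm], "mean"), aggregate_test(S, "mean"))
  expect_error(aggregate_test(S, "median"))
})

test_that("total loss decomposes into cross-entropy and scaled gene error", {
  cf <- tiny_config(gamma = 0)
  logits <- c(1.2, -0.3, 0.4)
  target <- c(0.5, -0.2, 1.0)
  pred <- c(0.4, 0.1, 0.8)
  l0 <- total_loss(logits, 2L, pred, target, cf)
  expect_equal(l0$total, l0$ce)
  expect_equal(l0$ce, -log(exp(-0.3) / sum(exp(logits))))

  cf5 <- tiny_config(gamma = 0.5)
  l <- total_loss(logits, 2L, pred, target, cf5)
  expect_equal(l$total, l$ce + 0.5 * mean((pred - target)^2))

  # perfect prediction in the large-margin limit
  lp <- total_loss(c(100, 0, 0), 1L, target, target, cf5)
  expect_lt(lp$total, 1e-8)

  # absolute-error variant
  cfa <- tiny_config(gamma = 0.5, gene_loss = "absolute")
  la <- total_loss(logits, 2L, pred, target, cfa)
  expect_equal(la$gene, mean(abs(pred - target)))

  expect_error(total_loss(logits, 7L, pred, target, cf5),
               class = "mf_argument_error")
  expect_error(total_loss(logits, 1L, pred, c(1, 2), cf5),
               class = "mf_argument_error")
})

test_that("baseline conv model equals a per-tile dense map and keeps shape", {
  cf <- tiny_config(dropout_head = 0)
  mh <- init_he2rna(cf, h = 6, seed = 4)
  X <- withr::with_seed(5, matrix(rnorm(4 * 9), 4, 9))
  out <- model_forward(mh, X)
  expect_equal(dim(out$tile_gene), c(cf$d_g, cf$k))
  expect_null(out$logits)

  # kernel-1 convolution over tiles == same dense map applied per tile
  p <- mh$params
  per_tile <- sapply(seq_len(nrow(X)), function(i) {
    a1 <- pmax(X[i, ] %*% p$W1 + p$b1, 0)
    a2 <- pmax(a1 %*% p$W2 + p$b2, 0)
    as.vector(a2 %*% p$W3 + p$b3)
  })
  expect_equal(out$tile_gene, per_tile, tolerance = 1e-5)

  expect_identical(out$tile_gene, model_forward(mh, X)$tile_gene)
})

test_that("parameter count closed form matches the instantiated model", {
  cf <- tiny_config()
  m <- init_transformer(cf, seed = 1)
  expect_identical(count_parameters(cf), count_parameters(m))

  big <- model_config(L = 8, D = 384, heads = 4, mlp_ratio = 4, k = 49,
                      d = 1024, d_g = 100, n_classes = 3)
  # classification head contributes D*n_classes + n_classes
  big4 <- model_config(L = 8, D = 384, heads = 4, mlp_ratio = 4, k = 49,
                       d = 1024, d_g = 100, n_classes = 4)
  expect_equal(count_parameters(big4) - count_parameters(big), 384 + 1)
  # position embedding contributes (k+1)*D
  big16 <- model_config(L = 8, D = 384, heads = 4, mlp_ratio = 4, k = 16,
                        d = 1024, d_g = 100, n_classes = 3,
                        topn_choices = c(1, 2, 5, 10, 16))
  expect_equal(count_parameters(big) - count_parameters(big16),
               (49 - 16) * 384)
})

test_that("config validation and JSON round trip", {
  expect_error(model_config(D = 10, heads = 4), class = "mf_config_error")
  expect_error(model_config(k = 10), class = "mf_config_error")
  expect_error(model_config(k = 9, topn_choices = c(1, 20)),
               class = "mf_config_error")
  cf <- tiny_config()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(cf, path)
  expect_equal(read_model_config(path), cf)
})
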