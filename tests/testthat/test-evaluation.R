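# Error metrics, correlation reports, multiple-testing corrections,
# classification metrics, PCA and the retrieval protocol.

test_that("error metrics follow their definitions and limits", {
  y <- c(1, 3, 2)
  em0 <- error_metrics(y, y)
  expect_equal(unlist(em0), c(mae = 0, rmse = 0, rrmse = 0))

  # the mean-predictor has RRMSE exactly 1
  emm <- error_metrics(rep(mean(y), 3), y)
  expect_equal(emm$rrmse, 1)

  # hand-computed case
  em <- error_metrics(c(1, 2, 3), c(1, 3, 2))
  expect_equal(em$mae, 2 / 3)
  expect_equal(em$rmse, sqrt(2 / 3))
  expect_equal(em$rrmse, 1)  # sum sq diffs 2 over denom 2

  # constant truth: RRMSE undefined, reported missing
  expect_true(is.na(error_metrics(c(1, 2, 3), c(2, 2, 2))$rrmse))

  # per-gene table carries a mean/sd summary
  pred <- withr::with_seed(1, matrix(rnorm(12), 3, 4))
  truth <- withr::with_seed(2, matrix(rnorm(12), 3, 4))
  tab <- gene_error_table(pred, truth)
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "summary")$mean[1], mean(tab$mae))
})

test_that("per-gene correlations match the covariance-formula oracle", {
  truth <- matrix(c(1, 2, 3, 4, 5,
                    2, 1, 4, 3, 5), 2, 5, byrow = TRUE)
  rep1 <- per_gene_correlation(truth, truth)
  expect_equal(rep1$pearson_r, c(1, 1))
  repm <- per_gene_correlation(-truth, truth)
  expect_equal(repm$pearson_r, c(-1, -1))

  pred <- withr::with_seed(3, matrix(rnorm(10), 2, 5))
  rp <- per_gene_correlation(pred, truth)
  for (g in 1:2) {
    x <- pred[g, ]; y <- truth[g, ]
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(rp$pearson_r[g], r_hand)
  }

  # zero-variance genes are flagged undefined and excluded from counts
  pred2 <- rbind(pred, 7)
  truth2 <- rbind(truth, c(1, 2, 3, 4, 5))
  rp2 <- per_gene_correlation(pred2, truth2)
  expect_false(rp2$defined[3])
  counts <- count_significant(rp2)
  expect_equal(attr(counts, "excluded"), 1L)

  expect_error(per_gene_correlation(pred, truth[, 1:4]),
               class = "mf_shape_error")
  expect_error(per_gene_correlation(pred[, 1:2], truth[, 1:2]),
               class = "mf_argument_error")
})

test_that("BH and HS corrections equal definition-level brute force", {
  # single p is unchanged by both methods
  expect_equal(adjust_pvalues(0.037, "holm-sidak"), 0.037)
  expect_equal(adjust_pvalues(0.037, "benjamini-hochberg"), 0.037)

  # printed step-up example
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "benjamini-hochberg"),
               c(0.03, 0.03, 0.03))

  # exhaustive over a p-grid for all short vectors, plus random longer
  # ones; a single aggregated max-error assertion per method
  grid <- c(0.01, 0.25, 0.6, 1)
  cases <- list()
  for (len in 1:5) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    cases <- c(cases, lapply(seq_len(nrow(combos)), function(i)
      as.numeric(combos[i, ])))
  }
  cases <- c(cases, withr::with_seed(4, lapply(1:50, function(rep)
    runif(sample(6:8, 1)))))
  err_bh <- max(vapply(cases, function(p)
    max(abs(adjust_pvalues(p, "benjamini-hochberg") - brute_bh(p))),
    numeric(1)))
  err_hs <- max(vapply(cases, function(p)
    max(abs(adjust_pvalues(p, "holm-sidak") - brute_hs(p))), numeric(1)))
  expect_lt(err_bh, 1e-12)
  expect_lt(err_hs, 1e-12)

  # corrections dominate the raw p-values elementwise
  p <- withr::with_seed(5, runif(40))
  expect_true(all(adjust_pvalues(p, "holm-sidak") >= p))
  expect_true(all(adjust_pvalues(p, "benjamini-hochberg") >= p))

  expect_error(adjust_pvalues(c(0.1, 1.2)), class = "mf_argument_error")
})

test_that("significance counting across method x correction cells", {
  fake <- data.frame(pearson_r = rep(0.9, 6), pearson_p = rep(1, 6),
                     spearman_rho = rep(0.9, 6), spearman_p = rep(1, 6),
                     defined = TRUE)
  class(fake) <- c("gene_correlation", "data.frame")
  expect_equal(unname(count_significant(fake)), rep(0, 4),
               ignore_attr = TRUE)

  fake$pearson_p <- fake$spearman_p <- rep(0, 6)
  expect_equal(unname(count_significant(fake)), rep(6, 4),
               ignore_attr = TRUE)

  # random p-values vs a brute-force threshold count
  withr::with_seed(6, {
    fake$pearson_p <- runif(6, 0, 0.05)
    fake$spearman_p <- runif(6, 0, 0.05)
  })
  counts <- count_significant(fake, alpha = 0.01)
  expect_equal(unname(counts["pearson_hs"]),
               sum(brute_hs(fake$pearson_p) < 0.01))
  expect_equal(unname(counts["spearman_bh"]),
               sum(brute_bh(fake$spearman_p) < 0.01))
})

test_that("classification metrics: analytic cases and a hand-computed
          confusion table", {
  truth <- c(1, 1, 2, 2, 3, 3)
  perfect <- classification_metrics(truth, diag(3)[truth, ], truth, 3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$weighted_f1, 1)
  expect_equal(perfect$micro_auc, 1)

  const <- classification_metrics(rep(1, 6), NULL, truth, 3)
  expect_equal(const$accuracy, 1 / 3)

  # 6-slide toy: pred (1,2,2,2,3,1) vs truth above
  pred <- c(1, 2, 2, 2, 3, 1)
  cm <- classification_metrics(pred, NULL, truth, 3)
  expect_equal(cm$accuracy, 4 / 6)
  # class 1: P=1/2, R=1/2, F1=1/2 ; class 2: P=2/3, R=1, F1=4/5
  # class 3: P=1, R=1/2, F1=2/3
  expect_equal(cm$per_class$f1, c(1 / 2, 4 / 5, 2 / 3))
  expect_equal(cm$macro_f1, mean(c(1 / 2, 4 / 5, 2 / 3)))
  expect_equal(cm$weighted_f1, mean(c(1 / 2, 4 / 5, 2 / 3)))  # balanced truth

  expect_warning(classification_metrics(c(1, 2), NULL, c(1, 1), 2),
                 "absent")
})

test_that("micro ROC-AUC of shuffled scores is near one half", {
  withr::with_seed(11, {
    truth <- sample(1:3, 300, replace = TRUE)
    scores <- matrix(runif(900), 300, 3)
    pred <- apply(scores, 1, which.max)
  })
  auc <- classification_metrics(pred, scores, truth, 3)$micro_auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("PCA projection behaves like an eigen-decomposition", {
  # points on a line: second component carries no variance
  t_line <- seq(-2, 2, length.out = 20)
  line <- cbind(t_line * 3, t_line * 4) +
    matrix(c(1, 2), 20, 2, byrow = TRUE)
  pr <- pca_project(line, 2)
  expect_lt(pr$sdev[2], 1e-12)
  expect_true(all(diff(pr$sdev) <= 1e-12))

  X <- withr::with_seed(12, matrix(rnorm(20 * 5), 20, 5))
  pr2 <- pca_project(X, 5)
  eig <- eigen(cov(X))
  expect_equal(pr2$sdev^2, eig$values, tolerance = 1e-9)
  # full reconstruction from all components is exact
  recon <- pr2$coords %*% t(pr2$rotation) +
    matrix(colMeans(X), 20, 5, byrow = TRUE)
  expect_equal(recon, X, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Pearson distance matrix matches the covariance oracle", {
  E <- withr::with_seed(13, matrix(rnorm(40), 5, 8))
  E[2, ] <- E[1, ]          # identical
  E[3, ] <- -E[1, ]         # anti-correlated
  d <- pearson_distance_matrix(E)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 2)
  expect_equal(diag(d), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    x <- E[i, ]; y <- E[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(d[i, j], 1 - r)
  }
  expect_error(pearson_distance_matrix(rbind(E, 1)),
               class = "mf_argument_error")
})

test_that("retrieval metrics: prefix precision and exhaustive MAP oracle", {
  # all gallery items share the query's label
  n <- 6
  d_all <- matrix(1, n, n); diag(d_all) <- 0
  r_all <- retrieval_eval(d_all, rep(1, n), 1:n, K = 3)
  expect_true(all(r_all$per_query$p_at_k == 1))
  expect_true(all(r_all$per_query$ap_at_k == 1))

  # constructed relevance pattern [1,0,1,0,0] for query 1
  labels <- c(9, 9, 0, 9, 0, 0)
  dmat <- matrix(10, 6, 6); diag(dmat) <- 0
  dmat[1, 2:6] <- dmat[2:6, 1] <- c(1, 2, 3, 4, 5)
  rr <- retrieval_eval(dmat, labels, 1:6, K = 5)
  q1 <- rr$per_query[rr$per_query$query == 1 & rr$per_query$K == 5, ]
  expect_equal(q1$p_at_k, 0.4)
  expect_equal(q1$ap_at_k, mean(c(1, 1 / 2, 2 / 3, 1 / 2, 2 / 5)))

  # exhaustive double-loop oracle on a random 6-slide toy
  E <- withr::with_seed(14, matrix(rnorm(6 * 7), 6, 7))
  lab <- c(1, 1, 2, 2, 3, 3)
  pats <- c("a", "a", "b", "c", "d", "e")
  dm <- pearson_distance_matrix(E)
  got <- retrieval_eval(dm, lab, pats, K = 3)$map[["map_at_3"]]
  expect_equal(got, brute_map_at_k(dm, lab, pats, 3))

  # MAP invariant under gallery permutation (relabelled consistently)
  perm <- c(4, 1, 6, 2, 5, 3)
  got_p <- retrieval_eval(dm[perm, perm], lab[perm], pats[perm],
                          K = 3)$map[["map_at_3"]]
  expect_equal(got_p, got)

  w <- capture_warnings(retrieval_eval(dm, lab, pats, K = 6))
  expect_gt(length(w), 0)
  expect_match(w, "smaller than K", all = TRUE)
})

test_that("search subsets draw one bag per slide and average over
          subsets", {
  reps <- list(s1 = matrix(1, 1, 4), s2 = matrix(2, 1, 4),
               s3 = matrix(3, 1, 4))
  subs <- build_search_subsets(reps, n_subsets = 4, seed = 1)
  expect_length(subs, 4)
  for (s in subs) {
    expect_equal(nrow(s), 3)
    expect_equal(rownames(s), c("s1", "s2", "s3"))
  }
  # single-bag slides make all subsets identical
  for (s in subs[-1]) expect_identical(s, subs[[1]])

  reps2 <- lapply(1:5, function(i)
    withr::with_seed(i, matrix(rnorm(3 * 6), 3, 6)))
  names(reps2) <- sprintf("sl%d", 1:5)
  subs2 <- build_search_subsets(reps2, n_subsets = 3, seed = 2)
  # every subset row comes from the slide's own bag matrix
  for (s in subs2) for (sl in names(reps2)) {
    hit <- any(apply(reps2[[sl]], 1, function(row)
      isTRUE(all.equal(row, s[sl, ], check.attributes = FALSE))))
    expect_true(hit)
  }
  ev <- retrieval_eval_subsets(subs2, labels = c(1, 1, 2, 2, 1),
                               patients = 1:5, K = c(2, 3))
  expect_named(ev$map, c("map_at_2", "map_at_3"))
  expect_true(all(ev$map >= 0 & ev$map <= 1))
})
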