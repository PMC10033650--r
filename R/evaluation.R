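# Evaluation protocols: per-gene correlation with multiple-testing
# correction, MAE/RMSE/RRMSE error metrics, slide classification metrics
# with micro ROC-AUC, PCA projection of slide representations, and the
# leave-one-patient-out retrieval protocol (P@K / AP@K / MAP@K).

#' Prediction error metrics for one gene
#'
#' MAE and RMSE over the test samples, and RRMSE: the RMSE normalized by
#' the RMSE of the mean-predictor (predicting the truth's test-set mean
#' everywhere gives RRMSE exactly 1). With constant truth the RRMSE
#' denominator is zero and `NA` is returned.
#'
#' @param pred,truth equal-length numeric vectors (>= 2 values for RRMSE).
#' @return list with `mae`, `rmse`, `rrmse`.
#' @export
error_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 1)
  diffs <- pred - truth
  mae <- mean(abs(diffs))
  rmse <- sqrt(mean(diffs^2))
  denom <- sum((mean(truth) - truth)^2)
  rrmse <- if (denom <= 0 || length(truth) < 2) NA_real_
           else sqrt(sum(diffs^2) / denom)
  list(mae = mae, rmse = rmse, rrmse = rrmse)
}

#' Per-gene error table with mean +/- sd summary
#'
#' @param pred,truth genes x samples matrices (rows are genes).
#' @return data.frame of per-gene `mae`, `rmse`, `rrmse`, with a `summary`
#'   attribute holding mean and sd per metric (NA-removed for RRMSE).
#' @export
gene_error_table <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  per <- t(vapply(seq_len(nrow(pred)), function(g)
    unlist(error_metrics(pred[g, ], truth[g, ])), numeric(3)))
  df <- as.data.frame(per)
  names(df) <- c("mae", "rmse", "rrmse")
  attr(df, "summary") <- data.frame(
    metric = names(df),
    mean = vapply(df, mean, numeric(1), na.rm = TRUE),
    sd = vapply(df, stats::sd, numeric(1), na.rm = TRUE))
  df
}

#' Per-gene Pearson and Spearman correlation with p-values
#'
#' For each gene (row), correlates predicted and true values across
#' samples with two-sided tests. Genes with zero variance in either
#' vector are flagged undefined (`defined = FALSE`, `NA` statistics) and
#' excluded from downstream counting.
#'
#' @param pred,truth genes x samples matrices with >= 3 samples.
#' @return data.frame of class `gene_correlation`: per-gene `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `defined`.
#' @export
per_gene_correlation <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_mf("pred %s and truth %s differ in shape",
            paste(dim(pred), collapse = "x"),
            paste(dim(truth), collapse = "x"), class = "mf_shape_error")
  if (ncol(pred) < 3L)
    stop_mf("need >= 3 samples for per-gene correlation, got %d",
            ncol(pred), class = "mf_argument_error")
  n <- nrow(pred)
  out <- data.frame(pearson_r = rep(NA_real_, n), pearson_p = NA_real_,
                    spearman_rho = NA_real_, spearman_p = NA_real_,
                    defined = FALSE)
  for (g in seq_len(n)) {
    x <- pred[g, ]; y <- truth[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    pt <- stats::cor.test(x, y, method = "pearson")
    st <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    out$pearson_r[g] <- unname(pt$estimate)
    out$pearson_p[g] <- pt$p.value
    out$spearman_rho[g] <- unname(st$estimate)
    out$spearman_p[g] <- st$p.value
    out$defined[g] <- TRUE
  }
  class(out) <- c("gene_correlation", "data.frame")
  out
}

#' Adjust p-values for multiple testing
#'
#' `"benjamini-hochberg"` is the FDR step-up procedure (via
#' [stats::p.adjust()]): sorted ascending, `p * m / rank` with a running
#' minimum from the largest p down, clipped at 1. `"holm-sidak"` is the
#' family-wise step-down procedure: sorted ascending,
#' `1 - (1 - p_i)^(m - i + 1)` with a running maximum. Both dominate the
#' raw p-values elementwise.
#'
#' @param p numeric vector of p-values in `[0, 1]` (no NAs).
#' @param method `"holm-sidak"` or `"benjamini-hochberg"`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("holm-sidak",
                                         "benjamini-hochberg")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_mf("p-values must lie in [0, 1] with no NAs",
            class = "mf_argument_error")
  if (method == "benjamini-hochberg")
    return(stats::p.adjust(p, method = "BH"))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Attach adjusted p-values to a correlation report
#'
#' Adjustment runs over defined genes only; undefined genes keep `NA`.
#'
#' @param report a [per_gene_correlation()] result.
#' @return the report with `pearson_p_hs`, `pearson_p_bh`,
#'   `spearman_p_hs`, `spearman_p_bh` columns.
#' @export
adjust_correlation_report <- function(report) {
  ok <- report$defined
  for (src in c("pearson_p", "spearman_p")) {
    for (meth in c(hs = "holm-sidak", bh = "benjamini-hochberg")) {
      col <- paste0(src, "_", if (meth == "holm-sidak") "hs" else "bh")
      vals <- rep(NA_real_, nrow(report))
      vals[ok] <- adjust_pvalues(report[[src]][ok], meth)
      report[[col]] <- vals
    }
  }
  report
}

#' Count genes significant after correction
#'
#' @param report an adjusted report (see [adjust_correlation_report()];
#'   adjustment is applied here if the columns are missing).
#' @param alpha significance level (0.01 in the study protocol).
#' @return named numeric: `pearson_hs`, `pearson_bh`, `spearman_hs`,
#'   `spearman_bh`, with attribute `excluded` (undefined-gene count).
#' @export
count_significant <- function(report, alpha = 0.01) {
  if (is.null(report$pearson_p_hs))
    report <- adjust_correlation_report(report)
  counts <- c(
    pearson_hs = sum(report$pearson_p_hs < alpha, na.rm = TRUE),
    pearson_bh = sum(report$pearson_p_bh < alpha, na.rm = TRUE),
    spearman_hs = sum(report$spearman_p_hs < alpha, na.rm = TRUE),
    spearman_bh = sum(report$spearman_p_bh < alpha, na.rm = TRUE))
  attr(counts, "excluded") <- sum(!report$defined)
  counts
}

#' Slide classification metrics
#'
#' Accuracy, per-class F1 with macro and truth-frequency-weighted
#' averages, the confusion matrix, and micro-averaged ROC-AUC computed by
#' flattening the one-vs-rest (slide x class) indicators against the
#' slide score matrix. Classes absent from the truth are excluded from
#' the macro average with a warning.
#'
#' @param pred integer predicted labels (1..n_classes).
#' @param scores slides x classes matrix of class probabilities (mean
#'   softmax over bags in the pipeline); `NULL` skips the AUC.
#' @param truth integer true labels.
#' @param n_classes number of classes.
#' @return list with `accuracy`, `macro_f1`, `weighted_f1`, `per_class`,
#'   `confusion`, `micro_auc`.
#' @export
classification_metrics <- function(pred, scores, truth,
                                   n_classes = max(c(pred, truth))) {
  lev <- seq_len(n_classes)
  confusion <- table(pred = factor(pred, lev), truth = factor(truth, lev))
  accuracy <- mean(pred == truth)
  f1 <- prec <- rec <- numeric(n_classes)
  for (cl in lev) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec[cl] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[cl] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[cl] <- if (prec[cl] + rec[cl] > 0)
      2 * prec[cl] * rec[cl] / (prec[cl] + rec[cl]) else 0
  }
  present <- lev %in% truth
  if (!all(present))
    warning(sprintf("classes %s absent from truth; excluded from macro F1",
                    paste(lev[!present], collapse = ",")))
  weights <- tabulate(truth, nbins = n_classes) / length(truth)
  micro_auc <- NA_real_
  if (!is.null(scores)) {
    ind <- outer(truth, lev, `==`) * 1
    micro_auc <- as.numeric(pROC::auc(
      response = factor(as.vector(ind), levels = c(0, 1)),
      predictor = as.vector(scores), quiet = TRUE, direction = "<"))
  }
  list(accuracy = accuracy,
       macro_f1 = mean(f1[present]),
       weighted_f1 = sum(weights * f1),
       per_class = data.frame(class = lev, precision = prec, recall = rec,
                              f1 = f1, present = present),
       confusion = confusion,
       micro_auc = micro_auc)
}

#' Project slide representations onto principal components
#'
#' @param representations slides x D matrix.
#' @param n_components number of components kept.
#' @return list with `coords` (slides x n), `sdev` (all component standard
#'   deviations, non-increasing), `rotation`.
#' @export
pca_project <- function(representations, n_components = 2L) {
  fit <- stats::prcomp(representations, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(fit$x))
  list(coords = fit$x[, seq_len(n_components), drop = FALSE],
       sdev = fit$sdev, rotation = fit$rotation)
}

#' Build retrieval subsets, one bag representation per slide
#'
#' Emulates the search protocol: from each slide's bag representations,
#' each subset draws one bag uniformly at random, yielding a slides x D
#' embedding matrix per subset.
#'
#' @param bag_reps_by_slide named list; element `slide` is an
#'   `n_bags x D` matrix of class-token vectors.
#' @param n_subsets number of subsets (100 in the study).
#' @param seed RNG seed.
#' @return list of matrices with slide ids as row names.
#' @export
build_search_subsets <- function(bag_reps_by_slide, n_subsets = 100L,
                                 seed = 1L) {
  slides <- names(bag_reps_by_slide)
  stopifnot(!is.null(slides))
  with_seed(seed, {
    lapply(seq_len(n_subsets), function(s) {
      E <- do.call(rbind, lapply(bag_reps_by_slide, function(m) {
        m[if (nrow(m) == 1L) 1L else sample.int(nrow(m), 1L), , drop = FALSE]
      }))
      rownames(E) <- slides
      E
    })
  })
}

#' Pairwise Pearson-correlation distance matrix
#'
#' `1 - r` between embedding row vectors; the diagonal is exactly 0.
#' Identical vectors are at distance 0, perfectly anti-correlated vectors
#' at 2.
#'
#' @param embeddings items x D matrix; rows must have nonzero variance.
#' @return symmetric items x items matrix.
#' @export
pearson_distance_matrix <- function(embeddings) {
  sds <- apply(embeddings, 1L, stats::sd)
  if (any(sds == 0))
    stop_mf("rows %s have zero variance; Pearson distance undefined",
            paste(which(sds == 0), collapse = ","),
            class = "mf_argument_error")
  d <- 1 - stats::cor(t(embeddings))
  diag(d) <- 0
  d
}

#' Leave-one-patient-out retrieval evaluation
#'
#' Every item is a query; its gallery excludes all items of the same
#' patient. The gallery is ranked by ascending distance (ties broken by
#' item order), `P@i` is the fraction of the top i sharing the query's
#' label, `AP@K = mean(P@1..P@K)`, and MAP@K averages AP@K over queries.
#'
#' @param dist symmetric distance matrix.
#' @param labels item labels.
#' @param patients item patient ids (drives the leave-one-patient-out
#'   gallery).
#' @param K vector of cutoffs (`c(5, 10)` in the study); cut down with a
#'   warning when a gallery is smaller than K.
#' @return list with per-query data.frame `per_query` (query, K, p_at_k,
#'   ap_at_k) and named vector `map` (`MAP@K`).
#' @export
retrieval_eval <- function(dist, labels, patients = seq_along(labels),
                           K = c(5L, 10L)) {
  n <- length(labels)
  stopifnot(nrow(dist) == n, ncol(dist) == n)
  rows <- list()
  for (q in seq_len(n)) {
    gallery <- which(patients != patients[q])
    if (length(gallery) == 0L) next
    ord <- gallery[order(dist[q, gallery], gallery)]
    rel <- labels[ord] == labels[q]
    p_at <- cumsum(rel) / seq_along(rel)
    for (kk in K) {
      k_use <- min(kk, length(ord))
      if (k_use < kk)
        warning(sprintf("gallery of query %d smaller than K=%d; using %d",
                        q, kk, k_use))
      rows[[length(rows) + 1L]] <-
        data.frame(query = q, K = kk, p_at_k = p_at[k_use],
                   ap_at_k = mean(p_at[seq_len(k_use)]))
    }
  }
  per_query <- do.call(rbind, rows)
  map <- vapply(K, function(kk)
    mean(per_query$ap_at_k[per_query$K == kk]), numeric(1))
  names(map) <- paste0("map_at_", K)
  list(per_query = per_query, map = map)
}

#' Retrieval evaluation averaged over subsets
#'
#' Runs [pearson_distance_matrix()] + [retrieval_eval()] on each subset
#' and averages MAP@K over subsets, the study's reported quantity.
#'
#' @param subsets list from [build_search_subsets()].
#' @param labels,patients per-slide metadata in subset row order.
#' @param K cutoffs.
#' @return list with `map` (averaged over subsets) and `per_subset`
#'   matrix.
#' @export
retrieval_eval_subsets <- function(subsets, labels, patients,
                                   K = c(5L, 10L)) {
  per <- t(vapply(subsets, function(E) {
    retrieval_eval(pearson_distance_matrix(E), labels, patients, K)$map
  }, numeric(length(K))))
  per <- matrix(per, length(subsets), length(K),
                dimnames = list(NULL, paste0("map_at_", K)))
  list(map = colMeans(per), per_subset = per)
}
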