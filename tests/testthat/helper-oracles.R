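# Independent brute-force oracles and small shared fixtures. These stay
# definition-level (explicit loops) so they never share code paths with
# the implementations they check.

# tissue fraction of every full tile by per-pixel counting
brute_tile_filter <- function(mask, side, frac) {
  keep <- data.frame(grid_col = integer(0), grid_row = integer(0))
  for (gr in seq_len(nrow(mask) %/% side) - 1L) {
    for (gc in seq_len(ncol(mask) %/% side) - 1L) {
      count <- 0L
      for (r in seq_len(side)) for (cc in seq_len(side))
        count <- count + mask[gr * side + r, gc * side + cc]
      if (count / side^2 >= frac)
        keep[nrow(keep) + 1L, ] <- c(gc, gr)
    }
  }
  keep
}

# top-n mean by explicit sort per gene
brute_topn <- function(s, n) {
  out <- numeric(nrow(s))
  for (g in seq_len(nrow(s))) {
    vals <- rev(sort(s[g, ]))
    out[g] <- sum(vals[1:n]) / n
  }
  out
}

# Benjamini-Hochberg by its step-up definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * p[o[j]] / j)
    adj_sorted[i] <- min(cand, 1)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Holm-Sidak by its step-down definition
brute_hs <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- -Inf
    for (j in 1:i) cand <- max(cand, 1 - (1 - p[o[j]])^(m - j + 1))
    adj_sorted[i] <- min(cand, 1)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# MAP@K by an exhaustive double loop over queries and ranks
brute_map_at_k <- function(dist, labels, patients, K) {
  aps <- c()
  for (q in seq_along(labels)) {
    gallery <- setdiff(seq_along(labels), which(patients == patients[q]))
    ord <- gallery[order(dist[q, gallery], gallery)]
    ps <- numeric(K)
    for (i in 1:K) {
      hits <- 0L
      for (j in 1:i) hits <- hits + (labels[ord[j]] == labels[q])
      ps[i] <- hits / i
    }
    aps <- c(aps, mean(ps))
  }
  mean(aps)
}

# adjusted Rand index from the pair-counting definition
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# tiny model configuration reused across model tests
tiny_config <- function(...) {
  defaults <- list(L = 2L, D = 8L, heads = 2L, mlp_ratio = 2L, k = 4L,
                   d = 9L, d_g = 3L, n_classes = 3L, dropout_head = 0,
                   topn_choices = c(1L, 2L, 4L))
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# small separable cohort shared by training-level tests
tiny_cohort <- function(bags_per_slide = 10L, slides_per_class = 3L,
                        seed = 7L) {
  generate_cohort(cohort_spec(
    n_classes = 2L, slides_per_class = slides_per_class, k = 4L, d = 9L,
    d_g = 3L, bags_per_slide = bags_per_slide, class_separation = 3,
    noise_sd = 0.05, seed = seed))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

`%||%` <- function(a, b) if (is.null(a)) b else a
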