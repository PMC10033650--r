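# Hand-derived backpropagation for both model families. Gradients share
# the exact structure of `model$params`; correctness is pinned down by a
# finite-difference test over every leaf tensor.

zeros_like <- function(node) {
  if (is.list(node)) lapply(node, zeros_like)
  else if (is.matrix(node)) matrix(0, nrow(node), ncol(node))
  else numeric(length(node))
}

# elementwise binary op over two parameter trees
tree_map2 <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) tree_map2(x, y, f), a, b)
  else f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, tree_map, f = f)
  else f(a)
}

tree_sum <- function(a, f = identity) {
  total <- 0
  walk <- function(node) {
    if (is.list(node)) lapply(node, walk) else total <<- total + sum(f(node))
    invisible(NULL)
  }
  walk(a)
  total
}

#' Backpropagate through a model for one bag
#'
#' Given the cache from `model_forward(..., keep_cache = TRUE)` and the
#' gradients of the loss with respect to the class logits and the per-tile
#' gene predictions, returns the gradient tree matching `model$params`.
#'
#' @param model the model that produced `cache`.
#' @param cache forward cache.
#' @param dlogits gradient w.r.t. class logits (or `NULL`).
#' @param dtile_gene gradient w.r.t. the d_g x k tile predictions (or
#'   `NULL`).
#' @param ... passed to methods.
#' @return list of gradients with the structure of `model$params`.
#' @export
model_backward <- function(model, cache, dlogits = NULL, dtile_gene = NULL,
                           ...)
  UseMethod("model_backward")

#' @export
model_backward.transformer_model <- function(model, cache, dlogits = NULL,
                                             dtile_gene = NULL, ...) {
  p <- model$params; cf <- model$config
  k <- cf$k; D <- cf$D; nh <- cf$heads; Dh <- D %/% nh
  scal <- 1 / sqrt(Dh)
  g <- zeros_like(p)

  dz <- matrix(0, k + 1L, D)

  # classification head and final LN (class-token row only)
  if (!is.null(dlogits)) {
    g$Wc <- outer(cache$cvec, dlogits)
    g$bc <- dlogits
    dc <- matrix(as.vector(p$Wc %*% dlogits), 1L, D)
    lb <- ln_bwd(dc, cache$lnf, p$lnf_g)
    g$lnf_g <- lb$dg; g$lnf_b <- lb$db
    dz[1L, ] <- lb$dx
  }

  # gene head
  if (!is.null(dtile_gene)) {
    dG <- t(dtile_gene)                       # k x d_g
    g$Wg <- t(cache$Zt_drop) %*% dG
    g$bg <- colSums(dG)
    dZt <- dG %*% t(p$Wg)
    if (!is.null(cache$m_g)) dZt <- dZt * cache$m_g
    dz[-1L, ] <- dz[-1L, ] + dZt
  }

  for (l in rev(seq_len(cf$L))) {
    lay <- p$layers[[l]]; ca <- cache$layers[[l]]
    gl <- g$layers[[l]]

    # MLP branch: z_l = z2 + mlp
    dmlp <- dz
    if (!is.null(ca$m_enc2)) dmlp <- dmlp * ca$m_enc2
    gl$W2 <- t(ca$gdrop) %*% dmlp
    gl$b2 <- colSums(dmlp)
    dgdrop <- dmlp %*% t(lay$W2)
    if (!is.null(ca$m_enc)) dgdrop <- dgdrop * ca$m_enc
    da1 <- dgdrop * gelu_grad(ca$a1)
    gl$W1 <- t(ca$ln2$y) %*% da1
    gl$b1 <- colSums(da1)
    dh2 <- da1 %*% t(lay$W1)
    lb2 <- ln_bwd(dh2, ca$ln2, lay$ln2_g)
    gl$ln2_g <- lb2$dg; gl$ln2_b <- lb2$db
    dz2 <- dz + lb2$dx

    # attention branch: z2 = z_in + attn
    dattn <- dz2
    gl$Wo <- t(ca$O) %*% dattn
    gl$bo <- colSums(dattn)
    dO <- dattn %*% t(lay$Wo)
    dQ <- matrix(0, k + 1L, D); dK <- dQ; dV <- dQ
    for (h in seq_len(nh)) {
      idx <- (h - 1L) * Dh + seq_len(Dh)
      A <- ca$A_heads[[h]]
      dOh <- dO[, idx, drop = FALSE]
      Vh <- ca$V[, idx, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, idx] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% ca$K[, idx, drop = FALSE] * scal
      dK[, idx] <- t(dS) %*% ca$Q[, idx, drop = FALSE] * scal
    }
    gl$Wq <- t(ca$ln1$y) %*% dQ; gl$bq <- colSums(dQ)
    gl$Wk <- t(ca$ln1$y) %*% dK; gl$bk <- colSums(dK)
    gl$Wv <- t(ca$ln1$y) %*% dV; gl$bv <- colSums(dV)
    dh1 <- dQ %*% t(lay$Wq) + dK %*% t(lay$Wk) + dV %*% t(lay$Wv)
    lb1 <- ln_bwd(dh1, ca$ln1, lay$ln1_g)
    gl$ln1_g <- lb1$dg; gl$ln1_b <- lb1$db
    dz <- dz2 + lb1$dx

    g$layers[[l]] <- gl
  }

  g$E_pos <- dz
  g$x_class <- dz[1L, , drop = FALSE]
  dtokens <- dz[-1L, , drop = FALSE]
  g$E <- t(cache$X) %*% dtokens
  g$E_b <- colSums(dtokens)
  g
}

#' @export
model_backward.he2rna_model <- function(model, cache, dlogits = NULL,
                                        dtile_gene = NULL, ...) {
  p <- model$params
  g <- zeros_like(p)
  if (is.null(dtile_gene)) return(g)
  dG <- t(dtile_gene)
  g$W3 <- t(cache$d2) %*% dG
  g$b3 <- colSums(dG)
  dd2 <- dG %*% t(p$W3)
  if (!is.null(cache$m2)) dd2 <- dd2 * cache$m2
  da2 <- dd2 * (cache$a2 > 0)
  g$W2 <- t(cache$d1) %*% da2
  g$b2 <- colSums(da2)
  dd1 <- da2 %*% t(p$W2)
  if (!is.null(cache$m1)) dd1 <- dd1 * cache$m1
  da1 <- dd1 * (cache$a1 > 0)
  g$W1 <- t(cache$X) %*% da1
  g$b1 <- colSums(da1)
  g
}

# Gradients of the multitask loss at the model outputs, together with the
# routing of the aggregated-gene gradient back to the selected tiles.
loss_output_grads <- function(out, label, gene_target, config, n_top) {
  dlogits <- NULL
  if (!is.null(out$logits) && !is.na(label)) {
    pr <- softmax_vec(out$logits)
    onehot <- numeric(config$n_classes); onehot[label] <- 1
    dlogits <- pr - onehot
  }
  dtile <- NULL
  agg <- NULL
  if (!is.null(gene_target)) {
    agg <- aggregate_topn_idx(out$tile_gene, n_top)
    diffs <- agg$S - gene_target
    dS <- if (config$gene_loss == "mse") {
      config$gamma * 2 * diffs / config$d_g
    } else {
      config$gamma * sign(diffs) / config$d_g
    }
    dtile <- matrix(0, config$d_g, ncol(out$tile_gene))
    for (gidx in seq_len(config$d_g))
      dtile[gidx, agg$idx[gidx, ]] <- dS[gidx] / n_top
  }
  list(dlogits = dlogits, dtile_gene = dtile, S_train = agg$S %||% NULL)
}

# Numeric gradient of f(params) by central differences; used in tests to
# validate model_backward leaf by leaf (on a thinned index set).
numeric_gradient_leaf <- function(f, params, path, idx, eps = 1e-5) {
  get_leaf <- function(p) {
    for (nm in path) p <- p[[nm]]
    p
  }
  set_leaf <- function(p, rest, val) {
    if (length(rest) == 1L) { p[[rest[[1]]]] <- val; return(p) }
    p[[rest[[1]]]] <- set_leaf(p[[rest[[1]]]], rest[-1], val)
    p
  }
  leaf <- get_leaf(params)
  vapply(idx, function(i) {
    lp <- leaf; lp[i] <- lp[i] + eps
    up <- f(set_leaf(params, path, lp))
    lm <- leaf; lm[i] <- lm[i] - eps
    dn <- f(set_leaf(params, path, lm))
    (up - dn) / (2 * eps)
  }, numeric(1))
}
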