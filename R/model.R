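# The MIL transformer and the conv-MLP baseline, in plain matrix code.
#
# Model: a bag of k tile embeddings (k x d) is linearly projected to k
# D-dimensional tokens, a learnable class token is prepended, a learnable
# position embedding is added, and L pre-norm transformer encoder layers
# are applied:
#   z'_l = MSA(LN(z_{l-1})) + z_{l-1}
#   z_l  = MLP(LN(z'_l))   + z'_l
# The class-token row, layer-normed, is the slide representation c; a
# linear head maps c to class logits. The remaining k token rows pass
# through dropout and a kernel-1 1-D convolution (i.e. a shared linear map)
# to per-tile gene predictions s (d_g x k), aggregated over tiles by
# top-n averaging.

#' Model configuration
#'
#' Holds every architectural and loss hyperparameter. Defaults are the
#' study settings: token width 384, 4 heads, MLP ratio 4, bag size 49,
#' 1024-dim tile embeddings, gene-head dropout 0.25, loss scale gamma 0.5,
#' weight-decay coefficient 0.01, and top-n choice set {1,2,5,10,20,49}.
#'
#' @param L encoder depth.
#' @param D token width; must be divisible by `heads`.
#' @param heads number of self-attention heads.
#' @param mlp_ratio hidden width of the MLP block as a multiple of `D`.
#' @param k bag size; must be a perfect square (tile grid).
#' @param d tile-embedding dimension.
#' @param d_g number of genes predicted.
#' @param n_classes number of slide classes.
#' @param dropout_head dropout probability before the gene head.
#' @param dropout_encoder dropout inside MLP blocks (0 in the study recipe).
#' @param gamma scale of the gene-prediction loss term.
#' @param lambda weight-decay coefficient (applied in the optimizer, not
#'   added to the returned loss).
#' @param topn_choices integer set from which the training-time top-n is
#'   drawn each iteration; max must be <= k.
#' @param test_aggregation `"mean"` (average of S(1..k), default) or
#'   `"literal"` (the printed sum of S(i)/i).
#' @param gene_loss `"mse"` (default) or `"absolute"`.
#' @return object of class `model_config` (a validated list).
#' @export
model_config <- function(L = 8L, D = 384L, heads = 4L, mlp_ratio = 4L,
                         k = 49L, d = 1024L, d_g = 31793L, n_classes = 3L,
                         dropout_head = 0.25, dropout_encoder = 0,
                         gamma = 0.5, lambda = 0.01,
                         topn_choices = c(1L, 2L, 5L, 10L, 20L, 49L),
                         test_aggregation = c("mean", "literal"),
                         gene_loss = c("mse", "absolute")) {
  test_aggregation <- match.arg(test_aggregation)
  gene_loss <- match.arg(gene_loss)
  if (D %% heads != 0L)
    stop_mf("D=%d must be divisible by heads=%d", D, heads,
            class = "mf_config_error")
  if (abs(sqrt(k) - round(sqrt(k))) > 1e-9)
    stop_mf("k=%d must be a perfect square (tile grid)", k,
            class = "mf_config_error")
  topn_choices <- as.integer(topn_choices)
  if (max(topn_choices) > k || min(topn_choices) < 1L)
    stop_mf("topn_choices must lie in 1..k=%d", k, class = "mf_config_error")
  structure(list(L = as.integer(L), D = as.integer(D),
                 heads = as.integer(heads), mlp_ratio = as.integer(mlp_ratio),
                 k = as.integer(k), d = as.integer(d), d_g = as.integer(d_g),
                 n_classes = as.integer(n_classes),
                 dropout_head = dropout_head,
                 dropout_encoder = dropout_encoder,
                 gamma = gamma, lambda = lambda,
                 topn_choices = topn_choices,
                 test_aggregation = test_aggregation,
                 gene_loss = gene_loss),
            class = "model_config")
}

#' Round-trip a model configuration through JSON
#' @param config a `model_config`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
write_model_config <- function(config, path = NULL) {
  if (is.null(path))
    return(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_config
#' @param json JSON string or file path produced by [write_model_config()].
#' @export
read_model_config <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
         else jsonlite::fromJSON(json)
  do.call(model_config, obj)
}

trunc_normal <- function(n, sd = 0.02) {
  # truncated at +/- 2 sd, the usual token/position initialization
  x <- stats::rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

tn_mat <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

#' Initialize a transformer model
#'
#' Weights are truncated-normal (sd 0.02), biases zero, layer-norm gains
#' one. Deterministic given `seed`.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the initialization.
#' @return object of class `transformer_model`: list with `params`,
#'   `config`, `seed`.
#' @export
init_transformer <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  D <- config$D; d <- config$d; k <- config$k; H <- config$mlp_ratio * D
  params <- with_seed(seed, {
    layers <- lapply(seq_len(config$L), function(l) list(
      ln1_g = rep(1, D), ln1_b = rep(0, D),
      Wq = tn_mat(D, D), bq = rep(0, D),
      Wk = tn_mat(D, D), bk = rep(0, D),
      Wv = tn_mat(D, D), bv = rep(0, D),
      Wo = tn_mat(D, D), bo = rep(0, D),
      ln2_g = rep(1, D), ln2_b = rep(0, D),
      W1 = tn_mat(D, H), b1 = rep(0, H),
      W2 = tn_mat(H, D), b2 = rep(0, D)))
    list(x_class = tn_mat(1, D),
         E = tn_mat(d, D), E_b = rep(0, D),
         E_pos = tn_mat(k + 1L, D),
         layers = layers,
         lnf_g = rep(1, D), lnf_b = rep(0, D),
         Wc = tn_mat(D, config$n_classes), bc = rep(0, config$n_classes),
         Wg = tn_mat(D, config$d_g), bg = rep(0, config$d_g))
  })
  structure(list(params = params, config = config, seed = as.integer(seed)),
            class = c("transformer_model", "mf_model"))
}

#' Initialize the conv-MLP baseline
#'
#' Three kernel-1, stride-1 1-D convolutions over the tile axis — i.e. the
#' same dense map applied to every tile embedding — with ReLU and dropout
#' between layers: d -> h -> h -> d_g. This is the HE2RNA-style backbone
#' used as the gene-prediction comparator; it has no class token and no
#' classification head.
#'
#' @param config a [model_config()] (uses `d`, `d_g`, `dropout_head`,
#'   `gamma`, loss settings).
#' @param h internal representation width (1024 in the study).
#' @param seed RNG seed.
#' @return object of class `he2rna_model`.
#' @export
init_he2rna <- function(config, h = 1024L, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d; d_g <- config$d_g
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h), b1 = rep(0, h),
    W2 = matrix(stats::rnorm(h * h, sd = sqrt(2 / h)), h, h), b2 = rep(0, h),
    W3 = matrix(stats::rnorm(h * d_g, sd = sqrt(2 / h)), h, d_g),
    b3 = rep(0, d_g)))
  structure(list(params = params, config = config, h = as.integer(h),
                 seed = as.integer(seed)),
            class = c("he2rna_model", "mf_model"))
}

# --- layer primitives ------------------------------------------------------

LN_EPS <- 1e-5

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  n <- nrow(dy)
  dxhat <- dy * rep(g, each = n)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

add_bias <- function(x, b) x + rep(b, each = nrow(x))

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# --- forward ---------------------------------------------------------------

#' Run a model forward on one bag
#'
#' @param model a `transformer_model` or `he2rna_model`.
#' @param X bag matrix, k x d tile embeddings (cluster-sorted rows).
#' @param train logical; enables dropout (sampled from the current RNG
#'   stream). In eval mode the forward pass is deterministic.
#' @param keep_cache keep intermediate activations for [model_backward()].
#' @param ... passed to methods.
#' @return list with `c` (D-vector slide representation, transformer only),
#'   `logits` (class scores, transformer only), `tile_gene` (d_g x k
#'   per-tile gene predictions) and, if requested, `cache`.
#' @export
model_forward <- function(model, X, train = FALSE, keep_cache = FALSE, ...)
  UseMethod("model_forward")

#' @export
model_forward.transformer_model <- function(model, X, train = FALSE,
                                            keep_cache = FALSE, ...) {
  p <- model$params; cf <- model$config
  k <- cf$k; D <- cf$D; nh <- cf$heads; Dh <- D %/% nh
  if (!is.matrix(X) || nrow(X) != k || ncol(X) != cf$d)
    stop_mf("bag matrix must be %d x %d, got %d x %d", k, cf$d,
            NROW(X), NCOL(X), class = "mf_shape_error")
  scal <- 1 / sqrt(Dh)

  tokens <- add_bias(X %*% p$E, p$E_b)
  z <- rbind(p$x_class, tokens) + p$E_pos
  caches <- if (keep_cache) vector("list", cf$L)

  for (l in seq_len(cf$L)) {
    lay <- p$layers[[l]]
    ln1 <- ln_fwd(z, lay$ln1_g, lay$ln1_b)
    Q <- add_bias(ln1$y %*% lay$Wq, lay$bq)
    K <- add_bias(ln1$y %*% lay$Wk, lay$bk)
    V <- add_bias(ln1$y %*% lay$Wv, lay$bv)
    O <- matrix(0, k + 1L, D)
    A_heads <- if (keep_cache) vector("list", nh)
    for (h in seq_len(nh)) {
      idx <- (h - 1L) * Dh + seq_len(Dh)
      A <- softmax_rows(Q[, idx, drop = FALSE] %*%
                          t(K[, idx, drop = FALSE]) * scal)
      O[, idx] <- A %*% V[, idx, drop = FALSE]
      if (keep_cache) A_heads[[h]] <- A
    }
    attn <- add_bias(O %*% lay$Wo, lay$bo)
    z2 <- z + attn
    ln2 <- ln_fwd(z2, lay$ln2_g, lay$ln2_b)
    a1 <- add_bias(ln2$y %*% lay$W1, lay$b1)
    gact <- gelu(a1)
    m_enc <- if (train) dropout_mask(nrow(gact), ncol(gact),
                                     cf$dropout_encoder)
    gdrop <- if (is.null(m_enc)) gact else gact * m_enc
    mlp <- add_bias(gdrop %*% lay$W2, lay$b2)
    m_enc2 <- if (train) dropout_mask(nrow(mlp), ncol(mlp),
                                      cf$dropout_encoder)
    if (!is.null(m_enc2)) mlp <- mlp * m_enc2
    z_new <- z2 + mlp
    if (keep_cache)
      caches[[l]] <- list(z_in = z, ln1 = ln1, Q = Q, K = K, V = V,
                          A_heads = A_heads, O = O, z2 = z2, ln2 = ln2,
                          a1 = a1, gdrop = gdrop, m_enc = m_enc,
                          m_enc2 = m_enc2)
    z <- z_new
  }

  lnf <- ln_fwd(z[1L, , drop = FALSE], p$lnf_g, p$lnf_b)
  cvec <- as.vector(lnf$y)
  logits <- as.vector(cvec %*% p$Wc) + p$bc
  Zt <- z[-1L, , drop = FALSE]
  m_g <- if (train) dropout_mask(k, D, cf$dropout_head)
  Zt_drop <- if (is.null(m_g)) Zt else Zt * m_g
  G <- add_bias(Zt_drop %*% p$Wg, p$bg)   # k x d_g
  if (anyNA(G) || anyNA(logits))
    stop_mf("NaN in model output (after final heads)",
            class = "mf_numeric_error")

  out <- list(c = cvec, logits = logits, tile_gene = t(G))
  if (keep_cache)
    out$cache <- list(X = X, layers = caches, z_final = z, lnf = lnf,
                      cvec = cvec, Zt_drop = Zt_drop, m_g = m_g)
  out
}

#' @export
model_forward.he2rna_model <- function(model, X, train = FALSE,
                                       keep_cache = FALSE, ...) {
  p <- model$params; cf <- model$config
  if (!is.matrix(X) || ncol(X) != cf$d)
    stop_mf("bag matrix must have d=%d columns, got %d", cf$d, NCOL(X),
            class = "mf_shape_error")
  a1 <- add_bias(X %*% p$W1, p$b1); r1 <- pmax(a1, 0)
  m1 <- if (train) dropout_mask(nrow(r1), ncol(r1), cf$dropout_head)
  d1 <- if (is.null(m1)) r1 else r1 * m1
  a2 <- add_bias(d1 %*% p$W2, p$b2); r2 <- pmax(a2, 0)
  m2 <- if (train) dropout_mask(nrow(r2), ncol(r2), cf$dropout_head)
  d2 <- if (is.null(m2)) r2 else r2 * m2
  G <- add_bias(d2 %*% p$W3, p$b3)
  out <- list(c = NULL, logits = NULL, tile_gene = t(G))
  if (keep_cache)
    out$cache <- list(X = X, a1 = a1, d1 = d1, m1 = m1, a2 = a2, d2 = d2,
                      m2 = m2)
  out
}

#' Patch projection applied to the image form
#'
#' Applies the model's tile projection as the stride-b 2-D convolution of
#' the pipeline diagram: each b x b block of the image form is flattened
#' (row-major, matching [rearrange_to_image()]) and mapped by `E` plus
#' bias. Equal, up to float round-off, to `X %*% E + bias` on the original
#' bag matrix — the consistency the cross-module tests enforce.
#'
#' @param image_form square matrix from [rearrange_to_image()].
#' @param model a `transformer_model`.
#' @return k x D token matrix.
#' @export
patch_project <- function(image_form, model) {
  cf <- model$config
  gb <- grid_block_sides(cf$k, cf$d)
  if (nrow(image_form) != gb["g"] * gb["b"])
    stop_mf("image side %d does not match k=%d, d=%d layout",
            nrow(image_form), cf$k, cf$d, class = "mf_shape_error")
  M <- inverse_rearrange(image_form, grid = gb["g"])
  add_bias(M %*% model$params$E, model$params$E_b)
}

# --- aggregation ------------------------------------------------------------

#' Average the top-n per-tile predictions, per gene
#'
#' For each gene independently, the k tile predictions are sorted in
#' descending order and the first n are averaged. S(1) is the per-gene
#' max, S(k) the per-gene mean, and S(n) is non-increasing in n.
#'
#' @param s d_g x k matrix of per-tile gene predictions.
#' @param n how many top predictions to average, 1 <= n <= k.
#' @return length-d_g vector S(n).
#' @export
aggregate_topn <- function(s, n) {
  k <- ncol(s)
  if (length(n) != 1L || is.na(n) || n < 1L || n > k)
    stop_mf("n must be a single integer in 1..%d, got %s", k, format(n),
            class = "mf_argument_error")
  n <- as.integer(n)
  apply(s, 1L, function(row) mean(sort(row, decreasing = TRUE)[seq_len(n)]))
}

# top-n with the tile indices used, for backpropagation
aggregate_topn_idx <- function(s, n) {
  idx <- matrix(t(apply(s, 1L, function(row)
    order(row, decreasing = TRUE)[seq_len(n)])), nrow(s), n)
  vals <- vapply(seq_len(nrow(s)), function(g) mean(s[g, idx[g, ]]),
                 numeric(1))
  list(S = vals, idx = idx)
}

#' Test-time aggregation over all top-n values
#'
#' Mode `"mean"` (default) returns the average of S(1), ..., S(k); mode
#' `"literal"` returns the plain sum of S(i)/i over i = 1..k (for a
#' constant field v this equals v times the k-th harmonic number).
#'
#' @param s d_g x k matrix of per-tile gene predictions.
#' @param mode `"mean"` or `"literal"`.
#' @return length-d_g vector S.
#' @export
aggregate_test <- function(s, mode = c("mean", "literal")) {
  mode <- match.arg(mode)
  k <- ncol(s)
  # prefix means of the descending sort give all S(n) in one pass
  sorted <- t(apply(s, 1L, sort, decreasing = TRUE))
  sorted <- matrix(sorted, nrow(s), k)
  prefix <- t(apply(sorted, 1L, cumsum)) / rep(seq_len(k), each = nrow(s))
  prefix <- matrix(prefix, nrow(s), k)
  if (mode == "mean") rowMeans(prefix)
  else as.vector(prefix %*% (1 / seq_len(k)))
}

# --- loss -------------------------------------------------------------------

softmax_vec <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' Multitask loss: cross-entropy plus scaled gene-prediction error
#'
#' `total = CE(softmax(logits), label) + gamma * genes_err`, where the gene
#' term is the mean squared error (default) or mean absolute error between
#' the aggregated slide prediction and the log-space target. The
#' weight-regularization term of the objective is realized as decoupled
#' weight decay inside the optimizer and is not part of the returned
#' scalar, so reported losses match training logs.
#'
#' @param logits raw class scores.
#' @param label integer class in 1..n_classes (may be `NA` to drop the
#'   classification term, as for the baseline model).
#' @param slide_gene_pred aggregated gene prediction (length d_g).
#' @param gene_target true log-space gene vector (length d_g).
#' @param config a [model_config()].
#' @return list with `total`, `ce`, `gene_scaled` (gamma * error), `gene`.
#' @export
total_loss <- function(logits, label, slide_gene_pred, gene_target, config) {
  ce <- 0
  if (!is.null(logits) && !is.na(label)) {
    if (label < 1L || label > config$n_classes)
      stop_mf("label %d outside 1..%d", label, config$n_classes,
              class = "mf_argument_error")
    pr <- softmax_vec(logits)
    ce <- -log(max(pr[label], 1e-300))
  }
  gene <- 0
  if (!is.null(gene_target)) {
    if (length(gene_target) != config$d_g)
      stop_mf("gene_target length %d != d_g=%d", length(gene_target),
              config$d_g, class = "mf_argument_error")
    diffs <- slide_gene_pred - gene_target
    gene <- if (config$gene_loss == "mse") mean(diffs^2) else mean(abs(diffs))
  }
  list(total = ce + config$gamma * gene, ce = ce,
       gene_scaled = config$gamma * gene, gene = gene)
}

# --- parameter counting -----------------------------------------------------

#' Count learnable parameters
#'
#' On a `model_config`, returns the closed-form count of the transformer's
#' learnable tensors (class token, projection + bias, position embedding,
#' per-layer layer-norms / QKVO / MLP, final layer-norm, both heads). On a
#' fitted model object, counts the instantiated arrays; the two agree
#' exactly.
#'
#' @param x a `model_config`, `transformer_model` or `he2rna_model`.
#' @param ... unused.
#' @return integer parameter count.
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.model_config <- function(x, ...) {
  D <- x$D; H <- x$mlp_ratio * D
  per_layer <- 2 * D + 4 * (D * D + D) + 2 * D + (D * H + H) + (H * D + D)
  as.integer(
    D +                     # class token
      (x$d * D + D) +       # E + bias
      (x$k + 1) * D +       # position embedding
      x$L * per_layer +
      2 * D +               # final LN
      (D * x$n_classes + x$n_classes) +
      (D * x$d_g + x$d_g))
}

#' @export
count_parameters.mf_model <- function(x, ...) {
  total <- 0L
  walk <- function(node) {
    if (is.list(node)) lapply(node, walk)
    else total <<- total + length(node)
    invisible(NULL)
  }
  walk(x$params)
  total
}

#' @export
count_parameters.he2rna_model <- function(x, ...) {
  NextMethod()
}
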