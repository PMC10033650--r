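# Multitask training: AdamW with decoupled weight decay, reduce-on-plateau
# learning-rate schedule, model selection at the lowest validation loss,
# and slide-level inference by majority vote over bags.

#' Training configuration
#'
#' Defaults follow the study recipe: 20 epochs, minibatch 64, AdamW with
#' starting learning rate 3e-4 and weight decay 0.01, learning rate
#' divided by ten after two epochs without validation-loss improvement,
#' and the checkpoint with the lowest validation loss returned.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size (bags).
#' @param lr starting learning rate.
#' @param weight_decay decoupled weight-decay coefficient (the lambda
#'   regularization term of the objective).
#' @param plateau_factor multiplicative learning-rate factor on plateau.
#' @param plateau_patience epochs without improvement before reducing.
#' @param min_lr learning-rate floor.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed RNG seed governing batch shuffling, the per-iteration top-n
#'   draw and dropout; identical seeds give identical runs.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 64L, lr = 3e-4,
                         weight_decay = 0.01, plateau_factor = 0.1,
                         plateau_patience = 2L, min_lr = 1e-7,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0, plateau_patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Reduce-on-plateau schedule as a pure function
#'
#' Replays the scheduler over a sequence of validation losses: the first
#' epoch sets the incumbent best; each later epoch without strict
#' improvement increments a counter, and once the counter reaches
#' `patience` the learning rate is multiplied by `factor` (not below
#' `min_lr`) and the counter resets.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param lr0 starting learning rate.
#' @param factor,patience,min_lr schedule parameters.
#' @return numeric vector: the learning rate in force *after* each epoch.
#' @export
plateau_schedule <- function(val_losses, lr0 = 3e-4, factor = 0.1,
                             patience = 2L, min_lr = 1e-7) {
  lr <- lr0; best <- Inf; bad <- 0L
  out <- numeric(length(val_losses))
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best) {
      best <- val_losses[i]; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        lr <- max(lr * factor, min_lr)
        bad <- 0L
      }
    }
    out[i] <- lr
  }
  out
}

adamw_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr, wd, b1, b2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  state$m <- tree_map2(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
  upd <- tree_map2(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, function(p, u) p - lr * u)
  if (wd > 0)
    params <- tree_map(params, function(p) p - lr * wd * p)
  list(params = params, state = state)
}

bag_matrix_of <- function(bag) if (is.matrix(bag)) bag else bag$X
bag_label_of <- function(bag) if (is.matrix(bag)) NA_integer_ else
  (bag$label %||% NA_integer_)
bag_target_of <- function(bag) if (is.matrix(bag)) NULL else bag$gene_target

# deterministic eval-mode loss over a bag set (test aggregation for genes)
eval_loss <- function(model, bags) {
  cf <- model$config
  tot <- 0
  for (bag in bags) {
    out <- model_forward(model, bag_matrix_of(bag), train = FALSE)
    S <- aggregate_test(out$tile_gene, cf$test_aggregation)
    l <- total_loss(out$logits, bag_label_of(bag), S, bag_target_of(bag), cf)
    tot <- tot + l$total
  }
  tot / length(bags)
}

#' Train a model on bags of tile embeddings
#'
#' Minibatch training of the multitask objective. Each iteration draws a
#' top-n value uniformly from the config's choice set, aggregates the
#' per-tile gene predictions with it, and backpropagates cross-entropy
#' plus the scaled gene error; AdamW applies decoupled weight decay. The
#' validation loss (eval mode, deterministic test aggregation) drives the
#' reduce-on-plateau schedule and selects the returned checkpoint. Fully
#' reproducible under `config$seed`.
#'
#' @param model a `transformer_model` or `he2rna_model`.
#' @param train_bags,val_bags lists of bags: each a list with `X` (k x d
#'   matrix), `label` (integer or `NA`), `gene_target` (numeric or
#'   `NULL`).
#' @param config a [train_config()].
#' @return list with `model` (lowest-validation-loss checkpoint), `final`
#'   (last-epoch model), and `history` (per-epoch data.frame: train CE,
#'   scaled gene loss, validation loss, learning rate).
#' @export
train_model <- function(model, train_bags, val_bags, config) {
  stopifnot(inherits(config, "train_config"))
  cf <- model$config
  history <- data.frame(epoch = integer(0), train_ce = numeric(0),
                        train_gene_scaled = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  if (config$epochs == 0L)
    return(list(model = model, final = model, history = history))

  n_train <- length(train_bags)
  lr <- config$lr; best_val <- Inf; bad <- 0L
  best_model <- model
  state <- adamw_init(model$params)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n_train)
      starts <- seq(1L, n_train, by = config$batch_size)
      ep_ce <- 0; ep_gene <- 0; n_seen <- 0L
      for (s0 in starts) {
        batch <- idx[s0:min(s0 + config$batch_size - 1L, n_train)]
        n_top <- cf$topn_choices[sample.int(length(cf$topn_choices), 1L)]
        gacc <- NULL
        for (bi in batch) {
          bag <- train_bags[[bi]]
          out <- model_forward(model, bag_matrix_of(bag), train = TRUE,
                               keep_cache = TRUE)
          lg <- loss_output_grads(out, bag_label_of(bag),
                                  bag_target_of(bag), cf, n_top)
          l <- total_loss(out$logits, bag_label_of(bag),
                          lg$S_train %||% numeric(cf$d_g),
                          bag_target_of(bag), cf)
          if (!is.finite(l$total))
            stop_mf("non-finite loss at epoch %d (bag %d)", epoch, bi,
                    class = "mf_numeric_error")
          ep_ce <- ep_ce + l$ce; ep_gene <- ep_gene + l$gene_scaled
          n_seen <- n_seen + 1L
          gb <- model_backward(model, out$cache, lg$dlogits, lg$dtile_gene)
          gacc <- if (is.null(gacc)) gb else
            tree_map2(gacc, gb, `+`)
        }
        gacc <- tree_map(gacc, function(x) x / length(batch))
        st <- adamw_step(model$params, gacc, state, lr, config$weight_decay,
                         config$beta1, config$beta2, config$adam_eps)
        model$params <- st$params
        state <- st$state
      }
      val <- eval_loss(model, val_bags)
      # reduce-on-plateau bookkeeping
      if (val < best_val) {
        best_val <- val; bad <- 0L
        best_model <- model
      } else {
        bad <- bad + 1L
        if (bad >= config$plateau_patience) {
          lr <- max(lr * config$plateau_factor, config$min_lr)
          bad <- 0L
        }
      }
      history[nrow(history) + 1L, ] <-
        list(epoch, ep_ce / n_seen, ep_gene / n_seen, val, lr)
    }
  })
  list(model = best_model, final = model, history = history)
}

#' Per-bag inference
#'
#' Eval-mode forward over a list of bags: per-bag class probabilities and
#' argmax, the test-time aggregated gene prediction, and the class-token
#' representation.
#'
#' @param model a trained model.
#' @param bags list of bags (or bare k x d matrices).
#' @return list with `probs` (bags x classes, or `NULL`), `pred` (argmax
#'   labels), `genes` (bags x d_g), `reps` (bags x D, or `NULL`).
#' @export
predict_bags <- function(model, bags) {
  cf <- model$config
  n <- length(bags)
  has_cls <- inherits(model, "transformer_model")
  probs <- if (has_cls) matrix(0, n, cf$n_classes)
  reps <- if (has_cls) matrix(0, n, cf$D)
  genes <- matrix(0, n, cf$d_g)
  pred <- integer(n)
  for (i in seq_len(n)) {
    out <- model_forward(model, bag_matrix_of(bags[[i]]), train = FALSE)
    genes[i, ] <- aggregate_test(out$tile_gene, cf$test_aggregation)
    if (has_cls) {
      probs[i, ] <- softmax_vec(out$logits)
      reps[i, ] <- out$c
      pred[i] <- which.max(out$logits)
    }
  }
  list(probs = probs, pred = if (has_cls) pred else NULL, genes = genes,
       reps = reps)
}

#' Majority vote over per-bag predictions
#'
#' Ties are resolved to the lowest class index, with a warning.
#'
#' @param preds integer per-bag argmax labels.
#' @param n_classes number of classes.
#' @return list with `label`, `votes`, `tie`.
#' @export
majority_vote <- function(preds, n_classes) {
  votes <- tabulate(preds, nbins = n_classes)
  winners <- which(votes == max(votes))
  tie <- length(winners) > 1L
  if (tie)
    warning(sprintf("slide-level vote tie between classes %s; taking %d",
                    paste(winners, collapse = ","), winners[1L]))
  list(label = winners[1L], votes = votes, tie = tie)
}

#' Slide-level prediction from that slide's bags
#'
#' The slide label is the most common per-bag argmax (ties resolved to the
#' lowest class index, with a warning); the slide gene prediction is the
#' mean over bags of the test-time aggregated predictions; the slide
#' representation is the mean class-token vector; the slide score vector
#' is the mean per-bag softmax.
#'
#' @param model a trained model.
#' @param bags all bags of one slide (>= 1).
#' @return list with `label`, `votes`, `tie` (logical), `gene_pred`,
#'   `representation`, `scores`.
#' @export
predict_slide <- function(model, bags) {
  if (length(bags) == 0L)
    stop_mf("predict_slide() needs at least one bag",
            class = "mf_argument_error")
  pb <- predict_bags(model, bags)
  label <- NA_integer_; votes <- NULL; tie <- FALSE; scores <- NULL
  if (!is.null(pb$pred)) {
    mv <- majority_vote(pb$pred, model$config$n_classes)
    votes <- mv$votes; tie <- mv$tie; label <- mv$label
    scores <- colMeans(pb$probs)
  }
  list(label = label, votes = votes, tie = tie,
       gene_pred = colMeans(pb$genes),
       representation = if (is.null(pb$reps)) NULL else colMeans(pb$reps),
       scores = scores)
}
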