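# Stage-wise pipeline over a working directory. Every stage reads the
# previous stage's JSON manifest and writes its own; each manifest records
# the producing seed and a hash of the stage configuration. Matrices are
# stored as TSV, reports as JSON.

# Polynomial rolling hash over the config's JSON form; a small stable
# fingerprint recorded in every manifest (not cryptographic).
config_hash <- function(obj) {
  s <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (byte in utf8ToInt(s)) h <- (h * 31 + byte) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(workdir, stage, config, extra = list()) {
  obj <- c(list(stage = stage, config = config,
                config_hash = config_hash(config),
                seed = config$seed %||% NA), extra)
  jsonlite::write_json(obj, file.path(workdir, paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(obj)
}

require_manifest <- function(workdir, stage) {
  path <- file.path(workdir, paste0(stage, ".json"))
  if (!file.exists(path))
    stop_mf("missing %s manifest in '%s'; run the `%s` command first",
            stage, workdir, stage, class = "mf_missing_upstream_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: simulate a synthetic cohort
#'
#' Generates a [generate_cohort()] cohort and writes slide metadata, bag
#' embeddings and gene targets under `workdir`.
#'
#' @param workdir working directory (created if needed).
#' @param spec a [cohort_spec()]; its `seed` governs the draw.
#' @return invisibly, the manifest.
#' @export
pipeline_simulate <- function(workdir, spec = cohort_spec()) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec)
  write_tsv(cohort$slides, file.path(workdir, "slides.tsv"))
  gt <- data.frame(gene = sprintf("G%03d", seq_len(spec$d_g)),
                   cohort$gene_targets, check.names = FALSE)
  colnames(gt) <- c("gene", cohort$slides$slide_id)
  write_tsv(gt, file.path(workdir, "gene_targets.tsv"))
  store <- file.path(workdir, "embeddings")
  for (sid in cohort$slides$slide_id) {
    mats <- lapply(Filter(function(b) b$slide_id == sid, cohort$bags),
                   function(b) b$X)
    write_embedding_store(store, sid, mats, backbone_id = "synthetic",
                          seed = spec$seed)
  }
  write_manifest(workdir, "simulate", unclass(spec)[
    setdiff(names(unclass(spec)), "W")],
    extra = list(n_slides = nrow(cohort$slides),
                 n_bags = length(cohort$bags)))
}

load_cohort_bags <- function(workdir) {
  slides <- utils::read.delim(file.path(workdir, "slides.tsv"))
  gt <- utils::read.delim(file.path(workdir, "gene_targets.tsv"),
                          check.names = FALSE)
  targets <- as.matrix(gt[, -1, drop = FALSE])
  bags <- list()
  for (i in seq_len(nrow(slides))) {
    sid <- slides$slide_id[i]
    arr <- read_embedding_store(file.path(workdir, "embeddings"), sid)
    for (b in seq_len(dim(arr)[1]))
      bags[[length(bags) + 1L]] <-
        list(X = arr[b, , ], label = slides$class[i], slide_id = sid,
             patient_id = slides$patient_id[i], bag_index = b,
             gene_target = targets[, sid])
  }
  list(bags = bags, slides = slides, targets = targets)
}

#' Pipeline stage: preprocess thumbnail images into bag manifests
#'
#' Masks each image, selects tissue tiles, clusters them spatially and
#' samples bags; writes one bag manifest per slide.
#'
#' @param workdir working directory.
#' @param images named list of RGB arrays, or a directory of PNG files.
#' @param k,n_bags,min_tissue_frac,tile_side_thumb preprocessing
#'   parameters.
#' @param seed RNG seed.
#' @return invisibly, the manifest.
#' @export
pipeline_preprocess <- function(workdir, images, k = 49L, n_bags = 100L,
                                min_tissue_frac = 0.5,
                                tile_side_thumb = 14L, seed = 1L) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(images)) {
    files <- list.files(images, pattern = "\\.png$", full.names = TRUE)
    imgs <- lapply(files, read_rgb_image)
    names(imgs) <- sub("\\.png$", "", basename(files))
    images <- imgs
  }
  dir.create(file.path(workdir, "bags"), showWarnings = FALSE)
  kept <- character(0)
  for (sid in names(images)) {
    mask <- compute_tissue_mask(images[[sid]])
    coords <- select_tile_positions(mask, tile_side_thumb = tile_side_thumb,
                                    min_tissue_frac = min_tissue_frac,
                                    slide_id = sid)
    if (nrow(coords) < k) next
    asg <- cluster_tiles(coords, k = k, seed = seed)
    bags <- sample_bags(asg, n_bags = n_bags, seed = seed + 1L,
                        slide_id = sid)
    write_tsv(bag_manifest(bags),
              file.path(workdir, "bags", paste0(sid, ".tsv")))
    kept <- c(kept, sid)
  }
  if (length(kept) == 0L)
    stop_mf("no slide had >= %d tissue tiles", k,
            class = "mf_no_tissue_error")
  write_manifest(workdir, "preprocess",
                 list(k = k, n_bags = n_bags,
                      min_tissue_frac = min_tissue_frac,
                      tile_side_thumb = tile_side_thumb, seed = seed),
                 extra = list(slides = kept))
}

#' Pipeline stage: embed preprocessed bags
#'
#' Reads the bag manifests of `preprocess`, serves tiles through the
#' slide readers and writes an embedding store.
#'
#' @param workdir working directory.
#' @param readers named list of slide readers, one per slide id.
#' @param backbone a backbone function.
#' @param seed recorded in the store manifest.
#' @return invisibly, the manifest.
#' @export
pipeline_embed <- function(workdir, readers,
                           backbone = backbone_random_projection(64L),
                           seed = 1L) {
  pre <- require_manifest(workdir, "preprocess")
  store <- file.path(workdir, "embeddings")
  side_thumb <- pre$config$tile_side_thumb
  for (sid in pre$slides) {
    man <- utils::read.delim(file.path(workdir, "bags", paste0(sid, ".tsv")))
    mats <- lapply(split(man, man$bag_index), function(mb) {
      bag <- structure(list(slide_id = sid, tiles = data.frame(
        cluster = mb$cluster_index, grid_col = mb$grid_col,
        grid_row = mb$grid_row)), class = "wsi_bag")
      embed_tiles(bag, readers[[sid]], backbone,
                  tile_side_hi = side_thumb * 16L,
                  tile_side_thumb = side_thumb)
    })
    write_embedding_store(store, sid, mats,
                          backbone_id = attr(backbone, "id"), seed = seed)
  }
  write_manifest(workdir, "embed",
                 list(backbone = attr(backbone, "id"),
                      d = attr(backbone, "d"), seed = seed))
}

#' Pipeline stage: train on a simulated cohort
#'
#' Splits slides patient-wise, trains a transformer on the training bags
#' and writes the checkpoint, history and split.
#'
#' @param workdir working directory holding `simulate` outputs.
#' @param model_cfg a [model_config()] matching the cohort's k/d/d_g.
#' @param train_cfg a [train_config()].
#' @param ratios patient-wise train/val/test fractions.
#' @return invisibly, the manifest.
#' @export
pipeline_train <- function(workdir, model_cfg, train_cfg,
                           ratios = c(0.8, 0.1, 0.1)) {
  sim <- require_manifest(workdir, "simulate")
  data <- load_cohort_bags(workdir)
  split <- split_cases(data$slides$slide_id, data$slides$patient_id,
                       ratios = ratios, seed = train_cfg$seed)
  sets <- lapply(split[c("train", "val", "test")], function(ids)
    Filter(function(b) b$slide_id %in% ids, data$bags))
  model <- init_transformer(model_cfg, seed = train_cfg$seed)
  fit <- train_model(model, sets$train, sets$val, train_cfg)
  saveRDS(list(model = fit$model, split = split), file.path(workdir,
                                                            "checkpoint.rds"))
  write_tsv(fit$history, file.path(workdir, "history.tsv"))
  write_manifest(workdir, "train",
                 c(unclass(model_cfg),
                   list(epochs = train_cfg$epochs, lr = train_cfg$lr,
                        seed = train_cfg$seed, ratios = ratios)),
                 extra = list(best_val = min(fit$history$val_loss)))
}

#' Pipeline stage: slide-level prediction on the test split
#' @param workdir working directory holding `train` outputs.
#' @return invisibly, the manifest.
#' @export
pipeline_predict <- function(workdir) {
  require_manifest(workdir, "train")
  ck <- readRDS(file.path(workdir, "checkpoint.rds"))
  data <- load_cohort_bags(workdir)
  test_ids <- ck$split$test
  rows <- list(); gene_pred <- list(); reps <- list(); scores <- list()
  for (sid in test_ids) {
    bags <- Filter(function(b) b$slide_id == sid, data$bags)
    ps <- predict_slide(ck$model, bags)
    rows[[sid]] <- data.frame(slide_id = sid,
                              truth = bags[[1]]$label,
                              pred = ps$label, tie = ps$tie)
    gene_pred[[sid]] <- ps$gene_pred
    reps[[sid]] <- ps$representation
    scores[[sid]] <- ps$scores
  }
  preds <- do.call(rbind, rows)
  write_tsv(preds, file.path(workdir, "predictions.tsv"))
  gp <- data.frame(gene = sprintf("G%03d",
                                  seq_along(gene_pred[[1]])),
                   do.call(cbind, gene_pred), check.names = FALSE)
  colnames(gp) <- c("gene", test_ids)
  write_tsv(gp, file.path(workdir, "gene_predictions.tsv"))
  write_tsv(data.frame(slide_id = test_ids, do.call(rbind, scores)),
            file.path(workdir, "scores.tsv"))
  write_tsv(data.frame(slide_id = test_ids, do.call(rbind, reps)),
            file.path(workdir, "representations.tsv"))
  write_manifest(workdir, "predict", list(seed = NA),
                 extra = list(n_test = length(test_ids)))
}

#' Pipeline stage: evaluate predictions
#'
#' Classification metrics, per-gene correlation counts and error
#' summaries over the test split, written as `metrics.json`.
#'
#' @param workdir working directory holding `predict` outputs.
#' @param alpha significance level for corrected p-values.
#' @return invisibly, the metrics list.
#' @export
pipeline_evaluate <- function(workdir, alpha = 0.01) {
  require_manifest(workdir, "train")
  require_manifest(workdir, "predict")
  preds <- utils::read.delim(file.path(workdir, "predictions.tsv"))
  gp <- utils::read.delim(file.path(workdir, "gene_predictions.tsv"),
                          check.names = FALSE)
  data <- load_cohort_bags(workdir)
  pred_mat <- as.matrix(gp[, -1, drop = FALSE])
  truth_mat <- data$targets[, colnames(pred_mat), drop = FALSE]
  scores <- as.matrix(utils::read.delim(
    file.path(workdir, "scores.tsv"))[, -1, drop = FALSE])
  n_classes <- max(data$slides$class)
  cls <- classification_metrics(preds$pred, scores, preds$truth, n_classes)
  errs <- gene_error_table(pred_mat, truth_mat)
  esum <- attr(errs, "summary")
  metrics <- list(
    accuracy = cls$accuracy, macro_f1 = cls$macro_f1,
    weighted_f1 = cls$weighted_f1, micro_auc = cls$micro_auc,
    error_mean = as.list(stats::setNames(esum$mean, esum$metric)),
    n_test_slides = nrow(preds))
  if (ncol(pred_mat) >= 3) {
    rep_corr <- per_gene_correlation(pred_mat, truth_mat)
    counts <- count_significant(rep_corr, alpha = alpha)
    metrics$significant_genes <- as.list(counts)
    metrics$mean_pearson_r <- mean(rep_corr$pearson_r, na.rm = TRUE)
  }
  jsonlite::write_json(metrics, file.path(workdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(workdir, "evaluate", list(alpha = alpha, seed = NA))
  invisible(metrics)
}

#' Pipeline stage: retrieval over test-slide representations
#'
#' Builds bag-level class-token representations for every test slide,
#' draws search subsets and reports MAP@K.
#'
#' @param workdir working directory holding `train` outputs.
#' @param n_subsets number of search subsets.
#' @param K retrieval cutoffs.
#' @param seed RNG seed for subset draws.
#' @return invisibly, the retrieval report.
#' @export
pipeline_search <- function(workdir, n_subsets = 100L, K = c(5L, 10L),
                            seed = 1L) {
  require_manifest(workdir, "train")
  ck <- readRDS(file.path(workdir, "checkpoint.rds"))
  data <- load_cohort_bags(workdir)
  test_ids <- ck$split$test
  reps <- list()
  for (sid in test_ids) {
    bags <- Filter(function(b) b$slide_id == sid, data$bags)
    reps[[sid]] <- predict_bags(ck$model, bags)$reps
  }
  slides <- data$slides[match(test_ids, data$slides$slide_id), ]
  subsets <- build_search_subsets(reps, n_subsets = n_subsets, seed = seed)
  rep_eval <- retrieval_eval_subsets(subsets, slides$class,
                                     slides$patient_id, K = K)
  jsonlite::write_json(c(as.list(rep_eval$map),
                         list(n_subsets = n_subsets)),
                       file.path(workdir, "retrieval.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(workdir, "search",
                 list(n_subsets = n_subsets, K = K, seed = seed))
  invisible(rep_eval)
}
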