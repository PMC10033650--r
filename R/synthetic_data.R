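# Desk-scale generators reproducing the statistical structure the method
# assumes: thumbnails with tissue-like blobs (plus optional marker ink)
# for the masking stage, embedding cohorts with class-dependent means and
# a known linear gene map for model training, and FPKM-UQ-style tables
# with a controlled median-zero fraction for the preprocessing stage.

#' Generate a synthetic thumbnail with ground-truth masks
#'
#' Pink-hued elliptical tissue blobs on a white background, optionally
#' crossed by a saturated blue marker stripe. The returned ground-truth
#' tissue mask excludes the stripe (ink covers tissue), so mask-recovery
#' scores can be computed directly.
#'
#' @param width,height image size in pixels.
#' @param n_blobs number of tissue blobs (0 gives an empty mask).
#' @param marker add a vertical blue marker stripe.
#' @param seed RNG seed.
#' @param blob_radius_range ellipse semi-axis range, as a fraction of the
#'   smaller image side.
#' @return list with `image` (`[row, col, 3]` array), `tissue_mask`,
#'   `marker_mask` (0/1 matrices), and `blobs` (centers and semi-axes).
#' @export
generate_thumbnail <- function(width = 224L, height = 224L, n_blobs = 3L,
                               marker = FALSE, seed = 1L,
                               blob_radius_range = c(0.10, 0.18)) {
  with_seed(seed, {
    img <- array(1, c(height, width, 3L))
    tissue <- matrix(FALSE, height, width)
    xx <- matrix(rep(seq_len(width), each = height), height, width)
    yy <- matrix(rep(seq_len(height), width), height, width)
    blobs <- data.frame(cx = numeric(0), cy = numeric(0), rx = numeric(0),
                        ry = numeric(0))
    side <- min(width, height)
    for (b in seq_len(n_blobs)) {
      rx <- stats::runif(1, blob_radius_range[1], blob_radius_range[2]) * side
      ry <- stats::runif(1, blob_radius_range[1], blob_radius_range[2]) * side
      cx <- stats::runif(1, rx + 1, width - rx)
      cy <- stats::runif(1, ry + 1, height - ry)
      tissue <- tissue | (((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1)
      blobs[b, ] <- c(cx, cy, rx, ry)
    }
    if (any(tissue)) {
      n_t <- sum(tissue)
      img[, , 1][tissue] <- pmin(pmax(0.86 + stats::rnorm(n_t, 0, 0.02), 0), 1)
      img[, , 2][tissue] <- pmin(pmax(0.48 + stats::rnorm(n_t, 0, 0.02), 0), 1)
      img[, , 3][tissue] <- pmin(pmax(0.66 + stats::rnorm(n_t, 0, 0.02), 0), 1)
    }
    marker_mask <- matrix(FALSE, height, width)
    if (marker) {
      w <- max(3L, round(0.06 * width))
      x0 <- sample.int(width - w, 1L)
      marker_mask[, x0 + seq_len(w)] <- TRUE
      img[, , 1][marker_mask] <- 0.10
      img[, , 2][marker_mask] <- 0.15
      img[, , 3][marker_mask] <- 0.95
      tissue <- tissue & !marker_mask
    }
    list(image = img, tissue_mask = matrix(as.integer(tissue), height, width),
         marker_mask = matrix(as.integer(marker_mask), height, width),
         blobs = blobs)
  })
}

#' Specification of a synthetic embedding cohort
#'
#' Defaults define the package's desk-scale study conditions: 3 classes
#' (mirroring the three RCC subtypes), 10 slides per class with one
#' patient per slide, 100 bags per slide (the study's bag count), bags of
#' k = 9 tiles with d = 16 embedding dimensions, d_g = 8 genes, class
#' centroids separated by 3 within-class standard deviations, and
#' log-space gene noise with sd 0.1.
#'
#' @param n_classes number of slide classes.
#' @param slides_per_class slides per class.
#' @param patients total patients; fewer than the slide count creates
#'   multi-slide patients (within one class).
#' @param k,d,d_g bag size, embedding dimension, gene count.
#' @param bags_per_slide bags sampled per slide.
#' @param class_separation centroid distance in within-class sd units.
#' @param cluster_sd sd of per-slide cluster-center offsets.
#' @param noise_sd log-space gene-target noise sd.
#' @param W optional d_g x d gene map; default is a seeded Gaussian map.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_classes = 3L, slides_per_class = 10L,
                        patients = n_classes * slides_per_class,
                        k = 9L, d = 16L, d_g = 8L, bags_per_slide = 100L,
                        class_separation = 3, cluster_sd = 0.5,
                        noise_sd = 0.1, W = NULL, seed = 1L) {
  stopifnot(n_classes >= 1, slides_per_class >= 1, k >= 1, d >= 1,
            d_g >= 1, bags_per_slide >= 1, noise_sd >= 0,
            patients >= n_classes,
            patients <= n_classes * slides_per_class)
  structure(list(n_classes = as.integer(n_classes),
                 slides_per_class = as.integer(slides_per_class),
                 patients = as.integer(patients), k = as.integer(k),
                 d = as.integer(d), d_g = as.integer(d_g),
                 bags_per_slide = as.integer(bags_per_slide),
                 class_separation = class_separation,
                 cluster_sd = cluster_sd, noise_sd = noise_sd, W = W,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic embedding cohort
#'
#' Class centroids are orthogonal directions scaled so that centroid
#' pairs sit `class_separation` within-class standard deviations apart.
#' Each slide adds k cluster offsets (`N(0, cluster_sd^2 I)`); each bag
#' draws tile i from `N(centroid + offset_i, I)`. The slide's gene target
#' is `W %*% slide_mean + N(0, noise_sd^2)` in log space, where
#' `slide_mean` is the slide's expected tile embedding — a bulk,
#' slide-level readout of bag content, mirroring how bulk RNA-seq
#' supervises the MIL model.
#'
#' @param spec a [cohort_spec()].
#' @return list with `bags` (each: `X`, `label`, `slide_id`, `patient_id`,
#'   `bag_index`, `gene_target`), `slides` (data.frame), `gene_targets`
#'   (d_g x n_slides), `slide_means`, `W`, `centroids`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    d <- spec$d; k <- spec$k; d_g <- spec$d_g
    W <- spec$W
    if (is.null(W)) W <- matrix(stats::rnorm(d_g * d, sd = 1 / sqrt(d)),
                                d_g, d)
    # orthonormal class directions scaled so centroid distance = separation
    raw <- matrix(stats::rnorm(d * spec$n_classes), d, spec$n_classes)
    ortho <- qr.Q(qr(raw))
    centroids <- t(ortho) * spec$class_separation / sqrt(2)

    n_slides <- spec$n_classes * spec$slides_per_class
    slide_class <- rep(seq_len(spec$n_classes), each = spec$slides_per_class)
    # patients: first `patients` slides start patients; extras reuse a
    # patient of the same class
    patient_of_slide <- character(n_slides)
    per_class_patients <- split(seq_len(spec$patients),
                                rep(seq_len(spec$n_classes),
                                    length.out = spec$patients))
    counters <- rep(1L, spec$n_classes)
    for (s in seq_len(n_slides)) {
      cl <- slide_class[s]
      pool <- per_class_patients[[cl]]
      patient_of_slide[s] <- sprintf("P%03d",
                                     pool[(counters[cl] - 1L) %% length(pool) + 1L])
      counters[cl] <- counters[cl] + 1L
    }

    bags <- list()
    slide_means <- matrix(0, n_slides, d)
    slide_ids <- sprintf("S%03d", seq_len(n_slides))
    gene_targets <- matrix(0, d_g, n_slides,
                           dimnames = list(sprintf("G%03d", seq_len(d_g)),
                                           slide_ids))
    for (s in seq_len(n_slides)) {
      mu <- centroids[slide_class[s], ]
      offsets <- matrix(stats::rnorm(k * d, sd = spec$cluster_sd), k, d)
      m_slide <- mu + colMeans(offsets)
      slide_means[s, ] <- m_slide
      gene_targets[, s] <- as.vector(W %*% m_slide) +
        stats::rnorm(d_g, sd = spec$noise_sd)
      for (b in seq_len(spec$bags_per_slide)) {
        X <- offsets + matrix(mu, k, d, byrow = TRUE) +
          matrix(stats::rnorm(k * d), k, d)
        bags[[length(bags) + 1L]] <-
          list(X = X, label = slide_class[s], slide_id = slide_ids[s],
               patient_id = patient_of_slide[s], bag_index = b,
               gene_target = gene_targets[, s])
      }
    }
    list(bags = bags,
         slides = data.frame(slide_id = slide_ids,
                             patient_id = patient_of_slide,
                             class = slide_class),
         gene_targets = gene_targets, slide_means = slide_means, W = W,
         centroids = centroids, spec = spec)
  })
}

#' Generate a raw FPKM-UQ-style expression table
#'
#' A chosen fraction of genes is constructed to have an across-case
#' median of zero (more than half of their values are zeros); the rest
#' are strictly positive log-normal values on the FPKM-UQ scale. The
#' ground-truth keep set is recorded in the `keep` attribute.
#'
#' @param n_genes,n_cases table size.
#' @param zero_fraction fraction of genes with median zero.
#' @param seed RNG seed.
#' @return an `expression_table` with attribute `keep` (logical vector).
#' @export
generate_expression_table <- function(n_genes = 100L, n_cases = 12L,
                                      zero_fraction = 0.3, seed = 1L) {
  with_seed(seed, {
    n_zero <- round(zero_fraction * n_genes)
    keep <- rep(TRUE, n_genes)
    if (n_zero > 0)
      keep[sample.int(n_genes, n_zero)] <- FALSE
    vals <- matrix(stats::rlnorm(n_genes * n_cases, meanlog = 9, sdlog = 2),
                   n_genes, n_cases)
    need_zeros <- n_cases %/% 2 + 1L       # force median 0
    for (g in which(!keep)) {
      zi <- sample.int(n_cases, sample(need_zeros:n_cases, 1L))
      vals[g, zi] <- 0
    }
    # sprinkle sub-median zeros into kept genes (median stays positive)
    max_safe <- (n_cases - 1L) %/% 2
    if (max_safe > 0 && any(keep)) {
      kept_idx <- which(keep)
      for (g in kept_idx[sample.int(length(kept_idx),
                                    max(1L, length(kept_idx) %/% 4))]) {
        zi <- sample.int(n_cases, sample.int(max_safe, 1L))
        vals[g, zi] <- 0
      }
    }
    tab <- expression_table(vals,
                            sprintf("ENSG%011d.%d", seq_len(n_genes),
                                    sample(1:15, n_genes, replace = TRUE)),
                            sprintf("CASE-%04d", seq_len(n_cases)))
    attr(tab, "keep") <- keep
    tab
  })
}
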