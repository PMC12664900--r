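#' Synthetic multimodal single-cell data with known ground truth
#'
#' The generator emulates the structure the model assumes: a shared latent
#' cell state on a unit hypersphere observed through modality-specific
#' noisy linear maps, discrete cell types with tunable angular separation,
#' optional batch shifts applied in embedding space (the model consumes
#' batch-corrected embeddings, so shifts are off by default and raised only
#' to exercise the batch discriminator), and raw counts drawn from a
#' negative binomial observation model for RNA (softmax-mapped means times
#' a log-normal library size, per-gene dispersion) and a Bernoulli model
#' for binarized ATAC (sigmoid-mapped probabilities). Everything is seeded
#' and reproducible.
#'
#' @name synthetic
NULL

#' Configuration for the synthetic generator
#'
#' @param n_cells Number of cells.
#' @param n_types Number of discrete cell types (>= 2).
#' @param n_batches Number of batches.
#' @param latent_dim Dimension of the shared latent sphere.
#' @param embed_dims Per-modality embedding dimensions (length 2 or 3; a
#'   third, lower-dimensional entry models an epitope-like modality).
#' @param count_dims Feature counts for the RNA and ATAC count matrices
#'   (length 2), or NULL to skip count generation.
#' @param noise_sd Per-modality Gaussian noise added to the embeddings
#'   (recycled to the number of modalities).
#' @param batch_effect_sd Scale of the per-batch shifts in embedding space.
#' @param type_separation Minimum angle (radians) enforced between type
#'   centroids on the latent sphere.
#' @param within_type_sd Tangential spread of cells around their type
#'   centroid before re-projection onto the sphere.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 3000, n_types = 8, n_batches = 1,
                       latent_dim = 10, embed_dims = c(20, 25),
                       count_dims = c(300, 500), noise_sd = 0.1,
                       batch_effect_sd = 0, type_separation = 1.0,
                       within_type_sd = 0.3, seed = 0) {
  if (n_types < 2) stop_config("n_types must be >= 2")
  if (latent_dim < 2 || any(embed_dims < 2)) stop_config("all dimensions must be >= 2")
  if (!length(embed_dims) %in% c(2L, 3L)) stop_config("embed_dims must have length 2 or 3")
  if (any(noise_sd < 0) || batch_effect_sd < 0 || within_type_sd < 0) {
    stop_config("noise parameters must be >= 0")
  }
  if (!is.null(count_dims) && length(count_dims) != 2) {
    stop_config("count_dims must be NULL or length 2 (RNA genes, ATAC peaks)")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_types = as.integer(n_types),
         n_batches = as.integer(n_batches), latent_dim = as.integer(latent_dim),
         embed_dims = as.integer(embed_dims), count_dims = count_dims,
         noise_sd = rep_len(noise_sd, length(embed_dims)),
         batch_effect_sd = batch_effect_sd, type_separation = type_separation,
         within_type_sd = within_type_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Type centroids on the latent sphere with a minimum-angle rejection rule.
.draw_centroids <- function(n_types, q, min_angle) {
  cents <- matrix(NA_real_, n_types, q)
  for (k in seq_len(n_types)) {
    ok <- FALSE
    for (try in seq_len(5000)) {
      cand <- stats::rnorm(q)
      cand <- cand / sqrt(sum(cand^2))
      if (k == 1 || all(acos(pmin(pmax(cents[seq_len(k - 1), , drop = FALSE] %*% cand, -1), 1)) >= min_angle)) {
        cents[k, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_config("cannot place %d centroids at separation %.2f rad on S^%d", n_types, min_angle, q - 1)
  }
  cents
}

# Modality map latent (q) -> embedding (r): orthonormal rows when r >= q
# (geometry-preserving), otherwise a random Gaussian projection. Scaled by
# sqrt(q) so embedding coordinates have ~unit variance (unit-norm latent
# rows have per-coordinate variance 1/q), matching the O(1) per-dimension
# scale of the PCA/LSI/VAE representations the model consumes.
.modality_map <- function(q, r) {
  if (r >= q) {
    sqrt(q) * t(qr.Q(qr(matrix(stats::rnorm(r * q), r, q))))
  } else {
    matrix(stats::rnorm(q * r, sd = 1), q, r)
  }
}

.simulate_dataset <- function(config) {
  M <- length(config$embed_dims)
  modal_names <- c("rna", "atac", "epitope")[seq_len(M)]
  withr::with_seed(config$seed, {
    n <- config$n_cells; q <- config$latent_dim
    cents <- .draw_centroids(config$n_types, q, config$type_separation)
    type <- sample(rep_len(seq_len(config$n_types), n))
    batch <- sample(rep_len(seq_len(config$n_batches), n))
    latent <- cents[type, , drop = FALSE] +
      matrix(stats::rnorm(n * q, sd = config$within_type_sd), n, q)
    latent <- .normalize_rows(latent)
    ids <- sprintf("cell_%05d", seq_len(n))
    rownames(latent) <- ids

    embeddings <- list()
    for (m in seq_len(M)) {
      r <- config$embed_dims[m]
      A <- .modality_map(q, r)
      Y <- latent %*% A + matrix(stats::rnorm(n * r, sd = config$noise_sd[m]), n, r)
      if (config$n_batches > 1 && config$batch_effect_sd > 0) {
        shifts <- matrix(stats::rnorm(config$n_batches * r, sd = config$batch_effect_sd),
                         config$n_batches, r)
        Y <- Y + shifts[batch, , drop = FALSE]
      }
      rownames(Y) <- ids
      embeddings[[modal_names[m]]] <- embedding_set(
        Y, cell_ids = ids, batch = paste0("batch", batch), modality = modal_names[m]
      )
    }

    counts <- list()
    truth <- list(latent = latent, centroids = cents)
    if (!is.null(config$count_dims)) {
      d1 <- config$count_dims[1]
      Wg <- matrix(stats::rnorm(q * d1, sd = 1.5), q, d1)
      gene_int <- stats::rnorm(d1)
      logits <- latent %*% Wg + matrix(gene_int, n, d1, byrow = TRUE)
      pr <- exp(logits - .logsumexp_rows(logits))
      lib <- stats::rlnorm(n, meanlog = 8.5, sdlog = 0.35)
      sigma_g <- stats::runif(d1, 2, 10)
      mu_nb <- pr * lib
      Xrna <- matrix(stats::rnbinom(n * d1, size = rep(sigma_g, each = n), mu = mu_nb), n, d1)
      rownames(Xrna) <- ids
      counts$rna <- count_set(Xrna, feature_ids = sprintf("gene_%04d", seq_len(d1)), kind = "rna")
      truth$nb_mean <- mu_nb
      truth$nb_sigma <- sigma_g

      d2 <- config$count_dims[2]
      Wp <- matrix(stats::rnorm(q * d2, sd = 1.2), q, d2)
      peak_int <- stats::rnorm(d2, mean = -1.5, sd = 1)
      pacc <- stats::plogis(latent %*% Wp + matrix(peak_int, n, d2, byrow = TRUE))
      Xatac <- matrix(stats::rbinom(n * d2, 1, pacc), n, d2)
      rownames(Xatac) <- ids
      counts$atac <- count_set(Xatac, feature_ids = sprintf("peak_%04d", seq_len(d2)), kind = "atac")
      truth$atac_prob <- pacc
    }

    structure(
      list(embeddings = embeddings, counts = counts,
           cell_ids = ids, cell_type = factor(paste0("type", type)),
           batch = factor(paste0("batch", batch)), latent = latent,
           truth = truth, config = config),
      class = "sim_dataset"
    )
  })
}

#' Simulate a paired bimodal (RNA + ATAC) dataset
#'
#' @param config A [sim_config()] with `embed_dims` of length 2.
#' @return A `sim_dataset`: per-modality [embedding_set()]s and
#'   [count_set()]s plus ground-truth cell types, latent states and batches.
#' @export
simulate_multiome <- function(config = sim_config()) {
  if (length(config$embed_dims) != 2) stop_config("simulate_multiome needs 2 modalities; use simulate_trimodal for 3")
  .simulate_dataset(config)
}

#' Simulate a paired trimodal (RNA + ATAC + epitope) dataset
#'
#' The third modality mimics an epitope panel: a low-dimensional embedding
#' of the same latent state, without an accompanying count matrix.
#'
#' @param config A [sim_config()]; if `embed_dims` has length 2 an
#'   8-dimensional epitope modality is appended.
#' @return A `sim_dataset` with three embedding sets.
#' @export
simulate_trimodal <- function(config = sim_config()) {
  if (length(config$embed_dims) == 2) {
    config$embed_dims <- c(config$embed_dims, 8L)
    config$noise_sd <- c(config$noise_sd, config$noise_sd[1])
  }
  .simulate_dataset(config)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset: %d cells, %d types, %d batch(es), modalities: %s>\n",
              length(x$cell_ids), nlevels(x$cell_type), nlevels(x$batch),
              paste(names(x$embeddings), collapse = ", ")))
  invisible(x)
}

.subset_sim <- function(data, idx) {
  out <- data
  out$embeddings <- lapply(data$embeddings, function(e) {
    embedding_set(e$matrix[idx, , drop = FALSE], cell_ids = e$cell_ids[idx],
                  batch = as.character(e$batch)[idx], modality = e$modality)
  })
  out$counts <- lapply(data$counts, function(cs) {
    count_set(cs$matrix[idx, , drop = FALSE], feature_ids = cs$feature_ids, kind = cs$kind)
  })
  out$cell_ids <- data$cell_ids[idx]
  out$cell_type <- droplevels(data$cell_type[idx])
  out$batch <- droplevels(data$batch[idx])
  out$latent <- data$latent[idx, , drop = FALSE]
  out$truth <- list()
  out
}

#' Split a simulated dataset into a bridge and held-out unimodal parts
#'
#' Mirrors the bridge-integration protocol: a paired bridge subset used for
#' training and a disjoint held-out subset presented as two independent
#' unimodal datasets whose true correspondence is recorded in a truth
#' table.
#'
#' @param data A `sim_dataset`.
#' @param holdout_fraction Fraction of cells held out (ceiling applied).
#' @param seed Seed for the split and the shuffling of the unimodal sets.
#' @return List with `bridge` (a `sim_dataset`), `unimodal_A` and
#'   `unimodal_B` ([embedding_set()]s of the first/second modality in
#'   independent random orders), `truth` (data.frame `source_id`,
#'   `target_id`), and the held-out labels `holdout_type`.
#' @export
make_bridge_split <- function(data, holdout_fraction, seed = NULL) {
  if (!inherits(data, "sim_dataset")) stop_value("data must be a sim_dataset")
  if (holdout_fraction < 0 || holdout_fraction >= 1) stop_value("holdout_fraction must be in [0, 1)")
  n <- length(data$cell_ids)
  n_hold <- ceiling(holdout_fraction * n)
  with_seed_or_not(seed, {
    hold <- sort(sample.int(n, n_hold))
    keep <- setdiff(seq_len(n), hold)
    bridge <- .subset_sim(data, keep)
    mods <- names(data$embeddings)
    ordA <- sample(hold)
    ordB <- sample(hold)
    eA <- data$embeddings[[mods[1]]]
    eB <- data$embeddings[[mods[2]]]
    unimodal_A <- if (n_hold > 0) {
      embedding_set(eA$matrix[ordA, , drop = FALSE], cell_ids = eA$cell_ids[ordA],
                    batch = as.character(eA$batch)[ordA], modality = eA$modality)
    } else NULL
    unimodal_B <- if (n_hold > 0) {
      embedding_set(eB$matrix[ordB, , drop = FALSE], cell_ids = eB$cell_ids[ordB],
                    batch = as.character(eB$batch)[ordB], modality = eB$modality)
    } else NULL
    truth <- data.frame(source_id = data$cell_ids[hold],
                        target_id = data$cell_ids[hold],
                        stringsAsFactors = FALSE)
    ht <- data$cell_type[hold]
    names(ht) <- data$cell_ids[hold]
    list(bridge = bridge, unimodal_A = unimodal_A, unimodal_B = unimodal_B,
         truth = truth, holdout_type = ht)
  })
}

#' Downsample one cell type to a target proportion
#'
#' Robustness-protocol manipulation: reduces the named type's share of the
#' dataset to `target_proportion` (within one cell) by dropping a random
#' subset of that type; all other cells are untouched. `target_proportion
#' = 0` removes the type entirely.
#'
#' @param data A `sim_dataset`.
#' @param type_label The cell type to downsample.
#' @param target_proportion Desired share of the type in the output.
#' @param seed Seed for the random subset.
#' @return The downsampled `sim_dataset`.
#' @export
downsample_celltype <- function(data, type_label, target_proportion, seed = NULL) {
  if (!inherits(data, "sim_dataset")) stop_value("data must be a sim_dataset")
  if (target_proportion < 0 || target_proportion >= 1) stop_value("target_proportion must be in [0, 1)")
  is_type <- data$cell_type == type_label
  if (!any(is_type)) stop_value("cell type '%s' not present", type_label)
  n_other <- sum(!is_type)
  n_keep <- round(target_proportion * n_other / (1 - target_proportion))
  n_keep <- min(n_keep, sum(is_type))
  if (n_keep >= sum(is_type)) return(data)
  with_seed_or_not(seed, {
    keep_type <- sample(which(is_type), n_keep)
    idx <- sort(c(which(!is_type), keep_type))
    .subset_sim(data, idx)
  })
}

#' Make one cell type dominant
#'
#' The complementary robustness protocol: keeps all cells of the selected
#' type and downsamples every other type uniformly so the selected type
#' makes up `proportion` of the result.
#'
#' @param data A `sim_dataset`.
#' @param type_label The type to make dominant.
#' @param proportion Target share for the dominant type (e.g. 0.9).
#' @param seed Seed.
#' @return The rebalanced `sim_dataset`.
#' @export
make_dominant_type <- function(data, type_label, proportion, seed = NULL) {
  if (!inherits(data, "sim_dataset")) stop_value("data must be a sim_dataset")
  if (proportion <= 0 || proportion >= 1) stop_value("proportion must be in (0, 1)")
  is_type <- data$cell_type == type_label
  n_type <- sum(is_type)
  if (n_type == 0) stop_value("cell type '%s' not present", type_label)
  n_other_target <- round(n_type * (1 - proportion) / proportion)
  others <- which(!is_type)
  if (n_other_target >= length(others)) return(data)
  with_seed_or_not(seed, {
    keep_other <- sample(others, n_other_target)
    idx <- sort(c(which(is_type), keep_other))
    .subset_sim(data, idx)
  })
}
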