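#' Alignment and integration metrics
#'
#' Metrics for evaluating co-embeddings and pairings: FOSCTTM (fraction of
#' samples closer than the true match), graph iLISI (inverse Simpson index
#' of label diversity in kNN neighborhoods), kNN cell-type accuracy with
#' cross-batch and cross-validation drivers, triplet similarity (Tri-SIM)
#' and its percentile rank, cell-type-consistent pairing proportion, and
#' ARI/NMI cluster similarity. Distances on the sphere are Euclidean on the
#' unit vectors, which is rank-equivalent to cosine similarity.
#'
#' @name metrics
NULL

# Squared Euclidean cross-distance matrix between row sets.
.cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' For each cell, the fraction of other cells whose other-modality embedding
#' is strictly closer than the cell's own matched embedding; averaged over
#' cells and both directions. 0 means perfect alignment; ties at exactly
#' the true-match distance do not count against, so identical embeddings
#' give exactly 0.
#'
#' @param Z_A,Z_B Matched N x d embedding matrices (row i = same cell).
#' @return Scalar in [0, 1].
#' @export
foscttm <- function(Z_A, Z_B) {
  .assert_matrix(Z_A, "Z_A"); .assert_matrix(Z_B, "Z_B")
  if (!identical(dim(Z_A), dim(Z_B))) stop_shape("Z_A and Z_B must have identical dimensions")
  n <- nrow(Z_A)
  if (n < 2) stop_value("need at least 2 cells")
  D2 <- .cross_dist2(Z_A, Z_B)
  self <- diag(D2)
  frac_a <- (rowSums(D2 < self) - 0) / (n - 1)          # A_i vs all B_j
  frac_b <- (colSums(D2 < rep(self, each = n)) - 0) / (n - 1) # B_j vs all A_i
  # note: D2[i,i] < self[i] is FALSE, so self never counts
  (mean(frac_a) + mean(frac_b)) / 2
}

#' Graph iLISI: label mixing in kNN neighborhoods
#'
#' Mean over cells of the inverse Simpson index of label proportions within
#' each cell's k-nearest-neighbor set (self excluded). Ranges from 1 (no
#' mixing) to the number of labels (perfect mixing).
#'
#' @param Z N x d embedding matrix.
#' @param labels Per-cell labels (modality or batch).
#' @param k Neighborhood size (default 90, the common graph-LISI setting;
#'   capped at N - 1).
#' @return Scalar in [1, number of labels].
#' @export
graph_ilisi <- function(Z, labels, k = 90) {
  .assert_matrix(Z, "Z")
  labels <- as.factor(labels)
  n <- nrow(Z)
  if (length(labels) != n) stop_shape("labels length != cells")
  if (nlevels(droplevels(labels)) < 2) {
    warning("single label: iLISI is 1 by definition")
    return(1)
  }
  k <- min(k, n - 1)
  D2 <- .cross_dist2(Z, Z)
  diag(D2) <- Inf
  lab <- as.integer(droplevels(labels))
  L <- max(lab)
  simpson_inv <- vapply(seq_len(n), function(i) {
    nn <- order(D2[i, ])[seq_len(k)]
    p <- tabulate(lab[nn], nbins = L) / k
    1 / sum(p^2)
  }, numeric(1))
  mean(simpson_inv)
}

#' k-nearest-neighbor label prediction accuracy
#'
#' Majority-vote kNN accuracy for each k in `k_list` (defaults to the
#' standard grid 5, 17, 29, 41, 53, 65). Vote ties are broken toward the
#' class of the nearest neighbor among the tied classes, which is both
#' deterministic and invariant under renaming the classes.
#'
#' @param Z_train,Z_test Embedding matrices.
#' @param labels_train,labels_test Per-cell labels.
#' @param k_list Neighborhood sizes (each <= number of training cells).
#' @param exclude_self When train and test are the same set, exclude each
#'   point from its own neighbor list.
#' @return Named numeric vector of accuracies, one per k.
#' @export
knn_accuracy <- function(Z_train, labels_train, Z_test, labels_test,
                         k_list = c(5, 17, 29, 41, 53, 65),
                         exclude_self = FALSE) {
  .assert_matrix(Z_train, "Z_train"); .assert_matrix(Z_test, "Z_test")
  if (nrow(Z_test) == 0) stop_value("empty test set")
  if (length(labels_train) != nrow(Z_train)) stop_shape("labels_train length mismatch")
  if (length(labels_test) != nrow(Z_test)) stop_shape("labels_test length mismatch")
  if (any(k_list > nrow(Z_train) - as.integer(exclude_self))) {
    stop_value("k exceeds the number of training cells")
  }
  lt <- as.character(labels_train)
  levs <- sort(unique(lt))
  lt_i <- match(lt, levs)
  D2 <- .cross_dist2(Z_test, Z_train)
  if (exclude_self) diag(D2) <- Inf
  ord <- t(apply(D2, 1, order))
  acc <- vapply(k_list, function(k) {
    pred <- vapply(seq_len(nrow(D2)), function(i) {
      nn <- ord[i, seq_len(k)]
      votes <- tabulate(lt_i[nn], nbins = length(levs))
      tied <- which(votes == max(votes))
      if (length(tied) > 1) {
        # tie-break: class of the closest neighbor among the tied classes
        tied <- lt_i[nn[which(lt_i[nn] %in% tied)[1]]]
      }
      levs[tied]
    }, character(1))
    mean(pred == as.character(labels_test))
  }, numeric(1))
  names(acc) <- paste0("k", k_list)
  acc
}

#' Cross-batch kNN accuracy driver
#'
#' Holds out one batch at a time as the test set, using all other batches as
#' the neighbor pool (pure neighbor lookup, nothing refit).
#'
#' @inheritParams knn_accuracy
#' @param Z Embedding matrix for all cells.
#' @param labels Cell-type labels.
#' @param batch Batch labels.
#' @return data.frame with columns batch, k, accuracy.
#' @export
knn_cross_batch <- function(Z, labels, batch, k_list = c(5, 17, 29, 41, 53, 65)) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) stop_value("cross-batch validation needs >= 2 batches")
  out <- lapply(levels(batch), function(b) {
    te <- batch == b
    acc <- knn_accuracy(Z[!te, , drop = FALSE], labels[!te],
                        Z[te, , drop = FALSE], labels[te], k_list)
    data.frame(batch = b, k = k_list, accuracy = unname(acc))
  })
  do.call(rbind, out)
}

#' 10-fold cross-validated kNN accuracy driver
#'
#' @inheritParams knn_cross_batch
#' @param folds Number of folds.
#' @param seed Seed for fold assignment.
#' @return data.frame with columns fold, k, accuracy.
#' @export
knn_cv <- function(Z, labels, k_list = c(5, 17, 29, 41, 53, 65), folds = 10, seed = NULL) {
  n <- nrow(Z)
  fold <- with_seed_or_not(seed, sample(rep_len(seq_len(folds), n)))
  out <- lapply(seq_len(folds), function(f) {
    te <- fold == f
    acc <- knn_accuracy(Z[!te, , drop = FALSE], labels[!te],
                        Z[te, , drop = FALSE], labels[te], k_list)
    data.frame(fold = f, k = k_list, accuracy = unname(acc))
  })
  do.call(rbind, out)
}

#' Triplet similarity (Tri-SIM)
#'
#' Sum of the three pairwise cosine similarities among one cell's
#' embeddings from three modalities; 3 when all coincide, 0 for mutually
#' orthogonal directions.
#'
#' @param z1,z2,z3 Unit vectors, or matched matrices of unit rows.
#' @return Scalar, or vector with one value per row.
#' @export
trisim <- function(z1, z2, z3) {
  if (is.null(dim(z1))) { z1 <- rbind(z1); z2 <- rbind(z2); z3 <- rbind(z3); scalar <- TRUE }
  else scalar <- FALSE
  if (!identical(dim(z1), dim(z2)) || !identical(dim(z1), dim(z3))) {
    stop_shape("all three inputs must share dimensions")
  }
  v <- rowSums(z1 * z2) + rowSums(z1 * z3) + rowSums(z2 * z3)
  if (scalar) v[[1]] else v
}

#' Percentile rank of the true triplet's Tri-SIM
#'
#' For each cell i, ranks Tri-SIM(i, i, i) within the set of Tri-SIM(i, j,
#' k) over candidate partners (j, k). Exhaustive when N^2 candidates are at
#' most `exhaustive_limit`; otherwise a seeded subsample of `subsample`
#' candidate pairs is used (always including the true pair).
#'
#' @param Z_1,Z_2,Z_3 Matched N x d matrices of unit rows.
#' @param subsample Candidate pairs drawn per cell in subsampling mode.
#' @param seed Seed for subsampling.
#' @param exhaustive_limit Threshold on N^2 for the exhaustive mode.
#' @return Numeric vector of per-cell percentiles in (0, 100].
#' @export
trisim_percentile <- function(Z_1, Z_2, Z_3, subsample = 1e5, seed = NULL,
                              exhaustive_limit = 1e6) {
  if (!identical(dim(Z_1), dim(Z_2)) || !identical(dim(Z_1), dim(Z_3))) {
    stop_shape("all three embedding matrices must share dimensions")
  }
  n <- nrow(Z_1)
  c12 <- tcrossprod(Z_1, Z_2)
  c13 <- tcrossprod(Z_1, Z_3)
  c23 <- tcrossprod(Z_2, Z_3)
  true_sim <- diag(c12) + diag(c13) + diag(c23)
  if (n^2 <= exhaustive_limit || subsample >= n^2) {
    vapply(seq_len(n), function(i) {
      cand <- outer(c12[i, ], c13[i, ], `+`) + c23
      100 * mean(cand <= true_sim[i])
    }, numeric(1))
  } else {
    with_seed_or_not(seed, {
      vapply(seq_len(n), function(i) {
        j <- sample.int(n, subsample, replace = TRUE)
        k <- sample.int(n, subsample, replace = TRUE)
        cand <- c(c12[i, j] + c13[i, k] + c23[cbind(j, k)], true_sim[i])
        100 * mean(cand <= true_sim[i])
      }, numeric(1))
    })
  }
}

#' Cell-type-consistent pairing proportion
#'
#' A pairing is consistent when its source and target cells carry the same
#' label. Returns the number of consistent pairs divided by
#' `reference_count` (by default the number of pairs; the robustness
#' protocol divides by the original number of cells of a downsampled type).
#'
#' @param pairs A [assign_pairs()] result or a data.frame with columns
#'   `source_id` and `target_id`.
#' @param labels_source,labels_target Named label vectors covering all
#'   paired ids.
#' @param reference_count Denominator for the proportion.
#' @return List with `proportion`, `n_consistent`, `per_label` breakdown.
#' @export
pairing_consistency <- function(pairs, labels_source, labels_target,
                                reference_count = NULL) {
  df <- if (inherits(pairs, "pairing_result")) pairs$pairs else pairs
  if (nrow(df) == 0) {
    return(list(proportion = 0, n_consistent = 0L,
                per_label = data.frame(label = character(0), n_consistent = integer(0),
                                       n_pairs = integer(0))))
  }
  if (!all(df$source_id %in% names(labels_source))) stop_value("missing source label for a paired id")
  if (!all(df$target_id %in% names(labels_target))) stop_value("missing target label for a paired id")
  ls <- as.character(labels_source[df$source_id])
  lt <- as.character(labels_target[df$target_id])
  cons <- ls == lt
  ref <- reference_count %||% nrow(df)
  per <- stats::aggregate(cons, by = list(label = ls), FUN = function(v) c(sum(v), length(v)))
  per_label <- data.frame(label = per$label,
                          n_consistent = per$x[, 1], n_pairs = per$x[, 2])
  list(proportion = sum(cons) / ref, n_consistent = sum(cons), per_label = per_label)
}

#' Cluster similarity: adjusted Rand index and normalized mutual information
#'
#' Standard ARI (expected-value-corrected Rand index) and NMI (mutual
#' information normalized by the arithmetic mean of the entropies), both
#' computed from the contingency table. Identical labelings give (1, 1); a
#' constant labeling against a non-constant one gives (0, 0).
#'
#' @param labels_a,labels_b Two labelings of the same cells.
#' @return List with elements `ari` and `nmi`.
#' @export
cluster_similarity <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop_shape("labelings must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  # ARI
  sum_comb <- function(x) sum(choose(x, 2))
  a <- sum_comb(rowSums(tab)); b <- sum_comb(colSums(tab))
  index <- sum_comb(as.vector(tab))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  ari <- if (max_index == expected) {
    if (index == expected) 1 else 0
  } else {
    (index - expected) / (max_index - expected)
  }
  # NMI (arithmetic normalization)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  pij <- p[p > 0]
  mi <- sum(pij * log(pij / (rep(pa, times = ncol(tab))[p > 0] *
                               rep(pb, each = nrow(tab))[p > 0])))
  nmi <- if (Ha == 0 && Hb == 0) 1 else if (Ha == 0 || Hb == 0) 0 else mi / ((Ha + Hb) / 2)
  list(ari = ari, nmi = max(0, min(1, nmi)))
}

#' Write an evaluation report
#'
#' Writes a delimited (metric, split, k, value) table plus a JSON summary.
#'
#' @param rows data.frame with columns metric, split, k, value.
#' @param path Output TSV path; a `.json` twin is written alongside.
#' @export
write_metrics_report <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- split(rows$value, paste0(rows$metric, ifelse(is.na(rows$k), "", paste0("_k", rows$k))))
  jsonlite::write_json(lapply(js, function(v) unname(v)[1]),
                       sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
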