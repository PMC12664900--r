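#' Artificial pairing of unimodal profiles on the common sphere
#'
#' After bridge training, unimodal datasets are projected onto the common
#' hypersphere and matched: a bipartite graph weighted by cosine similarity
#' is built between the two cell sets, edges below 1 - epsilon are pruned
#' (so dissimilar cells stay unpaired rather than being force-matched), and
#' a maximum-weight matching over the surviving edges yields the artificial
#' multiomics cells. A chunked approximation handles large datasets, a
#' randomized greedy algorithm handles the (NP-hard) tripartite case, and a
#' linear-assignment variant pairs an already-paired two-modality dataset
#' with a third modality.
#'
#' @name pairing
NULL

.rowsafe_ids <- function(Z, prefix) {
  rownames(Z) %||% sprintf("%s%d", prefix, seq_len(nrow(Z)))
}

#' Build the pruned cosine-similarity bipartite graph
#'
#' Edge weight w(i, j) = cosine(z_i, z_j) when the cosine is at least
#' 1 - epsilon; other edges are absent. Zero- and negative-weight edges are
#' also absent: they can never contribute to a maximum-weight matching.
#'
#' @param Z_P,Z_Q Unit-row embedding matrices on the same sphere.
#' @param epsilon Cutoff adjustment in (0, 2).
#' @return A `similarity_graph`: sparse weights, cutoff, and the id vectors.
#' @export
build_similarity_graph <- function(Z_P, Z_Q, epsilon) {
  .assert_matrix(Z_P, "Z_P"); .assert_matrix(Z_Q, "Z_Q")
  if (ncol(Z_P) != ncol(Z_Q)) stop_shape("embeddings must share the sphere dimension")
  if (epsilon <= 0 || epsilon >= 2) stop_value("epsilon must be in (0, 2)")
  C <- tcrossprod(.normalize_rows(Z_P), .normalize_rows(Z_Q))
  keep <- C >= (1 - epsilon) & C > 0
  idx <- which(keep, arr.ind = TRUE)
  W <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = C[idx],
                            dims = dim(C))
  structure(
    list(weights = W, epsilon = epsilon,
         source_ids = .rowsafe_ids(Z_P, "P"), target_ids = .rowsafe_ids(Z_Q, "Q")),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph: %d x %d cells, %d edges, epsilon = %g>\n",
              nrow(x$weights), ncol(x$weights), Matrix::nnzero(x$weights), x$epsilon))
  invisible(x)
}

.pairing_result <- function(pairs, unpaired_source, unpaired_target, epsilon) {
  structure(
    list(pairs = pairs, unpaired_source = unpaired_source,
         unpaired_target = unpaired_target, epsilon = epsilon,
         total_weight = sum(pairs$similarity)),
    class = "pairing_result"
  )
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("<pairing_result: %d pairs (total weight %.3f), %d + %d unpaired, epsilon = %g>\n",
              nrow(x$pairs), x$total_weight, length(x$unpaired_source),
              length(x$unpaired_target), x$epsilon))
  invisible(x)
}

#' Maximum-weight bipartite matching on a pruned similarity graph
#'
#' Finds the matching of maximum total weight using only the surviving
#' (unpruned) edges; cells with no surviving edge remain unpaired. Edge
#' order is canonicalized by cell id so the result is reproducible for a
#' given input.
#'
#' @param graph A [build_similarity_graph()] result.
#' @return A `pairing_result` with the matched pairs (source_id, target_id,
#'   similarity), the unpaired ids on both sides, and the total weight.
#' @export
assign_pairs <- function(graph) {
  if (!inherits(graph, "similarity_graph")) stop_value("graph must be a similarity_graph")
  nP <- nrow(graph$weights); nQ <- ncol(graph$weights)
  tr <- Matrix::summary(graph$weights)
  tr <- tr[tr$x > 0, , drop = FALSE]
  empty <- data.frame(source_id = character(0), target_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(tr) == 0) {
    return(.pairing_result(empty, graph$source_ids, graph$target_ids, graph$epsilon))
  }
  # canonical edge order for solver determinism
  ord <- order(graph$source_ids[tr$i], graph$target_ids[tr$j])
  tr <- tr[ord, , drop = FALSE]
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nP), rep(TRUE, nQ)),
                                    rbind(tr$i, nP + tr$j))
  mm <- igraph::max_bipartite_match(g, weights = tr$x, eps = 1e-10)
  match_vec <- mm$matching[seq_len(nP)]
  paired <- which(!is.na(match_vec) & match_vec > 0)
  if (length(paired) == 0) {
    return(.pairing_result(empty, graph$source_ids, graph$target_ids, graph$epsilon))
  }
  tgt <- match_vec[paired] - nP
  sim <- graph$weights[cbind(paired, tgt)]
  pairs <- data.frame(source_id = graph$source_ids[paired],
                      target_id = graph$target_ids[tgt],
                      similarity = as.numeric(sim), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source_id), , drop = FALSE]
  rownames(pairs) <- NULL
  .pairing_result(pairs,
                  setdiff(graph$source_ids, pairs$source_id),
                  setdiff(graph$target_ids, pairs$target_id),
                  graph$epsilon)
}

#' Chunked approximate matching for large datasets
#'
#' Splits both cell sets into random disjoint subsets (seeded permutation,
#' then contiguous blocks) and solves the maximum-weight matching within
#' each chunk pair. The union of per-chunk matchings is a valid matching
#' whose total weight is at most the unchunked optimum; with a single chunk
#' the result is exactly [assign_pairs()].
#'
#' @inheritParams build_similarity_graph
#' @param chunk_size Cells per chunk (default 10000).
#' @param seed Seed for the random chunk assignment.
#' @return A `pairing_result`; pairs carry a `chunk_id` column.
#' @export
chunked_assign <- function(Z_P, Z_Q, epsilon, chunk_size = 10000, seed = NULL) {
  if (chunk_size < 2) stop_value("chunk_size must be >= 2")
  nP <- nrow(Z_P); nQ <- nrow(Z_Q)
  idsP <- .rowsafe_ids(Z_P, "P"); idsQ <- .rowsafe_ids(Z_Q, "Q")
  rownames(Z_P) <- idsP; rownames(Z_Q) <- idsQ
  n_chunks <- max(ceiling(nP / chunk_size), ceiling(nQ / chunk_size))
  split_idx <- function(n, n_chunks) {
    perm <- sample.int(n)
    block <- ceiling(n / n_chunks)
    split(perm, ceiling(seq_len(n) / block))
  }
  with_seed_or_not(seed, {
    chP <- split_idx(nP, n_chunks)
    chQ <- split_idx(nQ, n_chunks)
    pieces <- list()
    for (ci in seq_len(n_chunks)) {
      iP <- chP[[ci]]; iQ <- chQ[[ci]]
      if (length(iP) == 0 || length(iQ) == 0) next
      res <- assign_pairs(build_similarity_graph(Z_P[iP, , drop = FALSE],
                                                 Z_Q[iQ, , drop = FALSE], epsilon))
      if (nrow(res$pairs) > 0) {
        res$pairs$chunk_id <- ci
        pieces[[length(pieces) + 1]] <- res$pairs
      }
    }
    pairs <- if (length(pieces) > 0) do.call(rbind, pieces) else
      data.frame(source_id = character(0), target_id = character(0),
                 similarity = numeric(0), chunk_id = integer(0))
    pairs <- pairs[order(pairs$source_id), , drop = FALSE]
    rownames(pairs) <- NULL
    .pairing_result(pairs, setdiff(idsP, pairs$source_id),
                    setdiff(idsQ, pairs$target_id), epsilon)
  })
}

#' Randomized greedy tripartite matching
#'
#' Exact tripartite maximum matching is NP-hard, so triplets are built
#' greedily: a cell is drawn at random from the modality with the fewest
#' remaining cells, its best-partner pair (j, k) maximizing the triplet
#' similarity (sum of the three pairwise cosines) is selected, and all
#' three are removed. A drawn cell whose best attainable triplet falls
#' below `min_trisim` is left unpaired. When the remaining candidate
#' product exceeds `search_limit`, the argmax is restricted to the drawn
#' cell's `top_n` nearest neighbors in each modality.
#'
#' @param Z_1,Z_2,Z_3 Unit-row embedding matrices on the same sphere.
#' @param min_trisim Minimum triplet similarity to accept (in [-3, 3]).
#' @param seed Seed for the random selection order.
#' @param top_n Neighbor restriction for large instances.
#' @param search_limit Candidate-product threshold above which the
#'   restriction applies.
#' @return data.frame with columns id_1, id_2, id_3, trisim.
#' @export
greedy_triplet_pair <- function(Z_1, Z_2, Z_3, min_trisim, seed = NULL,
                                top_n = 50, search_limit = 20000) {
  Zs <- list(.normalize_rows(Z_1), .normalize_rows(Z_2), .normalize_rows(Z_3))
  dchk <- vapply(Zs, ncol, integer(1))
  if (length(unique(dchk)) != 1) stop_shape("all modalities must share the sphere dimension")
  ids <- list(.rowsafe_ids(Z_1, "A"), .rowsafe_ids(Z_2, "B"), .rowsafe_ids(Z_3, "C"))
  c12 <- tcrossprod(Zs[[1]], Zs[[2]])
  c13 <- tcrossprod(Zs[[1]], Zs[[3]])
  c23 <- tcrossprod(Zs[[2]], Zs[[3]])
  smallest <- which.min(vapply(Zs, nrow, integer(1)))
  rem <- lapply(Zs, function(z) seq_len(nrow(z)))
  out <- list()
  with_seed_or_not(seed, {
    while (all(lengths(rem) > 0)) {
      pick <- rem[[smallest]][sample.int(length(rem[[smallest]]), 1)]
      # express similarities relative to the picked modality
      if (smallest == 1) {
        sj <- c12[pick, rem[[2]]]; sk <- c13[pick, rem[[3]]]
        pairjk <- c23[rem[[2]], rem[[3]], drop = FALSE]
      } else if (smallest == 2) {
        sj <- c12[rem[[1]], pick]; sk <- c23[pick, rem[[3]]]
        pairjk <- c13[rem[[1]], rem[[3]], drop = FALSE]
      } else {
        sj <- c13[rem[[1]], pick]; sk <- c23[rem[[2]], pick]
        pairjk <- c12[rem[[1]], rem[[2]], drop = FALSE]
      }
      jcand <- seq_along(sj); kcand <- seq_along(sk)
      if (length(sj) * length(sk) > search_limit) {
        jcand <- order(sj, decreasing = TRUE)[seq_len(min(top_n, length(sj)))]
        kcand <- order(sk, decreasing = TRUE)[seq_len(min(top_n, length(sk)))]
      }
      score <- outer(sj[jcand], sk[kcand], `+`) + pairjk[jcand, kcand, drop = FALSE]
      best <- arrayInd(which.max(score), dim(score))
      best_val <- score[best]
      jj <- jcand[best[1]]; kk <- kcand[best[2]]
      if (smallest == 1) {
        trip <- c(pick, rem[[2]][jj], rem[[3]][kk])
      } else if (smallest == 2) {
        trip <- c(rem[[1]][jj], pick, rem[[3]][kk])
      } else {
        trip <- c(rem[[1]][jj], rem[[2]][kk], pick)
      }
      if (best_val >= min_trisim) {
        out[[length(out) + 1]] <- data.frame(
          id_1 = ids[[1]][trip[1]], id_2 = ids[[2]][trip[2]], id_3 = ids[[3]][trip[3]],
          trisim = best_val, stringsAsFactors = FALSE)
        for (m in 1:3) rem[[m]] <- setdiff(rem[[m]], trip[m])
      } else {
        # drawn cell cannot reach the threshold: leave it unpaired
        rem[[smallest]] <- setdiff(rem[[smallest]], pick)
      }
    }
  })
  if (length(out) == 0) {
    return(data.frame(id_1 = character(0), id_2 = character(0), id_3 = character(0),
                      trisim = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pair an already-paired two-modality dataset with a third modality
#'
#' Joint cells (with embeddings in two modalities) are matched against
#' third-modality cells under the summed cosine similarity; candidate pairs
#' whose summed similarity falls below 2 - epsilon are pruned, and the
#' optimum over the surviving edges is found by maximum-weight bipartite
#' matching.
#'
#' @param Z_paired_A,Z_paired_B Matched embeddings of the joint cells (same
#'   cells, same order).
#' @param Z_third Embeddings of the third-modality cells.
#' @param epsilon Cutoff adjustment in (0, 2); weights below 2 - epsilon
#'   are pruned.
#' @return A `pairing_result`; `similarity` holds the summed weight.
#' @export
paired_plus_one_assign <- function(Z_paired_A, Z_paired_B, Z_third, epsilon) {
  .assert_matrix(Z_paired_A, "Z_paired_A"); .assert_matrix(Z_paired_B, "Z_paired_B")
  if (nrow(Z_paired_A) != nrow(Z_paired_B)) stop_shape("paired partitions must index the same cells")
  idsA <- .rowsafe_ids(Z_paired_A, "P")
  idsB <- rownames(Z_paired_B)
  if (!is.null(idsB) && !identical(idsA, idsB)) stop_shape("paired partitions must index the same cells")
  if (epsilon <= 0 || epsilon >= 2) stop_value("epsilon must be in (0, 2)")
  if (ncol(Z_paired_A) != ncol(Z_third) || ncol(Z_paired_B) != ncol(Z_third)) {
    stop_shape("embeddings must share the sphere dimension")
  }
  W <- tcrossprod(.normalize_rows(Z_paired_A), .normalize_rows(Z_third)) +
    tcrossprod(.normalize_rows(Z_paired_B), .normalize_rows(Z_third))
  idsT <- .rowsafe_ids(Z_third, "T")
  keep <- W >= (2 - epsilon) & W > 0
  idx <- which(keep, arr.ind = TRUE)
  g <- structure(
    list(weights = Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2],
                                        x = W[idx], dims = dim(W)),
         epsilon = epsilon, source_ids = idsA, target_ids = idsT),
    class = "similarity_graph"
  )
  assign_pairs(g)
}
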