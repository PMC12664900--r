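#' Per-modality low-dimensional embedding container
#'
#' Holds a cells x r matrix of batch-corrected low-dimensional
#' representations (e.g. PCA for RNA, LSI for ATAC, a VAE latent space),
#' unique cell identifiers, and optional per-cell batch labels. This is the
#' input the model consumes; computing the representations themselves is
#' upstream of this package.
#'
#' @param matrix Numeric cells x r matrix, r >= 2, no missing values.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   the matrix rownames.
#' @param batch Optional per-cell batch labels (factor or character).
#' @param modality Name of the modality (e.g. "rna", "atac").
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(matrix, cell_ids = rownames(matrix), batch = NULL,
                          modality = "modality") {
  .assert_matrix(matrix, "matrix")
  if (ncol(matrix) < 2) stop_value("embedding matrix needs at least 2 columns")
  if (is.null(cell_ids)) stop_value("cell_ids are required (or set rownames)")
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(matrix)) {
    stop_shape("cell_ids length (%d) != number of rows (%d)", length(cell_ids), nrow(matrix))
  }
  if (anyDuplicated(cell_ids)) stop_value("cell_ids must be unique")
  if (is.null(batch)) batch <- rep("batch1", nrow(matrix))
  batch <- as.factor(batch)
  if (length(batch) != nrow(matrix)) stop_shape("batch length != number of cells")
  rownames(matrix) <- cell_ids
  structure(
    list(matrix = matrix, cell_ids = cell_ids, batch = batch,
         modality = as.character(modality)),
    class = "embedding_set"
  )
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set '%s': %d cells x %d dims, %d batch(es)>\n",
              x$modality, nrow(x$matrix), ncol(x$matrix), nlevels(x$batch)))
  invisible(x)
}

#' @export
dim.embedding_set <- function(x) dim(x$matrix)

#' Raw count matrix container
#'
#' Cells x features non-negative integer counts. ATAC counts are consumed in
#' binarized form (entry 1 iff the raw entry is >= 1); binarization happens
#' at model/likelihood level, the container keeps raw counts.
#'
#' @param matrix Numeric cells x features matrix of non-negative integers.
#' @param feature_ids Feature identifiers; default colnames.
#' @param kind One of "rna", "atac", "epitope".
#' @return An object of class `count_set`.
#' @export
count_set <- function(matrix, feature_ids = colnames(matrix),
                      kind = c("rna", "atac", "epitope")) {
  kind <- match.arg(kind)
  .assert_matrix(matrix, "matrix")
  if (any(matrix < 0) || any(matrix != round(matrix))) {
    stop_format("counts must be non-negative integers")
  }
  if (is.null(feature_ids)) feature_ids <- sprintf("feature_%d", seq_len(ncol(matrix)))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(matrix)) stop_shape("feature_ids length != columns")
  colnames(matrix) <- feature_ids
  structure(
    list(matrix = matrix, feature_ids = feature_ids, kind = kind),
    class = "count_set"
  )
}

#' @export
print.count_set <- function(x, ...) {
  cat(sprintf("<count_set (%s): %d cells x %d features>\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Binarize a count matrix
#'
#' @param x Numeric matrix or `count_set`.
#' @return Matrix of 0/1 values (1 iff count >= 1).
#' @export
binarize_counts <- function(x) {
  m <- if (inherits(x, "count_set")) x$matrix else x
  (m >= 1) * 1
}

#' Model hyperparameters
#'
#' Defaults follow the published training recipe: single hidden layer of 128
#' units with layer normalization and ELU activations for every network,
#' Adam with initial learning rate 0.005 and decay 0.00006 (interpreted as
#' additive L2 weight decay by default; a multiplicative learning-rate
#' schedule can be selected with `decay_mode = "lr_schedule"`), and a
#' minibatch size of 2000 (5000 is the published alternative for large
#' data). All four auxiliary loss weights default to 1 because the overall
#' objective is printed unweighted.
#'
#' @param latent_dim Dimension d of the ambient latent space; the embedding
#'   sphere is S^(d-1). Must be >= 2.
#' @param hidden_units Hidden layer width for every network.
#' @param loss_weights Named weights for the contrastive, modality
#'   discriminator, batch discriminator and alignment terms.
#' @param learning_rate Initial Adam learning rate.
#' @param weight_decay Decay constant (L2 weight decay, or the schedule rate
#'   when `decay_mode = "lr_schedule"`).
#' @param decay_mode How to apply `weight_decay`.
#' @param minibatch_size Cells per minibatch (>= 2; the contrastive loss is
#'   degenerate for a single cell).
#' @param n_epochs Training epochs.
#' @param seed Integer seed controlling initialization and training.
#' @param use_count_decoders Train negative-binomial / Bernoulli count
#'   decoders on top of the low-dimensional decoders.
#' @param use_pretrained_decoders Expect a caller-supplied reconstruction
#'   function at imputation time instead of trained count decoders.
#' @param tau_init Initial contrastive temperature (learned in log space,
#'   clamped to [1e-3, 100]).
#' @return An object of class `model_config`.
#' @export
model_config <- function(latent_dim = 10,
                         hidden_units = 128,
                         loss_weights = c(contrastive = 1, modality_disc = 1,
                                          batch_disc = 1, align = 1),
                         learning_rate = 0.005,
                         weight_decay = 0.00006,
                         decay_mode = c("weight_decay", "lr_schedule"),
                         minibatch_size = 2000,
                         n_epochs = 100,
                         seed = 0,
                         use_count_decoders = FALSE,
                         use_pretrained_decoders = FALSE,
                         tau_init = 0.07) {
  decay_mode <- match.arg(decay_mode)
  if (latent_dim < 2) stop_config("latent_dim must be >= 2")
  if (minibatch_size < 2) stop_config("minibatch_size must be >= 2 (contrastive loss is degenerate at 1)")
  need <- c("contrastive", "modality_disc", "batch_disc", "align")
  if (!all(need %in% names(loss_weights))) {
    stop_config("loss_weights must name: %s", paste(need, collapse = ", "))
  }
  if (any(loss_weights < 0)) stop_config("loss weights must be >= 0")
  if (n_epochs < 0) stop_config("n_epochs must be >= 0")
  if (tau_init <= 0) stop_config("tau_init must be > 0")
  structure(
    list(latent_dim = as.integer(latent_dim), hidden_units = as.integer(hidden_units),
         loss_weights = loss_weights[need], learning_rate = learning_rate,
         weight_decay = weight_decay, decay_mode = decay_mode,
         minibatch_size = as.integer(minibatch_size), n_epochs = as.integer(n_epochs),
         seed = as.integer(seed), use_count_decoders = isTRUE(use_count_decoders),
         use_pretrained_decoders = isTRUE(use_pretrained_decoders),
         tau_init = tau_init),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: d=%d, hidden=%d, lr=%g, mb=%d, epochs=%d, seed=%d>\n",
              x$latent_dim, x$hidden_units, x$learning_rate, x$minibatch_size,
              x$n_epochs, x$seed))
  invisible(x)
}

# Coerce an embedding_set or bare matrix to a numeric matrix.
.as_embedding_matrix <- function(Y) {
  m <- if (inherits(Y, "embedding_set")) Y$matrix else Y
  .assert_matrix(m, "embedding matrix")
  m
}
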