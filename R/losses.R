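#' Loss functions of the co-embedding model
#'
#' The training objective combines five parts: a spherical VAE ELBO
#' (closed-form KL to the uniform prior plus Gaussian reconstruction of the
#' low-dimensional inputs, optionally extended with negative-binomial RNA
#' and Bernoulli ATAC count likelihoods), a temperature-scaled symmetric
#' contrastive loss over matched cells, an adversarial modality
#' discriminator, an adversarial batch discriminator, and a cosine alignment
#' term. Discriminators maximize their log-likelihood terms while encoders
#' minimize them (a min-max objective trained by alternating updates).
#'
#' @name losses
NULL

.logsumexp_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  m + log(rowSums(exp(S - m)))
}

#' Symmetric contrastive (CLIP-style) loss for one modality pair
#'
#' Given matched unit directions for N cells in two modalities, computes the
#' temperature-scaled cross-entropy in both directions (each cell against
#' all candidates of the other modality, with the matched cell as the
#' positive) and returns their sum, each averaged over cells. Identical
#' batches at `tau = 1` give `2 * log(N)`; a single cell gives 0.
#'
#' @param mu_A,mu_B N x d matrices of unit row vectors, row i of each being
#'   the same cell.
#' @param tau Positive temperature.
#' @return Scalar loss (>= 0).
#' @export
clip_pair_loss <- function(mu_A, mu_B, tau) {
  .assert_matrix(mu_A, "mu_A")
  .assert_matrix(mu_B, "mu_B")
  if (!identical(dim(mu_A), dim(mu_B))) stop_shape("mu_A and mu_B must have identical dimensions")
  if (length(tau) != 1 || !is.finite(tau) || tau <= 0) stop_value("tau must be a positive scalar")
  .clip_loss_grad(mu_A, mu_B, tau, want_grads = FALSE)$loss
}

# Contrastive loss with gradients wrt both direction matrices and log(tau).
.clip_loss_grad <- function(mu_A, mu_B, tau, want_grads = TRUE) {
  n <- nrow(mu_A)
  C <- tcrossprod(mu_A, mu_B) # cosine similarities (rows unit norm)
  S <- C / tau
  idx <- cbind(seq_len(n), seq_len(n))
  lse_r <- .logsumexp_rows(S)
  tS <- t(S)
  lse_c <- .logsumexp_rows(tS)
  loss_ab <- mean(lse_r - S[idx])
  loss_ba <- mean(lse_c - S[idx])
  loss <- loss_ab + loss_ba
  if (!want_grads) return(list(loss = loss))
  P_row <- exp(S - lse_r)      # row-wise softmax
  P_col <- t(exp(tS - lse_c))  # column-wise softmax
  dS <- (P_row + P_col) / n
  dS[idx] <- dS[idx] - 2 / n
  dA <- (dS %*% mu_B) / tau
  dB <- (crossprod(dS, mu_A)) / tau
  dlogtau <- -sum(dS * S) # d/dlog(tau) of S = -S
  list(loss = loss, dA = dA, dB = dB, dlogtau = dlogtau)
}

#' Cosine alignment loss across modalities
#'
#' Negative mean pairwise cosine similarity between the per-cell directions
#' of all unordered modality pairs; -1 per pair when modalities coincide,
#' +1 per pair when they are antipodal.
#'
#' @param mu_list List of M matched N x d unit-row matrices.
#' @return Scalar loss.
#' @export
alignment_loss <- function(mu_list) {
  if (!is.list(mu_list) || length(mu_list) < 2) stop_value("mu_list must list >= 2 modalities")
  dims <- lapply(mu_list, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_shape("all modality direction matrices must share dimensions")
  }
  M <- length(mu_list)
  total <- 0
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      total <- total - mean(rowSums(mu_list[[i]] * mu_list[[j]]))
    }
  }
  total
}

# Multinomial cross-entropy with gradients: logits (n x K), labels in 1..K.
.softmax_ce_grad <- function(logits, labels) {
  n <- nrow(logits)
  lse <- .logsumexp_rows(logits)
  idx <- cbind(seq_len(n), labels)
  ce <- mean(lse - logits[idx])
  P <- exp(logits - lse)
  dlogits <- P / n
  dlogits[idx] <- dlogits[idx] - 1 / n
  list(ce = ce, dlogits = dlogits, P = P)
}

#' Modality discriminator objective
#'
#' The modality discriminator takes each per-modality direction and predicts
#' which modality produced it. Returns the discriminator's mean
#' log-probability of the correct modality summed over modalities (the
#' quantity the discriminator maximizes and the encoders minimize). A
#' chance-level discriminator with M modalities returns `M * log(1/M)`.
#'
#' @param state A fitted or initialized model (see [fit_spherepair()]).
#' @param mus Named list of N_m x d direction matrices, one per modality, in
#'   the model's modality order.
#' @return Scalar objective value (<= 0).
#' @export
modality_disc_loss <- function(state, mus) {
  .check_model(state)
  mus <- .check_mus(state, mus)
  total <- 0
  for (m in seq_along(mus)) {
    fw <- .nn_block_forward(state$disc_params$mod, mus[[m]])
    logp <- fw$out - .logsumexp_rows(fw$out)
    total <- total + mean(logp[, m])
  }
  total
}

#' Batch discriminator objective
#'
#' The batch discriminator predicts the batch of origin from each
#' modality's direction. Returns the mean log-probability of the correct
#' batch summed over modalities; with a single batch the value is 0.
#'
#' @inheritParams modality_disc_loss
#' @param batch_labels Per-cell batch labels (must come from the batches
#'   seen at initialization/training).
#' @return Scalar objective value (<= 0).
#' @export
batch_disc_loss <- function(state, mus, batch_labels) {
  .check_model(state)
  mus <- .check_mus(state, mus)
  lv <- state$batch_levels
  batch_labels <- as.character(batch_labels)
  if (!all(batch_labels %in% lv)) {
    stop_value("unseen batch label(s): %s",
               paste(setdiff(unique(batch_labels), lv), collapse = ", "))
  }
  lab <- match(batch_labels, lv)
  total <- 0
  for (m in seq_along(mus)) {
    if (nrow(mus[[m]]) != length(lab)) stop_shape("batch_labels length != cells")
    fw <- .nn_block_forward(state$disc_params$batch, mus[[m]])
    logp <- fw$out - .logsumexp_rows(fw$out)
    total <- total + mean(logp[cbind(seq_along(lab), lab)])
  }
  total
}

#' Negative binomial log-likelihood per cell
#'
#' Counts are modeled as NB with per-entry means and per-gene dispersion
#' `sigma` (the "size" parameterization: variance = mean + mean^2 / sigma,
#' so sigma -> Inf recovers the Poisson). Returns the log-likelihood summed
#' over genes, one value per cell.
#'
#' @param x Cells x genes matrix of non-negative integer counts.
#' @param mean Matrix of positive NB means, same shape as `x`.
#' @param sigma Positive per-gene dispersions (length = ncol(x)).
#' @return Numeric vector, one log-likelihood per cell.
#' @export
nb_log_likelihood <- function(x, mean, sigma) {
  .assert_matrix(x, "x")
  if (any(x < 0) || any(x != round(x))) stop_value("counts must be non-negative integers")
  if (!identical(dim(x), dim(mean))) stop_shape("x and mean must have identical dimensions")
  if (any(mean <= 0)) stop_value("NB means must be positive")
  if (length(sigma) != ncol(x) || any(sigma <= 0)) stop_value("sigma must be positive, one per gene")
  ll <- stats::dnbinom(x, size = rep(sigma, each = nrow(x)), mu = mean, log = TRUE)
  rowSums(matrix(ll, nrow(x), ncol(x)))
}

#' Bernoulli log-likelihood per cell
#'
#' For binarized accessibility: each region is a Bernoulli draw with
#' per-entry probability `p` (clamped away from 0 and 1).
#'
#' @param x_binary Cells x regions matrix with entries in {0, 1}.
#' @param p Probability matrix of the same shape.
#' @return Numeric vector, one log-likelihood per cell.
#' @export
bernoulli_log_likelihood <- function(x_binary, p) {
  .assert_matrix(x_binary, "x_binary")
  if (!all(x_binary %in% c(0, 1))) stop_value("x_binary must be 0/1; binarize counts first")
  if (!identical(dim(x_binary), dim(p))) stop_shape("x_binary and p must have identical dimensions")
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  rowSums(x_binary * log(p) + (1 - x_binary) * log1p(-p))
}

# NB gradient pieces used by the count decoder during training.
# dloglik/dmean and dloglik/dsigma for the size parameterization above.
.nb_grad_mean <- function(x, mean, sigma_row) {
  x / mean - (x + sigma_row) / (sigma_row + mean)
}

.nb_grad_sigma <- function(x, mean, sigma) {
  sig <- rep(sigma, each = nrow(x))
  g <- digamma(x + sig) - digamma(sig) + log(sig / (sig + mean)) + 1 - (x + sig) / (sig + mean)
  colSums(matrix(g, nrow(x), ncol(x)))
}
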