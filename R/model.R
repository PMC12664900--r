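#' @title Model core: contrastive hyperspherical co-embedding
#' @description
#' The model embeds each modality's low-dimensional representation onto a
#' common unit hypersphere through a per-modality encoder (single hidden
#' layer, layer normalization, ELU, then an affine head followed by L2
#' normalization). A shared concentration network maps the concatenated
#' inputs to kappa > 0. The per-modality directions are merged by a
#' dropout-derived rule (each coordinate taken from one modality chosen
#' uniformly at random during training; the coordinate mean at evaluation),
#' renormalized, and used as the direction of a Power Spherical posterior
#' from which one latent z per cell is drawn. Decoders reconstruct the
#' low-dimensional inputs (unit-variance Gaussian likelihood) and,
#' optionally, raw counts (negative binomial for RNA-like modalities,
#' Bernoulli for binarized ATAC). Training alternates a discriminator
#' update (maximizing the modality and batch discriminator objectives) with
#' an encoder/decoder update (minimizing -ELBO plus the weighted
#' contrastive, adversarial and alignment terms) using Adam.
#' @name model_core
NULL

.check_model <- function(state) {
  if (!inherits(state, "spherepair_model")) {
    stop_value("expected a 'spherepair_model' (see fit_spherepair())")
  }
  invisible(state)
}

.check_mus <- function(state, mus) {
  if (!is.list(mus) || length(mus) != length(state$modalities)) {
    stop_shape("need one direction matrix per modality (%d)", length(state$modalities))
  }
  if (!is.null(names(mus)) && all(names(mus) %in% state$modalities)) {
    mus <- mus[state$modalities]
  }
  d <- state$config$latent_dim
  for (m in seq_along(mus)) {
    .assert_matrix(mus[[m]], sprintf("mus[[%d]]", m))
    if (ncol(mus[[m]]) != d) stop_shape("direction matrix %d has %d columns, expected %d", m, ncol(mus[[m]]), d)
  }
  mus
}

.init_state <- function(input_dims, count_info, n_batches, batch_levels, config) {
  M <- length(input_dims)
  d <- config$latent_dim
  H <- config$hidden_units
  params <- list(
    enc = lapply(input_dims, function(r) .nn_init_block(r, H, d)),
    kappa = .nn_init_block(sum(input_dims), H, 1),
    dec = lapply(input_dims, function(r) .nn_init_block(d, H, r)),
    log_tau = log(config$tau_init)
  )
  # start concentrated (kappa ~ 10): gives the decoders a useful posterior
  # sample from the first step and avoids early posterior collapse, where
  # the KL term drives kappa into a saturated low-softplus regime before
  # the reconstruction gradient can counteract it
  params$kappa$b2 <- 10
  if (config$use_count_decoders && length(count_info) > 0) {
    params$cnt <- lapply(names(count_info), function(m) {
      .nn_init_block(input_dims[[m]], H, count_info[[m]]$n_features)
    })
    names(params$cnt) <- names(count_info)
    rna_like <- names(count_info)[vapply(count_info, function(ci) ci$kind != "atac", logical(1))]
    if (length(rna_like) > 0) {
      params$sigma_raw <- lapply(count_info[rna_like], function(ci) rep(1, ci$n_features))
    }
  }
  disc_params <- list(
    mod = .nn_init_block(d, H, M),
    batch = .nn_init_block(d, H, max(n_batches, 1L))
  )
  structure(
    list(
      params = params, disc_params = disc_params, config = config,
      modalities = names(input_dims), input_dims = input_dims,
      count_info = count_info, n_batches = n_batches,
      batch_levels = batch_levels, libsize_ref = NULL,
      trained = FALSE, history = NULL
    ),
    class = "spherepair_model"
  )
}

#' @export
print.spherepair_model <- function(x, ...) {
  cat(sprintf("<spherepair_model: %s -> S^%d, %s>\n",
              paste(sprintf("%s(%d)", x$modalities, unlist(x$input_dims)), collapse = " + "),
              x$config$latent_dim - 1,
              if (x$trained) sprintf("trained %d epochs", nrow(x$history)) else "untrained"))
  invisible(x)
}

#' Encode one modality onto the unit hypersphere
#'
#' Passes a modality's low-dimensional representations through that
#' modality's encoder and L2-normalizes the output, yielding one unit
#' direction per cell. Deterministic given the model state.
#'
#' @param state A `spherepair_model`.
#' @param Y An [embedding_set()] or numeric matrix whose column count
#'   matches the modality's configured input dimension.
#' @param modality Name of the modality to encode.
#' @return A cells x latent_dim matrix of unit row vectors (rownames carry
#'   the cell ids when available).
#' @export
encode <- function(state, Y, modality) {
  .check_model(state)
  if (!modality %in% state$modalities) {
    stop_value("unknown modality '%s' (model has: %s)", modality,
               paste(state$modalities, collapse = ", "))
  }
  X <- .as_embedding_matrix(Y)
  r <- state$input_dims[[modality]]
  if (ncol(X) != r) {
    stop_shape("modality '%s' expects %d input dimensions, got %d", modality, r, ncol(X))
  }
  fw <- .nn_block_forward(state$params$enc[[modality]], X)
  out <- .l2norm_forward(fw$out)$out
  rownames(out) <- rownames(X)
  out
}

#' Compute the posterior concentration kappa
#'
#' The concentration network consumes the concatenation of all modalities'
#' representations (training-time information), so every modality must be
#' supplied. At projection time (single modality) kappa is not available;
#' pairing and metrics use directions only.
#'
#' @param state A `spherepair_model`.
#' @param Y_all Named list with one embedding matrix / [embedding_set()] per
#'   modality, or a pre-concatenated matrix with `sum(input_dims)` columns.
#' @return Strictly positive concentration per cell.
#' @export
compute_kappa <- function(state, Y_all) {
  .check_model(state)
  if (is.list(Y_all) && !is.data.frame(Y_all)) {
    missing_m <- setdiff(state$modalities, names(Y_all))
    if (length(missing_m) > 0) {
      stop(errorCondition(
        sprintf("kappa requires all modalities; missing: %s", paste(missing_m, collapse = ", ")),
        class = c("spherepair_unsupported_error", "spherepair_error")))
    }
    X <- do.call(cbind, lapply(Y_all[state$modalities], .as_embedding_matrix))
  } else {
    X <- .as_embedding_matrix(Y_all)
  }
  if (ncol(X) != sum(unlist(state$input_dims))) {
    stop_shape("concatenated input must have %d columns", sum(unlist(state$input_dims)))
  }
  a <- drop(.nn_block_forward(state$params$kappa, X)$out)
  kap <- pmin(.softplus(a) + 1e-4, .KAPPA_MAX)
  names(kap) <- rownames(X)
  kap
}

#' Merge per-modality directions into a single posterior direction
#'
#' During training each coordinate of the merged vector is taken from one
#' modality chosen independently and uniformly at random (a dropout-derived
#' rule, probability 1/M per modality); at evaluation the coordinate-wise
#' mean is used (the expectation of the random mask). The merged vector is
#' renormalized to unit norm, as required by the Power Spherical direction.
#'
#' @param mu_list List of M matched cells x d matrices with unit rows.
#' @param mode `"train"` (random per-coordinate selection) or `"eval"`
#'   (deterministic mean).
#' @param seed Optional seed for the training-mode mask.
#' @return A cells x d matrix of unit rows.
#' @export
merge_directions <- function(mu_list, mode = c("train", "eval"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.list(mu_list) || length(mu_list) < 1) stop_value("mu_list must be a non-empty list")
  dims <- lapply(mu_list, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_shape("all direction matrices must share dimensions")
  }
  for (m in mu_list) {
    if (!.is_unit_rows(m, tol = 1e-4)) stop_value("direction rows must be unit norm")
  }
  M <- length(mu_list)
  if (M == 1) return(mu_list[[1]])
  if (mode == "eval") {
    V <- Reduce(`+`, mu_list) / M
  } else {
    n <- nrow(mu_list[[1]]); d <- ncol(mu_list[[1]])
    mask <- with_seed_or_not(seed, matrix(sample.int(M, n * d, replace = TRUE), n, d))
    V <- mu_list[[1]]
    for (m in 2:M) {
      sel <- mask == m
      V[sel] <- mu_list[[m]][sel]
    }
  }
  .normalize_rows(V, fallback = mu_list[[1]])
}

# ---- training steps --------------------------------------------------------

# Discriminator update: maximize the modality and batch discriminator
# objectives, i.e. minimize their cross-entropies. Returns gradients for
# disc_params only.
.train_step_disc <- function(state, params, disc_params, Yb, batch_idx) {
  mods <- state$modalities
  mu <- lapply(mods, function(m) {
    .l2norm_forward(.nn_block_forward(params$enc[[m]], Yb[[m]])$out)$out
  })
  grads <- .tree_zero(disc_params)
  ce_mod <- 0
  for (m in seq_along(mods)) {
    fw <- .nn_block_forward(disc_params$mod, mu[[m]])
    ce <- .softmax_ce_grad(fw$out, rep(m, nrow(mu[[m]])))
    ce_mod <- ce_mod + ce$ce
    bk <- .nn_block_backward(disc_params$mod, fw$cache, ce$dlogits)
    grads$mod <- .tree_add(grads$mod, bk$grads)
  }
  ce_batch <- 0
  if (state$n_batches > 1) {
    for (m in seq_along(mods)) {
      fw <- .nn_block_forward(disc_params$batch, mu[[m]])
      ce <- .softmax_ce_grad(fw$out, batch_idx)
      ce_batch <- ce_batch + ce$ce
      bk <- .nn_block_backward(disc_params$batch, fw$cache, ce$dlogits)
      grads$batch <- .tree_add(grads$batch, bk$grads)
    }
  }
  list(grads = grads, ce_mod = ce_mod, ce_batch = ce_batch)
}

# Encoder/decoder update. Computes the full objective
#   KL + recon NLL (+ count NLL) + w_c * clip + w_m * L_D + w_a * align + w_b * L_B
# and its gradients with respect to `params`. `noise` (merge mask, Beta
# quantile, subsphere draw) is drawn from the current RNG when NULL and
# returned, so a step can be replayed exactly (used by the
# finite-difference gradient tests). mu receives the full pathwise gradient
# through the Householder reflection; kappa receives the closed-form KL
# gradient plus the pathwise sampling gradient obtained by implicit
# reparameterization of the Beta marginal (the quantile is held fixed and
# du/dalpha = -(dF/dalpha)/f is evaluated at the drawn point).
.train_step_enc <- function(state, params, disc_params, Yb, Xb, batch_idx, noise = NULL,
                            kl_weight = 1) {
  cfg <- state$config
  mods <- state$modalities
  M <- length(mods)
  d <- cfg$latent_dim
  n <- nrow(Yb[[1]])
  w <- cfg$loss_weights

  # encoders -> unit directions
  enc_fw <- list(); enc_l2 <- list(); mu <- list()
  for (m in mods) {
    enc_fw[[m]] <- .nn_block_forward(params$enc[[m]], Yb[[m]])
    enc_l2[[m]] <- .l2norm_forward(enc_fw[[m]]$out)
    mu[[m]] <- enc_l2[[m]]$out
  }

  # concentration
  kfw <- .nn_block_forward(params$kappa, do.call(cbind, Yb))
  a_k <- drop(kfw$out)
  kappa <- pmin(.softplus(a_k) + 1e-4, .KAPPA_MAX)

  # merged direction (training-mode dropout merge)
  if (is.null(noise)) {
    noise <- list(mask = matrix(sample.int(M, n * d, replace = TRUE), n, d))
  }
  V <- mu[[1]]
  if (M > 1) {
    for (m in 2:M) {
      sel <- noise$mask == m
      V[sel] <- mu[[mods[m]]][sel]
    }
  }
  ml2 <- .l2norm_forward(V)
  muhat <- ml2$out

  # one posterior sample per cell (Beta marginal along muhat + uniform
  # subsphere, assembled by Householder reflection)
  beta0 <- (d - 1) / 2
  alpha <- beta0 + kappa
  if (is.null(noise$q)) {
    u_raw <- stats::rbeta(n, alpha, beta0)
    noise$q <- stats::pbeta(u_raw, alpha, beta0)
    if (is.null(noise$vdir)) {
      if (d == 2) {
        noise$vdir <- matrix(sample(c(-1, 1), n, replace = TRUE), n, 1)
      } else {
        noise$vdir <- .normalize_rows(matrix(stats::rnorm(n * (d - 1)), n, d - 1))
      }
    }
  }
  u_beta <- pmin(pmax(stats::qbeta(noise$q, alpha, beta0), 1e-12), 1 - 1e-12)
  t_marg <- 2 * u_beta - 1
  s_marg <- pmax(sqrt(pmax(1 - t_marg^2, 0)), 1e-8)
  y <- cbind(t_marg, s_marg * noise$vdir)
  dimnames(y) <- NULL
  wv <- -muhat
  wv[, 1] <- wv[, 1] + 1
  nw <- sqrt(rowSums(wv^2))
  degen <- nw < 1e-12
  U <- wv
  U[!degen, ] <- wv[!degen, , drop = FALSE] / nw[!degen]
  s <- rowSums(U * y)
  Z <- y - 2 * U * s
  Z[degen, ] <- y[degen, , drop = FALSE]

  grads <- .tree_zero(params)

  # low-dimensional decoders + optional count decoders
  dec_fw <- list(); dyhat <- list()
  recon <- 0
  for (m in mods) {
    dec_fw[[m]] <- .nn_block_forward(params$dec[[m]], Z)
    resid <- dec_fw[[m]]$out - Yb[[m]]
    recon <- recon + 0.5 * sum(resid^2) / n
    dyhat[[m]] <- resid / n
  }

  count_nll <- 0
  if (cfg$use_count_decoders && length(Xb) > 0) {
    for (m in names(Xb)) {
      ci <- state$count_info[[m]]
      cfw <- .nn_block_forward(params$cnt[[m]], dec_fw[[m]]$out)
      logits <- cfw$out
      if (ci$kind == "atac") {
        xb <- Xb[[m]] # already binarized by fit()
        pr <- stats::plogis(logits)
        pr <- pmin(pmax(pr, 1e-8), 1 - 1e-8)
        count_nll <- count_nll - sum(xb * log(pr) + (1 - xb) * log1p(-pr)) / n
        dlogits <- (pr - xb) / n
      } else {
        x <- Xb[[m]]
        lib <- pmax(rowSums(x), 1)
        lse <- .logsumexp_rows(logits)
        P <- exp(logits - lse)
        mu_nb <- pmax(P * lib, 1e-10)
        sigma <- .softplus(params$sigma_raw[[m]]) + 1e-4
        sig_row <- rep(sigma, each = n)
        ll <- lgamma(x + sig_row) - lgamma(sig_row) - lgamma(x + 1) +
          sig_row * log(sig_row / (sig_row + mu_nb)) + x * log(mu_nb / (sig_row + mu_nb))
        count_nll <- count_nll - sum(ll) / n
        dmean <- -.nb_grad_mean(x, mu_nb, sig_row) / n
        a <- dmean * lib # chain through mean = P * lib
        dlogits <- P * (a - rowSums(P * a))
        dsig <- -.nb_grad_sigma(x, mu_nb, sigma) / n
        grads$sigma_raw[[m]] <- dsig * .softplus_grad(params$sigma_raw[[m]])
      }
      bk_cnt <- .nn_block_backward(params$cnt[[m]], cfw$cache, dlogits)
      grads$cnt[[m]] <- bk_cnt$grads
      dyhat[[m]] <- dyhat[[m]] + bk_cnt$dX
    }
  }

  # KL to the uniform prior
  klv <- kl_ps_uniform(kappa, d)
  kl <- mean(klv)

  # contrastive + alignment + adversarial terms accumulate into dmu
  dmu <- lapply(mu, function(m) m * 0)
  tau <- exp(min(max(params$log_tau, log(1e-3)), log(100)))
  clip_total <- 0
  dlogtau <- 0
  align <- 0
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      mi <- mods[i]; mj <- mods[j]
      cg <- .clip_loss_grad(mu[[mi]], mu[[mj]], tau)
      clip_total <- clip_total + cg$loss
      dmu[[mi]] <- dmu[[mi]] + w[["contrastive"]] * cg$dA
      dmu[[mj]] <- dmu[[mj]] + w[["contrastive"]] * cg$dB
      dlogtau <- dlogtau + w[["contrastive"]] * cg$dlogtau
      align <- align - mean(rowSums(mu[[mi]] * mu[[mj]]))
      dmu[[mi]] <- dmu[[mi]] - w[["align"]] * mu[[mj]] / n
      dmu[[mj]] <- dmu[[mj]] - w[["align"]] * mu[[mi]] / n
    }
  }
  grads$log_tau <- dlogtau

  # adversarial terms (discriminators fixed; encoders minimize +L_D, +L_B)
  L_D <- 0
  for (m in seq_len(M)) {
    fw <- .nn_block_forward(disc_params$mod, mu[[mods[m]]])
    lse <- .logsumexp_rows(fw$out)
    L_D <- L_D + mean(fw$out[, m] - lse)
    if (w[["modality_disc"]] > 0) {
      P <- exp(fw$out - lse)
      dlg <- -P / n
      dlg[, m] <- dlg[, m] + 1 / n # d(mean log p_m)/dlogits
      bk <- .nn_block_backward(disc_params$mod, fw$cache, dlg)
      dmu[[mods[m]]] <- dmu[[mods[m]]] + w[["modality_disc"]] * bk$dX
    }
  }
  L_B <- 0
  if (state$n_batches > 1) {
    idx <- cbind(seq_len(n), batch_idx)
    for (m in seq_len(M)) {
      fw <- .nn_block_forward(disc_params$batch, mu[[mods[m]]])
      lse <- .logsumexp_rows(fw$out)
      L_B <- L_B + mean(fw$out[idx] - lse)
      if (w[["batch_disc"]] > 0) {
        P <- exp(fw$out - lse)
        dlg <- -P / n
        dlg[idx] <- dlg[idx] + 1 / n
        bk <- .nn_block_backward(disc_params$batch, fw$cache, dlg)
        dmu[[mods[m]]] <- dmu[[mods[m]]] + w[["batch_disc"]] * bk$dX
      }
    }
  }

  # backward: decoders -> z
  dZ <- matrix(0, n, d)
  for (m in mods) {
    bk <- .nn_block_backward(params$dec[[m]], dec_fw[[m]]$cache, dyhat[[m]])
    grads$dec[[m]] <- bk$grads
    dZ <- dZ + bk$dX
  }

  # z -> merged direction through the Householder reflection (y fixed)
  gu <- rowSums(dZ * U)
  dU <- -2 * (s * dZ + gu * y)
  udU <- rowSums(U * dU)
  dW <- (dU - U * udU) / nw
  dmuhat <- -dW
  dmuhat[degen, ] <- 0

  # merged direction -> per-modality directions through mask
  dV <- .l2norm_backward(ml2$cache, dmuhat)
  if (M == 1) {
    dmu[[mods[1]]] <- dmu[[mods[1]]] + dV
  } else {
    for (m in seq_len(M)) {
      sel <- noise$mask == m
      tmp <- dmu[[mods[m]]]
      tmp[sel] <- tmp[sel] + dV[sel]
      dmu[[mods[m]]] <- tmp
    }
  }

  # kappa: closed-form KL gradient plus the pathwise sampling gradient
  # (implicit reparameterization of the Beta marginal at fixed quantile)
  hg <- dZ - 2 * U * rowSums(U * dZ) # Householder is symmetric: H' dZ
  hg[degen, ] <- dZ[degen, , drop = FALSE]
  dt <- hg[, 1] - (t_marg / s_marg) * rowSums(hg[, -1, drop = FALSE] * noise$vdir)
  h_fd <- pmax(1e-5 * alpha, 1e-5)
  dFda <- (stats::pbeta(u_beta, alpha + h_fd, beta0) -
             stats::pbeta(u_beta, alpha - h_fd, beta0)) / (2 * h_fd)
  dens <- stats::dbeta(u_beta, alpha, beta0)
  du_dk <- ifelse(dens > 1e-12, -dFda / dens, 0)
  dkap <- kl_weight * .kl_grad_kappa(kappa, d) / n + 2 * dt * du_dk
  da_k <- dkap * .softplus_grad(a_k)
  da_k[kappa >= .KAPPA_MAX] <- 0
  grads$kappa <- .nn_block_backward(params$kappa, kfw$cache, matrix(da_k, n, 1))$grads

  # per-modality directions -> encoder parameters
  for (m in mods) {
    dpre <- .l2norm_backward(enc_l2[[m]]$cache, dmu[[m]])
    grads$enc[[m]] <- .nn_block_backward(params$enc[[m]], enc_fw[[m]]$cache, dpre)$grads
  }

  total <- kl_weight * kl + recon + count_nll + w[["contrastive"]] * clip_total +
    w[["modality_disc"]] * L_D + w[["align"]] * align + w[["batch_disc"]] * L_B
  metrics <- c(kl = kl, recon = recon, count_nll = count_nll, clip = clip_total,
               align = align, disc_mod = L_D, disc_batch = L_B, total = total)
  list(grads = grads, metrics = metrics, loss = total, noise = noise,
       kappa = kappa, mu = mu)
}

#' Fit the co-embedding model on a paired (bridge) dataset
#'
#' Trains the model on modalities measured in the same cells. Per
#' minibatch, one discriminator update (maximizing the modality/batch
#' discriminator objectives) is followed by one encoder/decoder update
#' (minimizing the full objective). Fully deterministic given
#' `config$seed`.
#'
#' @param embeddings Named list of 2 or 3 [embedding_set()] objects with
#'   identical cell ids in identical order.
#' @param counts Optional named list of [count_set()] objects (names must be
#'   a subset of the modality names) used when
#'   `config$use_count_decoders = TRUE`.
#' @param config A [model_config()].
#' @param verbose Print per-epoch progress.
#' @return A trained `spherepair_model`; `$history` holds the per-epoch
#'   loss table (see [write_training_log()]).
#' @export
fit_spherepair <- function(embeddings, counts = NULL, config = model_config(),
                           verbose = FALSE) {
  if (!is.list(embeddings) || !length(embeddings) %in% c(2L, 3L)) {
    stop_value("embeddings must be a named list of 2 or 3 embedding_set objects")
  }
  if (is.null(names(embeddings)) || anyDuplicated(names(embeddings))) {
    nm <- vapply(embeddings, function(e) e$modality, character(1))
    if (anyDuplicated(nm)) stop_value("modalities must have unique names")
    names(embeddings) <- nm
  }
  for (e in embeddings) {
    if (!inherits(e, "embedding_set")) stop_value("each modality must be an embedding_set")
  }
  ids <- embeddings[[1]]$cell_ids
  for (e in embeddings[-1]) {
    if (!identical(e$cell_ids, ids)) {
      stop_value("all modalities must share identical cell ids in identical order (paired data)")
    }
  }
  batch <- embeddings[[1]]$batch
  C <- length(ids)
  input_dims <- vapply(embeddings, function(e) ncol(e$matrix), integer(1))
  count_info <- list()
  if (!is.null(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(embeddings))) {
      stop_value("counts must be named by modality")
    }
    for (m in names(counts)) {
      cs <- counts[[m]]
      if (!inherits(cs, "count_set")) stop_value("counts entries must be count_set objects")
      if (nrow(cs$matrix) != C) stop_shape("counts for '%s' have %d cells, expected %d", m, nrow(cs$matrix), C)
      count_info[[m]] <- list(kind = cs$kind, n_features = ncol(cs$matrix))
    }
  }
  batch_levels <- levels(batch)
  n_batches <- length(batch_levels)
  batch_idx_all <- as.integer(batch)
  mb <- min(config$minibatch_size, C)

  withr::with_seed(config$seed, {
    state <- .init_state(input_dims, count_info, n_batches, batch_levels, config)
    if (length(count_info) > 0) {
      state$libsize_ref <- vapply(names(count_info), function(m) {
        stats::median(rowSums(counts[[m]]$matrix))
      }, numeric(1))
    }
    if (config$n_epochs == 0) {
      state
    } else {
    # pre-binarize ATAC counts once
    Xall <- NULL
    if (config$use_count_decoders && length(count_info) > 0) {
      Xall <- lapply(names(count_info), function(m) {
        if (count_info[[m]]$kind == "atac") binarize_counts(counts[[m]]) else counts[[m]]$matrix
      })
      names(Xall) <- names(count_info)
    }
    params <- state$params
    disc_params <- state$disc_params
    opt_enc <- .adam_init(params)
    opt_disc <- .adam_init(disc_params)
    wd <- if (config$decay_mode == "weight_decay") config$weight_decay else 0
    step <- 0L
    # KL warm-up: anneal the KL weight linearly over the first half of
    # training so the decoders learn to use the latent before the rate
    # penalty acts (guards against posterior collapse of kappa)
    total_steps <- config$n_epochs * ceiling(C / mb)
    warmup_steps <- max(1, floor(0.5 * total_steps))
    hist <- vector("list", config$n_epochs)
    for (epoch in seq_len(config$n_epochs)) {
      perm <- sample.int(C)
      chunks <- split(perm, ceiling(seq_along(perm) / mb))
      acc <- NULL; acc_n <- 0
      for (b in chunks) {
        if (length(b) < 2) next
        Yb <- lapply(embeddings, function(e) e$matrix[b, , drop = FALSE])
        Xb <- if (!is.null(Xall)) lapply(Xall, function(x) x[b, , drop = FALSE]) else list()
        bidx <- batch_idx_all[b]
        lr_t <- if (config$decay_mode == "lr_schedule") {
          config$learning_rate / (1 + config$weight_decay * step)
        } else config$learning_rate

        dres <- .train_step_disc(state, params, disc_params, Yb, bidx)
        if (!is.finite(dres$ce_mod) || !is.finite(dres$ce_batch)) {
          stop_numeric("non-finite discriminator loss (modality CE = %g, batch CE = %g)",
                       dres$ce_mod, dres$ce_batch)
        }
        st <- .adam_step(disc_params, dres$grads, opt_disc, lr_t, wd)
        disc_params <- st$params; opt_disc <- st$opt

        eres <- .train_step_enc(state, params, disc_params, Yb, Xb, bidx,
                                kl_weight = min(1, (step + 1) / warmup_steps))
        bad <- names(eres$metrics)[!is.finite(eres$metrics)]
        if (length(bad) > 0) {
          stop_numeric("non-finite loss term(s): %s", paste(bad, collapse = ", "))
        }
        if (!.tree_finite(eres$grads)) stop_numeric("non-finite gradient in encoder/decoder update")
        st <- .adam_step(params, eres$grads, opt_enc, lr_t, wd)
        params <- st$params; opt_enc <- st$opt
        params$log_tau <- min(max(params$log_tau, log(1e-3)), log(100))
        step <- step + 1L

        met <- c(eres$metrics, disc_ce_mod = dres$ce_mod, disc_ce_batch = dres$ce_batch)
        acc <- if (is.null(acc)) met * length(b) else acc + met * length(b)
        acc_n <- acc_n + length(b)
      }
      hist[[epoch]] <- c(epoch = epoch, acc / acc_n)
      .log_msg(verbose, "epoch %d/%d: total = %.4f, clip = %.4f, kl = %.4f",
               epoch, config$n_epochs, (acc / acc_n)[["total"]], (acc / acc_n)[["clip"]],
               (acc / acc_n)[["kl"]])
    }
    state$params <- params
    state$disc_params <- disc_params
    state$trained <- TRUE
    state$history <- as.data.frame(do.call(rbind, hist))
    state
    }
  })
}

#' Project a single modality onto the trained hypersphere
#'
#' Applies the trained encoder of one modality to (possibly unimodal,
#' held-out) data. No other modality is required; kappa is not computed.
#'
#' @inheritParams encode
#' @return A cells x latent_dim matrix of unit directions.
#' @export
project <- function(state, Y, modality) {
  .check_model(state)
  if (!isTRUE(state$trained)) stop_state("model is untrained; fit it before projecting")
  encode(state, Y, modality)
}

#' Cross-modal imputation
#'
#' Uses the source modality's direction as the merged latent direction and
#' applies the target modality's decoder(s). Low-dimensional output is
#' always available; count output requires trained count decoders or, with
#' `use_pretrained_decoders`, a caller-supplied `reconstructor` that maps a
#' cells x r_target matrix of reconstructed representations to a
#' cells x features matrix.
#'
#' @param state A trained `spherepair_model`.
#' @param Y_source Source-modality embeddings.
#' @param source_modality,target_modality Modality names.
#' @param what `"lowdim"` (reconstructed representation) or `"counts"`.
#' @param reconstructor Optional function for pre-trained decoder hooks.
#' @return A matrix: reconstructed representations, NB means (RNA-like) or
#'   Bernoulli probabilities (ATAC).
#' @export
impute <- function(state, Y_source, source_modality, target_modality,
                   what = c("lowdim", "counts"), reconstructor = NULL) {
  what <- match.arg(what)
  .check_model(state)
  if (!isTRUE(state$trained)) stop_state("model is untrained; fit it before imputing")
  if (!target_modality %in% state$modalities) {
    stop_value("unknown target modality '%s'", target_modality)
  }
  mu <- project(state, Y_source, source_modality)
  yhat <- .nn_block_forward(state$params$dec[[target_modality]], mu)$out
  rownames(yhat) <- rownames(mu)
  if (what == "lowdim") return(yhat)
  if (state$config$use_pretrained_decoders) {
    if (is.null(reconstructor)) {
      stop_config("use_pretrained_decoders is set: supply a reconstructor function")
    }
    return(reconstructor(yhat))
  }
  if (!state$config$use_count_decoders || !target_modality %in% names(state$params$cnt)) {
    stop_config("count imputation needs trained count decoders for '%s' or an external reconstructor",
                target_modality)
  }
  ci <- state$count_info[[target_modality]]
  logits <- .nn_block_forward(state$params$cnt[[target_modality]], yhat)$out
  out <- if (ci$kind == "atac") {
    stats::plogis(logits)
  } else {
    lse <- .logsumexp_rows(logits)
    exp(logits - lse) * state$libsize_ref[[target_modality]]
  }
  rownames(out) <- rownames(mu)
  out
}

#' Evidence lower bound components on paired data
#'
#' Evaluates the model in evaluation mode (deterministic coordinate-mean
#' merge, one Power Spherical sample per cell) and returns the per-cell KL
#' term, per-modality Gaussian reconstruction log-likelihoods (unit
#' variance, constants included), optional count log-likelihoods, and the
#' assembled per-cell ELBO.
#'
#' @param state A `spherepair_model`.
#' @param embeddings Named list of paired [embedding_set()] objects.
#' @param counts Optional named list of [count_set()] objects.
#' @param seed Seed for the single posterior sample.
#' @return List with `elbo` (mean scalar), `per_cell`, and `components`
#'   (`kl`, `recon`, `counts`, each per cell).
#' @export
elbo_components <- function(state, embeddings, counts = NULL, seed = NULL) {
  .check_model(state)
  mods <- state$modalities
  Y <- lapply(embeddings[mods], .as_embedding_matrix)
  mu <- lapply(mods, function(m) encode(state, Y[[m]], m))
  names(mu) <- mods
  kappa <- compute_kappa(state, Y)
  muhat <- merge_directions(mu, mode = "eval")
  n <- nrow(muhat); d <- state$config$latent_dim
  Z <- with_seed_or_not(seed, {
    drawn <- .ps_draw_noise(n, d, kappa)
    .ps_transform(drawn$y, muhat)
  })
  klv <- kl_ps_uniform(kappa, d)
  recon <- list()
  for (m in mods) {
    yhat <- .nn_block_forward(state$params$dec[[m]], Z)$out
    r <- ncol(Y[[m]])
    recon[[m]] <- -0.5 * rowSums((Y[[m]] - yhat)^2) - 0.5 * r * log(2 * pi)
  }
  cll <- list()
  if (!is.null(counts) && state$config$use_count_decoders) {
    for (m in intersect(names(counts), names(state$params$cnt))) {
      yhat <- .nn_block_forward(state$params$dec[[m]], Z)$out
      logits <- .nn_block_forward(state$params$cnt[[m]], yhat)$out
      ci <- state$count_info[[m]]
      if (ci$kind == "atac") {
        cll[[m]] <- bernoulli_log_likelihood(binarize_counts(counts[[m]]), stats::plogis(logits))
      } else {
        x <- counts[[m]]$matrix
        lib <- pmax(rowSums(x), 1)
        P <- exp(logits - .logsumexp_rows(logits))
        sigma <- .softplus(state$params$sigma_raw[[m]]) + 1e-4
        cll[[m]] <- nb_log_likelihood(x, pmax(P * lib, 1e-10), sigma)
      }
    }
  }
  per_cell <- -klv + Reduce(`+`, recon) + if (length(cll) > 0) Reduce(`+`, cll) else 0
  list(elbo = mean(per_cell), per_cell = per_cell,
       components = list(kl = klv, recon = recon, counts = cll))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive of all parameter tensors, the
#' configuration and the modality input dimensions; a load round-trip
#' restores an identical object.
#'
#' @param state A `spherepair_model`.
#' @param path File path.
#' @return `load_model` returns the restored model.
#' @export
save_model <- function(state, path) {
  .check_model(state)
  saveRDS(list(format = "spherepair_checkpoint", version = 1L, model = state), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "spherepair_checkpoint")) {
    stop_format("'%s' is not a model checkpoint", path)
  }
  obj$model
}

#' Write the per-epoch training log as delimited text
#'
#' @param state A trained `spherepair_model`.
#' @param path Output TSV path.
#' @export
write_training_log <- function(state, path) {
  .check_model(state)
  if (is.null(state$history)) stop_state("model has no training history")
  utils::write.table(state$history, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
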