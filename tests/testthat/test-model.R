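test_that("encoders produce unit directions deterministically", {
  fx <- get_tiny_state()
  mu <- encode(fx$state, fx$Y1, "rna")
  expect_true(all(abs(sqrt(rowSums(mu^2)) - 1) < 1e-10))
  expect_identical(mu, encode(fx$state, fx$Y1, "rna"))
  # identical input rows give identical outputs
  Ydup <- fx$Y1[c(1, 1, 2), ]
  mud <- encode(fx$state, Ydup, "rna")
  expect_equal(mud[1, ], mud[2, ], tolerance = 1e-14)
  # dimension mismatch names the modality
  expect_error(encode(fx$state, fx$Y2, "rna"), "rna", class = "spherepair_shape_error")
})

test_that("kappa head is positive, deterministic, and needs all modalities", {
  fx <- get_tiny_state()
  k <- compute_kappa(fx$state, list(rna = fx$Y1, atac = fx$Y2))
  expect_true(all(k > 0 & is.finite(k)))
  Yd1 <- fx$Y1[c(3, 3), ]; Yd2 <- fx$Y2[c(3, 3), ]
  kd <- compute_kappa(fx$state, list(rna = Yd1, atac = Yd2))
  expect_equal(kd[1], kd[2], tolerance = 1e-14, ignore_attr = TRUE)
  expect_error(compute_kappa(fx$state, list(rna = fx$Y1)),
               class = "spherepair_unsupported_error")
})

test_that("direction merging: identical inputs, selection property, eval mean", {
  A <- runif_sphere(6, 5, seed = 50)
  expect_equal(merge_directions(list(A, A), mode = "train", seed = 1), A, tolerance = 1e-12)
  expect_equal(merge_directions(list(A, A), mode = "eval"), A, tolerance = 1e-12)

  # +-0.5 construction: every coordinate comes from one input at that index
  m1 <- matrix(0.5, 4, 4)
  m2 <- matrix(rep(c(0.5, -0.5, 0.5, -0.5), 4), 4, 4, byrow = TRUE)
  out <- merge_directions(list(m1, m2), mode = "train", seed = 2)
  for (i in 1:4) for (j in 1:4) {
    expect_true(abs(out[i, j] - m1[i, j]) < 1e-12 || abs(out[i, j] - m2[i, j]) < 1e-12)
  }

  # eval mode with orthogonal basis vectors: (e1 + e2)/sqrt(2)
  e1 <- matrix(c(1, 0, 0, 0), 1); e2 <- matrix(c(0, 1, 0, 0), 1)
  expect_equal(merge_directions(list(e1, e2), mode = "eval"),
               matrix(c(1, 1, 0, 0) / sqrt(2), 1), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(60)
  n <- 10; Y1 <- matrix(rnorm(n * 5), n, 5); Y2 <- matrix(rnorm(n * 6), n, 6)
  rownames(Y1) <- rownames(Y2) <- sprintf("c%d", 1:n)
  X1 <- matrix(rpois(n * 7, 5), n, 7); X2 <- matrix(rbinom(n * 8, 1, .3), n, 8)
  batch <- rep(c("u", "v"), 5)
  emb <- list(rna = embedding_set(Y1, batch = batch, modality = "rna"),
              atac = embedding_set(Y2, batch = batch, modality = "atac"))
  cs <- list(rna = count_set(X1, kind = "rna"), atac = count_set(X2, kind = "atac"))
  st <- fit_spherepair(emb, counts = cs,
                       config = model_config(latent_dim = 4, hidden_units = 8,
                                             minibatch_size = n, n_epochs = 0, seed = 3,
                                             use_count_decoders = TRUE))
  Yb <- list(rna = Y1, atac = Y2); Xb <- list(rna = X1, atac = (X2 >= 1) * 1)
  bidx <- rep(c(1L, 2L), 5)
  set.seed(61)
  res <- spherepair:::.train_step_enc(st, st$params, st$disc_params, Yb, Xb, bidx)
  f <- function(p) spherepair:::.train_step_enc(st, p, st$disc_params, Yb, Xb, bidx,
                                                noise = res$noise)$loss
  eps <- 1e-6
  cases <- list(c("enc", "rna", "W1"), c("enc", "atac", "W2"), c("kappa", "W1"),
                c("kappa", "b2"), c("dec", "rna", "W2"), c("dec", "atac", "b1"),
                c("cnt", "rna", "W2"), c("cnt", "atac", "W1"), c("sigma_raw", "rna"),
                c("enc", "rna", "gamma"), c("dec", "atac", "beta"))
  for (keys in cases) {
    g <- res$grads; for (k in keys) g <- g[[k]]
    idx <- min(3, length(g))
    bump <- function(p, delta) {
      if (length(keys) == 2) p[[keys[1]]][[keys[2]]][idx] <- p[[keys[1]]][[keys[2]]][idx] + delta
      else p[[keys[1]]][[keys[2]]][[keys[3]]][idx] <- p[[keys[1]]][[keys[2]]][[keys[3]]][idx] + delta
      p
    }
    fd <- (f(bump(st$params, eps)) - f(bump(st$params, -eps))) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-4,
                 label = sprintf("analytic gradient for %s", paste(keys, collapse = "$")))
  }
  p1 <- st$params; p1$log_tau <- p1$log_tau + eps
  p2 <- st$params; p2$log_tau <- p2$log_tau - eps
  expect_equal(res$grads$log_tau, (f(p1) - f(p2)) / (2 * eps), tolerance = 1e-4)
})

test_that("losses and gradients stay finite over random minibatches", {
  fx <- get_tiny_state()
  set.seed(70)
  for (r in 1:10) {
    Yb <- list(rna = matrix(rnorm(20 * 5, sd = runif(1, 0.1, 5)), 20, 5),
               atac = matrix(rnorm(20 * 6, sd = runif(1, 0.1, 5)), 20, 6))
    res <- spherepair:::.train_step_enc(fx$state, fx$state$params, fx$state$disc_params,
                                        Yb, list(), rep(c(1L, 2L), 10))
    expect_true(all(is.finite(res$metrics)))
    expect_true(spherepair:::.tree_finite(res$grads))
  }
})

test_that("zero-epoch fit returns an untrained initialized state; training is seeded", {
  set.seed(80)
  Y1 <- matrix(rnorm(200 * 8), 200, 8); Y2 <- matrix(rnorm(200 * 9), 200, 9)
  rownames(Y1) <- rownames(Y2) <- sprintf("c%03d", 1:200)
  emb <- list(rna = embedding_set(Y1, modality = "rna"),
              atac = embedding_set(Y2, modality = "atac"))
  st0a <- fit_spherepair(emb, config = model_config(latent_dim = 5, minibatch_size = 100,
                                                    n_epochs = 0, seed = 4))
  st0b <- fit_spherepair(emb, config = model_config(latent_dim = 5, minibatch_size = 100,
                                                    n_epochs = 0, seed = 4))
  expect_false(st0a$trained)
  expect_identical(st0a$params, st0b$params)
  expect_error(project(st0a, Y1, "rna"), class = "spherepair_state_error")

  cfg <- model_config(latent_dim = 5, minibatch_size = 100, n_epochs = 8, seed = 4)
  sta <- fit_spherepair(emb, config = cfg)
  stb <- fit_spherepair(emb, config = cfg)
  expect_identical(sta$history, stb$history)
  expect_identical(encode(sta, Y1, "rna"), encode(stb, Y1, "rna"))
  expect_equal(nrow(sta$history), 8)
})

test_that("paired modalities must share cell ids and order", {
  set.seed(81)
  Y1 <- matrix(rnorm(40), 10, 4); Y2 <- matrix(rnorm(40), 10, 4)
  e1 <- embedding_set(Y1, cell_ids = sprintf("a%d", 1:10), modality = "m1")
  e2 <- embedding_set(Y2, cell_ids = sprintf("b%d", 1:10), modality = "m2")
  expect_error(fit_spherepair(list(m1 = e1, m2 = e2)), "identical cell ids")
  expect_error(model_config(minibatch_size = 1), class = "spherepair_config_error")
})

test_that("training aligns modalities and concentrates the posterior", {
  fx <- get_medium_fit()
  st <- fx$model; data <- fx$data
  muR <- encode(st, data$embeddings$rna, "rna")
  muA <- encode(st, data$embeddings$atac, "atac")
  expect_gt(mean(rowSums(muR * muA)), 0.9)
  Yall <- lapply(data$embeddings, function(e) e$matrix)
  expect_gt(median(compute_kappa(st, Yall)), median(compute_kappa(fx$init, Yall)))
})

test_that("per-cell ELBO improves over initialization for nearly all cells", {
  fx <- get_medium_fit()
  e0 <- elbo_components(fx$init, fx$data$embeddings, seed = 42)
  e1 <- elbo_components(fx$model, fx$data$embeddings, seed = 42)
  expect_gte(mean(e1$per_cell > e0$per_cell), 0.95)
  # bookkeeping identity: elbo decomposes exactly into its parts
  manual <- -e1$components$kl + Reduce(`+`, e1$components$recon)
  expect_equal(e1$per_cell, manual, tolerance = 1e-12)
  expect_equal(e1$elbo, mean(manual), tolerance = 1e-12)
})

test_that("projection matches encoding and is row-equivariant", {
  fx <- get_medium_fit()
  st <- fx$model
  Y <- fx$data$embeddings$rna
  expect_identical(project(st, Y, "rna"), encode(st, Y, "rna"))
  set.seed(90)
  p <- sample(nrow(Y$matrix))
  expect_equal(project(st, Y$matrix[p, ], "rna"),
               project(st, Y$matrix, "rna")[p, ], tolerance = 1e-14)
})

test_that("well-trained embeddings recover nearly all true partners when pairing", {
  fx <- get_medium_fit()
  st <- fx$model; data <- fx$data
  zR <- encode(st, data$embeddings$rna, "rna")
  zA <- encode(st, data$embeddings$atac, "atac")
  pr <- chunked_assign(zR, zA, epsilon = 0.1, seed = 5)
  exact <- sum(pr$pairs$source_id == pr$pairs$target_id)
  expect_gte(exact / nrow(data$embeddings$rna$matrix), 0.9)
})

test_that("self-imputation reconstructs the input representation", {
  fx <- get_medium_fit()
  yh <- impute(fx$model, fx$data$embeddings$rna, "rna", "rna")
  truth <- fx$data$embeddings$rna$matrix
  cors <- vapply(seq_len(ncol(yh)), function(j) cor(yh[, j], truth[, j]), numeric(1))
  expect_true(all(cors > 0.5))
})

test_that("count imputation: link functions and shuffle control", {
  fx <- get_count_fit()
  st <- fx$model; data <- fx$data
  xh <- impute(st, data$embeddings$atac, "atac", "rna", what = "counts")
  expect_true(all(xh > 0))
  ph <- impute(st, data$embeddings$rna, "rna", "atac", what = "counts")
  expect_true(all(ph > 0 & ph < 1))
  truth <- data$counts$rna$matrix
  sp_true <- vapply(seq_len(ncol(truth)), function(g)
    suppressWarnings(cor(xh[, g], truth[, g], method = "spearman")), numeric(1))
  set.seed(91)
  shuf <- sample(nrow(truth))
  sp_shuf <- vapply(seq_len(ncol(truth)), function(g)
    suppressWarnings(cor(xh[, g], truth[shuf, g], method = "spearman")), numeric(1))
  expect_gt(mean(sp_true, na.rm = TRUE), mean(sp_shuf, na.rm = TRUE))
})

test_that("count imputation without decoders is a configuration error; hooks work", {
  fx <- get_medium_fit()
  expect_error(impute(fx$model, fx$data$embeddings$rna, "rna", "atac", what = "counts"),
               class = "spherepair_config_error")
  # pre-trained decoder hook: the reconstructor receives cells x r_target
  st2 <- fx$model
  st2$config$use_pretrained_decoders <- TRUE
  got_dims <- NULL
  rec <- function(yhat) { got_dims <<- dim(yhat); yhat %*% matrix(1, ncol(yhat), 3) }
  out <- impute(st2, fx$data$embeddings$rna, "rna", "atac", what = "counts",
                reconstructor = rec)
  expect_equal(got_dims, c(600, ncol(fx$data$embeddings$atac$matrix)))
  expect_equal(ncol(out), 3)
  st3 <- st2
  expect_error(impute(st3, fx$data$embeddings$rna, "rna", "atac", what = "counts"),
               class = "spherepair_config_error")
})

test_that("checkpoint round-trip restores the exact model", {
  fx <- get_tiny_state()
  path <- tempfile(fileext = ".rds")
  save_model(fx$state, path)
  st2 <- load_model(path)
  expect_identical(st2$params, fx$state$params)
  expect_identical(st2$config, fx$state$config)
  expect_identical(st2$input_dims, fx$state$input_dims)
  expect_error(load_model({p <- tempfile(); saveRDS(1:3, p); p}),
               class = "spherepair_format_error")
})

test_that("three-modality model: duplicated modality collapses pairwise losses", {
  set.seed(95)
  Y1 <- matrix(rnorm(30 * 5), 30, 5)
  rownames(Y1) <- sprintf("c%d", 1:30)
  e1 <- embedding_set(Y1, modality = "m1")
  e2 <- embedding_set(Y1, modality = "m2") # identical data
  e3 <- embedding_set(matrix(rnorm(30 * 4), 30, 4, dimnames = list(rownames(Y1), NULL)),
                      cell_ids = rownames(Y1), modality = "m3")
  st <- fit_spherepair(list(m1 = e1, m2 = e2, m3 = e3),
                       config = model_config(latent_dim = 4, hidden_units = 8,
                                             minibatch_size = 30, n_epochs = 3, seed = 6))
  expect_true(st$trained)
  # encoders differ (independent init) but accept the duplicated input;
  # feeding the same data through the SAME encoder reduces the pair to its
  # identical-input values
  mu <- encode(st, Y1, "m1")
  expect_equal(clip_pair_loss(mu, mu, tau = 1), oracle_clip_loss(mu, mu, 1), tolerance = 1e-9)
  expect_equal(alignment_loss(list(mu, mu)), -1, tolerance = 1e-12)
  # a batch of identical cells at the identical-input value 2 log N
  rep_mu <- mu[rep(1, 6), ]
  expect_equal(clip_pair_loss(rep_mu, rep_mu, tau = 1), 2 * log(6), tolerance = 1e-9)
})

test_that("training history is a writable per-epoch loss table", {
  fx <- get_medium_fit()
  h <- fx$model$history
  expect_true(all(c("epoch", "kl", "recon", "clip", "align", "total") %in% names(h)))
  path <- tempfile(fileext = ".tsv")
  write_training_log(fx$model, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(h))
  expect_equal(back$total, h$total, tolerance = 1e-12)
})
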