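# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# Random unit row vectors.
runif_sphere <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# A well-separated low-noise bimodal dataset with a converged fit: used for
# the training-run assertions (alignment quality, kappa growth, ELBO
# improvement, exact partner recovery, self-imputation).
get_medium_fit <- function() {
  if (is.null(.fixtures$medium)) {
    data <- simulate_multiome(sim_config(n_cells = 600, n_types = 4, noise_sd = 0.02,
                                         count_dims = NULL, seed = 11))
    cfg <- model_config(latent_dim = 10, minibatch_size = 600, n_epochs = 100, seed = 3)
    model <- fit_spherepair(data$embeddings, config = cfg)
    init <- fit_spherepair(data$embeddings,
                           config = model_config(latent_dim = 10, minibatch_size = 600,
                                                 n_epochs = 0, seed = 3))
    .fixtures$medium <- list(data = data, model = model, init = init)
  }
  .fixtures$medium
}

# A small fit with count decoders enabled, for imputation tests.
get_count_fit <- function() {
  if (is.null(.fixtures$count)) {
    data <- simulate_multiome(sim_config(n_cells = 400, n_types = 4, noise_sd = 0.05,
                                         count_dims = c(60, 80), seed = 21))
    cfg <- model_config(latent_dim = 8, minibatch_size = 400, n_epochs = 80, seed = 9,
                        use_count_decoders = TRUE)
    model <- fit_spherepair(data$embeddings, counts = data$counts, config = cfg)
    .fixtures$count <- list(data = data, model = model)
  }
  .fixtures$count
}

# A tiny untrained state for loss/shape tests (2 batches, 2 modalities).
get_tiny_state <- function() {
  if (is.null(.fixtures$tiny)) {
    set.seed(5)
    n <- 20
    Y1 <- matrix(rnorm(n * 5), n, 5); Y2 <- matrix(rnorm(n * 6), n, 6)
    rownames(Y1) <- rownames(Y2) <- sprintf("c%02d", seq_len(n))
    batch <- rep(c("b1", "b2"), n / 2)
    emb <- list(rna = embedding_set(Y1, batch = batch, modality = "rna"),
                atac = embedding_set(Y2, batch = batch, modality = "atac"))
    st <- fit_spherepair(emb, config = model_config(latent_dim = 4, hidden_units = 8,
                                                    minibatch_size = n, n_epochs = 0, seed = 2))
    .fixtures$tiny <- list(state = st, embeddings = emb, Y1 = Y1, Y2 = Y2, batch = batch)
  }
  .fixtures$tiny
}
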