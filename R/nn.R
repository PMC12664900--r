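# Minimal dense neural-network machinery used by the model core.
#
# Every trainable component is a single hidden-layer block:
#   Linear(n_in -> n_hidden) -> LayerNorm -> ELU -> Linear(n_hidden -> n_out)
# Forward passes cache intermediates; backward passes return parameter
# gradients plus the gradient with respect to the input, so blocks compose
# by hand. Parameters/gradients are nested lists of numeric arrays and are
# updated by a hand-rolled Adam with optional L2 weight decay.

.LN_EPS <- 1e-5

.nn_init_block <- function(n_in, n_hidden, n_out) {
  list(
    W1 = matrix(stats::rnorm(n_in * n_hidden, sd = sqrt(1 / n_in)), n_in, n_hidden),
    b1 = numeric(n_hidden),
    gamma = rep(1, n_hidden),
    beta = numeric(n_hidden),
    W2 = matrix(stats::rnorm(n_hidden * n_out, sd = sqrt(1 / n_hidden)), n_hidden, n_out),
    b2 = numeric(n_out)
  )
}

.elu <- function(a) ifelse(a > 0, a, exp(pmin(a, 0)) - 1)
.elu_grad <- function(a) ifelse(a > 0, 1, exp(pmin(a, 0)))

.softplus <- function(a) log1p(exp(-abs(a))) + pmax(a, 0)
.softplus_grad <- function(a) stats::plogis(a)

.nn_block_forward <- function(p, X) {
  A1 <- X %*% p$W1
  A1 <- sweep(A1, 2, p$b1, `+`)
  m <- rowMeans(A1)
  xc <- A1 - m
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * istd
  A2 <- sweep(xhat, 2, p$gamma, `*`)
  A2 <- sweep(A2, 2, p$beta, `+`)
  H1 <- .elu(A2)
  out <- H1 %*% p$W2
  out <- sweep(out, 2, p$b2, `+`)
  list(out = out, cache = list(X = X, A2 = A2, H1 = H1, xhat = xhat, istd = istd))
}

.nn_block_backward <- function(p, cache, d_out) {
  dW2 <- crossprod(cache$H1, d_out)
  db2 <- colSums(d_out)
  dH1 <- tcrossprod(d_out, p$W2)
  dA2 <- dH1 * .elu_grad(cache$A2)
  dgamma <- colSums(dA2 * cache$xhat)
  dbeta <- colSums(dA2)
  dxhat <- sweep(dA2, 2, p$gamma, `*`)
  # LayerNorm backward (per row)
  dA1 <- cache$istd * (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  dW1 <- crossprod(cache$X, dA1)
  db1 <- colSums(dA1)
  dX <- tcrossprod(dA1, p$W1)
  list(
    grads = list(W1 = dW1, b1 = db1, gamma = dgamma, beta = dbeta, W2 = dW2, b2 = db2),
    dX = dX
  )
}

# Row-wise L2 normalization with backward pass.
.l2norm_forward <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm < 1e-12)) stop_numeric("zero-norm row before normalization")
  list(out = X / nrm, cache = list(out = X / nrm, nrm = nrm))
}

.l2norm_backward <- function(cache, d_out) {
  (d_out - cache$out * rowSums(d_out * cache$out)) / cache$nrm
}

# ---- parameter-tree utilities ----------------------------------------------

.tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) .tree_map(f, x)) else f(a)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) .tree_map2(f, x, y), a, b)
    out
  } else {
    f(a, b)
  }
}

.tree_zero <- function(a) .tree_map(function(x) x * 0, a)

.tree_add <- function(a, b) .tree_map2(`+`, a, b)

.tree_finite <- function(a) {
  ok <- TRUE
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else if (any(!is.finite(x))) ok <<- FALSE
    invisible(NULL)
  }
  walk(a)
  ok
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = .tree_zero(params), v = .tree_zero(params), t = 0L)
}

.adam_step <- function(params, grads, opt, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  if (weight_decay > 0) {
    grads <- .tree_map2(function(g, p) g + weight_decay * p, grads, params)
  }
  opt$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  c1 <- 1 / (1 - beta1^opt$t)
  c2 <- 1 / (1 - beta2^opt$t)
  upd <- .tree_map2(function(m, v) lr * (m * c1) / (sqrt(v * c2) + eps), opt$m, opt$v)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, opt = opt)
}
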