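# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed conditions so callers (and the CLI) can map failures to exit codes.
stop_shape <- function(...) {
  stop(errorCondition(sprintf(...), class = c("spherepair_shape_error", "spherepair_error")))
}

stop_value <- function(...) {
  stop(errorCondition(sprintf(...), class = c("spherepair_value_error", "spherepair_error")))
}

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("spherepair_format_error", "spherepair_error")))
}

stop_config <- function(...) {
  stop(errorCondition(sprintf(...), class = c("spherepair_config_error", "spherepair_error")))
}

stop_state <- function(...) {
  stop(errorCondition(sprintf(...), class = c("spherepair_state_error", "spherepair_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(sprintf(...), class = c("spherepair_numeric_error", "spherepair_error")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL means use (and advance) the current RNG stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_value("'%s' must be a numeric matrix", name)
  }
  if (anyNA(x)) stop_value("'%s' contains missing values", name)
  invisible(x)
}

# Row-wise L2 normalization; rows with ~zero norm trigger an error unless
# `fallback` supplies replacement rows.
.normalize_rows <- function(x, fallback = NULL) {
  nrm <- sqrt(rowSums(x^2))
  bad <- nrm < 1e-12
  if (any(bad)) {
    if (is.null(fallback)) stop_value("cannot normalize zero-norm rows")
    x[bad, ] <- fallback[bad, , drop = FALSE]
    nrm[bad] <- sqrt(rowSums(x[bad, , drop = FALSE]^2))
  }
  x / nrm
}

.is_unit_rows <- function(x, tol = 1e-6) {
  all(abs(sqrt(rowSums(x^2)) - 1) <= tol)
}

.log_msg <- function(verbose, ...) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
  }
}
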