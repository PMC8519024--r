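# Small seeded fixtures built in code; no files.

fixture_design <- function(n, p, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * p), n, p))
}

# A linear-model data set with optional signal.
fixture_linear <- function(n, p, seed = 1, beta = NULL, sigma = 1) {
  x <- fixture_design(n, p, seed)
  beta <- beta %||% numeric(p)
  y <- withr::with_seed(seed + 1000,
                        drop(x %*% beta) + sigma * rnorm(n))
  list(x = x, y = y, beta = beta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
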