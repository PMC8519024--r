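# Internal helpers shared across modules.

# Coerce a design input (matrix or data frame of numeric columns) to a
# numeric matrix, keeping dimnames.
as_design_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    bad <- !vapply(x, is.numeric, logical(1))
    if (any(bad)) {
      abort(sprintf(
        "non-numeric column(s) in `%s`: %s",
        arg, paste(names(x)[bad], collapse = ", ")
      ))
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix or data frame", arg))
  }
  storage.mode(x) <- "double"
  x
}

check_lambda <- function(lambda, several = FALSE) {
  if (!is.numeric(lambda) || length(lambda) < 1L) {
    abort("`lambda` must be numeric")
  }
  if (!several && length(lambda) != 1L) {
    abort("`lambda` must be a single value")
  }
  if (anyNA(lambda) || any(lambda < 0)) {
    abort("`lambda` must be >= 0 (Inf selects the null model)")
  }
  lambda
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1)")
  }
  alpha
}

# Derive a per-replication seed from a scenario seed and a counter, kept
# within 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483629)
}

# Run `code` under a temporary RNG seed; NULL seed means "use the current
# RNG stream".
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
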