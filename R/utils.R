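# Internal helpers shared across modules.

# Run code with a temporary RNG state so library functions never clobber the
# caller's random seed. `seed` must be a single finite integer-like value.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministically derive a child seed from a base seed and one or more
# small indices; stays below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Frobenius norm
fnorm <- function(x) sqrt(sum(x^2))

# random orthogonal K x K matrix from the current RNG stream
random_orthogonal <- function(k) {
  if (k == 1L) return(matrix(sample(c(-1, 1), 1L), 1L, 1L))
  qr_dec <- qr(matrix(stats::rnorm(k * k), k, k))
  q <- qr.Q(qr_dec)
  # fix the sign convention so Q is a deterministic function of the draw
  q %*% diag(sign(diag(qr.R(qr_dec))), k)
}
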