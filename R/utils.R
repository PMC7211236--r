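# Evaluate expr with a locally-set RNG seed; leaves the caller's RNG
# state untouched. seed = NULL means: use the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit sub-seed from a base seed and indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  for (k in idx) s <- (s * 69069 + as.double(k) * 2654435761) %% 2147483647
  as.integer(s)
}

# Random D x d matrix with orthonormal columns (Haar via QR of Gaussian).
random_orthonormal <- function(D, d) {
  orthonormalize(matrix(stats::rnorm(D * d), D, d))$Q
}

trace_of <- function(m) sum(diag(m))

is_symmetric_tol <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    norm(m - t(m), "F") <= tol * max(1, norm(m, "F"))
}
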