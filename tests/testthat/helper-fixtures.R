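# Shared fixtures and independent oracles, built in code.

# Random point on G(p, D) via QR of a Gaussian matrix.
rand_point <- function(D, p) {
  grassmann_point(orthonormalize(matrix(rnorm(D * p), D, p))$Q,
                  check = FALSE)
}

# Random p x p orthogonal matrix.
rand_rotation <- function(p) orthonormalize(matrix(rnorm(p * p), p, p))$Q

# Small labeled set with K classes of random points (no class structure).
rand_labeled_set <- function(n_per_class, K, D, p) {
  pts <- lapply(seq_len(n_per_class * K), function(i) rand_point(D, p))
  grassmann_set(pts, rep(paste0("c", seq_len(K)), each = n_per_class))
}

# Fréchet cost of a candidate mean.
frechet_cost <- function(points, m) {
  sum(vapply(points, projection_distance, numeric(1), x2 = m))
}

# Brute-force sphere-grid oracle for the p = 1 Fréchet mean: minimum
# cost over n_cand random unit vectors in R^D.
sphere_grid_min_cost <- function(points, n_cand = 1e4) {
  D <- points[[1]]$ambient_dim
  V <- matrix(rnorm(D * n_cand), D)
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  X <- do.call(cbind, lapply(points, `[[`, "basis"))  # D x n
  # cost(v) = sum_i (1 - (v . x_i)^2)
  costs <- length(points) - colSums(crossprod(X, V)^2)
  min(costs)
}

# Trace ratio of orthonormal A for a (B, Q) pencil.
trace_ratio_value <- function(A, B, Q) {
  sum(diag(crossprod(A, B %*% A))) / sum(diag(crossprod(A, Q %*% A)))
}

# Random PSD matrix of size D.
rand_psd <- function(D) {
  M <- matrix(rnorm(D * D), D)
  crossprod(M) / D
}
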