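#' Construct a point on the Grassmann manifold
#'
#' A point of the Grassmann manifold \eqn{\mathcal{G}(p, D)} is a
#' p-dimensional linear subspace of \eqn{R^D}, represented here (Stiefel
#' quotient convention) by any \eqn{D \times p} matrix with orthonormal
#' columns. Two bases that differ by right-multiplication with a
#' \eqn{p \times p} orthogonal matrix denote the same manifold point, and
#' every operation in this package is invariant to that choice.
#'
#' @param basis Numeric matrix of shape D x p with orthonormal columns.
#' @param check If `TRUE` (default), verify orthonormality within
#'   `tol` (Frobenius norm of \eqn{B^T B - I_p}).
#' @param tol Orthonormality tolerance; default `1e-8`.
#' @return An object of class `grassmann_point` with fields `basis`,
#'   `ambient_dim` and `subspace_dim`.
#' @examples
#' x <- grassmann_point(diag(4)[, 1:2])
#' x$subspace_dim
#' @export
grassmann_point <- function(basis, check = TRUE, tol = 1e-8) {
  basis <- as.matrix(basis)
  storage.mode(basis) <- "double"
  D <- nrow(basis)
  p <- ncol(basis)
  if (p < 1L || p > D) {
    stop("subspace dimension p must satisfy 1 <= p <= D (got p = ", p,
         ", D = ", D, ")", call. = FALSE)
  }
  if (check) {
    dev <- norm(crossprod(basis) - diag(p), type = "F")
    if (!is.finite(dev) || dev > tol) {
      stop("invalid Grassmann point: basis columns not orthonormal ",
           "(deviation ", format(dev), " > tol ", format(tol), ")",
           call. = FALSE)
    }
  }
  structure(
    list(basis = basis, ambient_dim = D, subspace_dim = p),
    class = "grassmann_point"
  )
}

#' @export
print.grassmann_point <- function(x, ...) {
  cat("<grassmann_point> subspace of dimension", x$subspace_dim,
      "in ambient dimension", x$ambient_dim, "\n")
  invisible(x)
}

#' Test for a Grassmann point
#' @param x Object to test.
#' @return `TRUE` if `x` is a `grassmann_point`.
#' @export
is_grassmann_point <- function(x) inherits(x, "grassmann_point")

#' Projection embedding of a subspace
#'
#' Maps a subspace with orthonormal basis \eqn{X} to its orthogonal
#' projection matrix \eqn{\Pi(X) = X X^T}, a symmetric idempotent
#' positive-semidefinite \eqn{D \times D} matrix of trace p. The
#' projector is unique per subspace (basis-rotation invariant), which is
#' what makes it a faithful embedding.
#'
#' @param x A [grassmann_point()].
#' @return A symmetric D x D projection matrix.
#' @export
project_embed <- function(x) {
  stopifnot(is_grassmann_point(x))
  tcrossprod(x$basis)
}

#' Projection metric between two subspaces
#'
#' The squared-chordal projection distance
#' \eqn{\delta_P(X_1, X_2) = \frac{1}{2} \| X_1 X_1^T - X_2 X_2^T \|_F^2},
#' computed stably as \eqn{p - \|X_1^T X_2\|_F^2}. It is symmetric,
#' nonnegative, zero exactly when both arguments span the same subspace,
#' and invariant to basis rotations of either argument. Its maximum is
#' p, attained by mutually orthogonal subspaces; for two lines (p = 1)
#' it equals \eqn{\sin^2\theta} of the angle between them. The 1/2
#' factor keeps values on the conventional scale for this metric.
#'
#' @param x1,x2 Two [grassmann_point()]s sharing ambient and subspace
#'   dimension.
#' @return Nonnegative scalar.
#' @export
projection_distance <- function(x1, x2) {
  stopifnot(is_grassmann_point(x1), is_grassmann_point(x2))
  if (x1$ambient_dim != x2$ambient_dim || x1$subspace_dim != x2$subspace_dim) {
    stop("dimension mismatch: points live on G(", x1$subspace_dim, ", ",
         x1$ambient_dim, ") and G(", x2$subspace_dim, ", ",
         x2$ambient_dim, ")", call. = FALSE)
  }
  d <- x1$subspace_dim - sum(crossprod(x1$basis, x2$basis)^2)
  max(d, 0)
}

#' Orthonormalize a full-column-rank matrix (QR with sign convention)
#'
#' Thin QR decomposition M = Q R with the diagonal of R forced
#' nonnegative, so that Q is a deterministic function of M. `span(Q)`
#' equals `span(M)`.
#'
#' @param m Real D x p matrix of full column rank.
#' @return List with `Q` (D x p, orthonormal columns) and `R` (p x p
#'   upper-triangular, nonnegative diagonal).
#' @export
orthonormalize <- function(m) {
  m <- as.matrix(m)
  p <- ncol(m)
  sv <- svd(m, nu = 0, nv = 0)$d
  rnk <- sum(sv > max(dim(m)) * .Machine$double.eps * max(sv, 0))
  if (rnk < p) {
    stop("rank-deficient matrix: numerical rank ", rnk, " < ", p,
         " columns", call. = FALSE)
  }
  qrm <- qr(m)
  Q <- qr.Q(qrm)
  R <- qr.R(qrm)
  s <- sign(diag(R))
  s[s == 0] <- 1
  Q <- sweep(Q, 2L, s, `*`)
  R <- sweep(R, 1L, s, `*`)
  list(Q = Q, R = R)
}

#' Fréchet mean of a set of subspaces under the projection metric
#'
#' The minimizer over \eqn{\mathcal{G}(p, D)} of
#' \eqn{\sum_i \delta_P(X_i, M)}. Under the projection metric it has a
#' closed form: the subspace spanned by the p largest-eigenvalue
#' eigenvectors of the summed projectors \eqn{\sum_i X_i X_i^T}. When
#' eigenvalues p and p+1 tie (within `tie_tol`, relative), the mean is
#' only defined up to the tied directions and a warning is issued; the
#' solver's eigenvector order then decides.
#'
#' @param points List of [grassmann_point()]s sharing (D, p).
#' @param tie_tol Relative tolerance for the eigenvalue-tie warning.
#' @return A [grassmann_point()].
#' @export
frechet_mean <- function(points, tie_tol = 1e-8) {
  if (length(points) == 0L) {
    stop("cannot take the Fréchet mean of an empty collection",
         call. = FALSE)
  }
  stopifnot(all(vapply(points, is_grassmann_point, logical(1))))
  D <- points[[1L]]$ambient_dim
  p <- points[[1L]]$subspace_dim
  ok <- vapply(points, function(x) {
    x$ambient_dim == D && x$subspace_dim == p
  }, logical(1))
  if (!all(ok)) stop("all points must share (D, p)", call. = FALSE)
  B <- do.call(cbind, lapply(points, `[[`, "basis"))
  S <- tcrossprod(B)  # sum of projectors
  e <- eigen(S, symmetric = TRUE)
  if (p < D) {
    gap <- e$values[p] - e$values[p + 1L]
    scale <- max(abs(e$values[1L]), 1)
    if (gap <= tie_tol * scale) {
      warning("Fréchet mean ill-defined: eigenvalues ", p, " and ",
              p + 1L, " tie within tolerance; returning solver order",
              call. = FALSE)
    }
  }
  grassmann_point(e$vectors[, seq_len(p), drop = FALSE], check = FALSE)
}

#' Labeled collection of Grassmann points
#'
#' Bundles points that share ambient and subspace dimension with class
#' labels (stored as a factor). This is the sample container consumed
#' by [fmgda()], [knn_predict()] and the experiment grid.
#'
#' @param points List of [grassmann_point()]s with common (D, p).
#' @param labels Vector of class labels, one per point; coerced to
#'   factor. Every class must have at least one member.
#' @return Object of class `grassmann_set` with fields `points`,
#'   `labels`, `ambient_dim`, `subspace_dim`.
#' @export
grassmann_set <- function(points, labels) {
  stopifnot(is.list(points), length(points) >= 1L)
  stopifnot(all(vapply(points, is_grassmann_point, logical(1))))
  if (length(labels) != length(points)) {
    stop("labels must have one entry per point", call. = FALSE)
  }
  D <- points[[1L]]$ambient_dim
  p <- points[[1L]]$subspace_dim
  ok <- vapply(points, function(x) {
    x$ambient_dim == D && x$subspace_dim == p
  }, logical(1))
  if (!all(ok)) stop("all points must share (D, p)", call. = FALSE)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  structure(
    list(points = points, labels = labels, ambient_dim = D,
         subspace_dim = p),
    class = "grassmann_set"
  )
}

#' @export
print.grassmann_set <- function(x, ...) {
  cat("<grassmann_set>", length(x$points), "points on G(",
      x$subspace_dim, ",", x$ambient_dim, "); classes:",
      paste(sprintf("%s(%d)", levels(x$labels), tabulate(x$labels)),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
length.grassmann_set <- function(x) length(x$points)

#' @export
`[.grassmann_set` <- function(x, i) {
  grassmann_set(x$points[i], x$labels[i])
}

#' Pairwise projection distances
#'
#' Projection-metric distances between all points of one set, or
#' between two sets. Computed in one blocked cross-product.
#'
#' @param x A [grassmann_set()].
#' @param y Optional second [grassmann_set()] (same (D, p)); if omitted,
#'   distances within `x`.
#' @return Numeric matrix, `length(x)` by `length(y)` (or square when
#'   `y` is omitted).
#' @export
projection_distance_matrix <- function(x, y = NULL) {
  stopifnot(inherits(x, "grassmann_set"))
  sym <- is.null(y)
  if (sym) y <- x
  stopifnot(inherits(y, "grassmann_set"))
  if (x$ambient_dim != y$ambient_dim || x$subspace_dim != y$subspace_dim) {
    stop("sets live on different Grassmannians", call. = FALSE)
  }
  p <- x$subspace_dim
  Bx <- do.call(cbind, lapply(x$points, `[[`, "basis"))
  By <- do.call(cbind, lapply(y$points, `[[`, "basis"))
  G <- crossprod(Bx, By)^2
  nx <- length(x$points)
  ny <- length(y$points)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    rows <- ((i - 1L) * p + 1L):(i * p)
    blk <- G[rows, , drop = FALSE]
    # column sums per p-column block of the query set
    s <- colSums(blk)
    out[i, ] <- p - colSums(matrix(s, nrow = p))
  }
  out[out < 0] <- 0
  if (sym) diag(out) <- 0
  out
}
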