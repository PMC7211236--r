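#' Class and global Fréchet means of a labeled Grassmann set
#'
#' Computes the projection-metric Fréchet mean of every class and of
#' the pooled sample, the subspace centroids that play the role of the
#' class means and grand mean of linear discriminant analysis.
#'
#' @param data A [grassmann_set()].
#' @return List with `class_means` (named list of [grassmann_point()]s,
#'   one per class level) and `global_mean`.
#' @export
class_frechet_means <- function(data) {
  stopifnot(inherits(data, "grassmann_set"))
  lv <- levels(data$labels)
  cm <- lapply(lv, function(k) {
    frechet_mean(data$points[data$labels == k])
  })
  names(cm) <- lv
  list(class_means = cm, global_mean = frechet_mean(data$points))
}

# QR-normalize a point against the current map A: with A^T X = Q R,
# X' = X R^{-1} satisfies A^T X' = Q (orthonormal); span(A^T X') =
# span(A^T X). Errors name the offending point.
normalize_primed <- function(basis, A, what = "point") {
  ax <- crossprod(A, basis)
  qrf <- tryCatch(orthonormalize(ax), error = function(e) {
    stop("QR normalization failed for ", what, ": ",
         conditionMessage(e), call. = FALSE)
  })
  # right-solve against upper-triangular R
  t(backsolve(qrf$R, t(basis), transpose = TRUE))
}

#' Between- and within-class scatter surrogates
#'
#' Given the current map `A_prev`, QR-normalizes every point and mean
#' (X' = X R^-1 with A^T X = QR) and accumulates the two symmetric
#' D x D surrogate matrices whose trace ratio, evaluated at
#' `A = A_prev`, equals the exact between/within distance ratio:
#' \deqn{\tilde B = \sum_k n_k B^{(k)} A A^T B^{(k)}, \quad
#'       B^{(k)} = M'^{(k)} M'^{(k)T} - M' M'^T}
#' \deqn{\tilde Q = \sum_k \sum_i w_k Q_{ik} A A^T Q_{ik}, \quad
#'       Q_{ik} = X_i'^{(k)} X_i'^{(k)T} - M'^{(k)} M'^{(k)T}}
#' with \eqn{w_k = n_k} under `weighting = "paper"` and \eqn{w_k = 1}
#' under `"uniform"`. Both outputs are explicitly symmetrized.
#'
#' @param data A [grassmann_set()].
#' @param means Output of [class_frechet_means()] for `data`.
#' @param A_prev Full-column-rank D x d matrix (the map of the previous
#'   iteration).
#' @param weighting `"paper"` (class-size factor inside the within-class
#'   double sum) or `"uniform"`.
#' @return List with symmetric D x D matrices `B` and `Q`.
#' @export
scatter_surrogates <- function(data, means, A_prev,
                               weighting = c("paper", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(data, "grassmann_set"))
  A_prev <- as.matrix(A_prev)
  lv <- levels(data$labels)
  nk <- tabulate(data$labels)
  names(nk) <- lv

  Mp <- normalize_primed(means$global_mean$basis, A_prev, "global mean")
  Mpk <- lapply(lv, function(k) {
    normalize_primed(means$class_means[[k]]$basis, A_prev,
                     paste0("class mean '", k, "'"))
  })
  names(Mpk) <- lv

  PM <- tcrossprod(Mp)           # M' M'^T (D x D, rank p)
  AM <- Mp %*% crossprod(Mp, A_prev)   # M' M'^T A, avoids D x D product

  bcols <- vector("list", length(lv))
  qcols <- vector("list", 0L)
  for (ki in seq_along(lv)) {
    k <- lv[ki]
    Mk <- Mpk[[k]]
    AMk <- Mk %*% crossprod(Mk, A_prev)       # M'(k) M'(k)^T A
    Ck <- AMk - AM                            # B(k) A
    bcols[[ki]] <- sqrt(nk[[k]]) * Ck
    wk <- if (weighting == "paper") nk[[k]] else 1
    idx <- which(data$labels == k)
    qk <- lapply(idx, function(i) {
      Xp <- normalize_primed(data$points[[i]]$basis, A_prev,
                             paste0("point ", i))
      sqrt(wk) * (Xp %*% crossprod(Xp, A_prev) - AMk)   # Q_ik A
    })
    qcols <- c(qcols, qk)
  }
  Bt <- tcrossprod(do.call(cbind, bcols))
  Qt <- tcrossprod(do.call(cbind, qcols))
  list(B = (Bt + t(Bt)) / 2, Q = (Qt + t(Qt)) / 2)
}

# Exact between/within distances at map A (QR normalization at A):
#   d_w(A) = sum_k sum_i w_k || Qx Qx^T - Qmk Qmk^T ||_F^2
#   d_b(A) = sum_k n_k || Qmk Qmk^T - Qm Qm^T ||_F^2
# where Qx is the orthonormal factor of A^T X etc.
exact_objective <- function(data, means, A, weighting = "paper") {
  lv <- levels(data$labels)
  nk <- tabulate(data$labels)
  names(nk) <- lv
  p <- data$subspace_dim
  orthof <- function(b) orthonormalize(crossprod(A, b))$Q
  Qm <- orthof(means$global_mean$basis)
  db <- 0
  dw <- 0
  for (ki in seq_along(lv)) {
    k <- lv[ki]
    Qmk <- orthof(means$class_means[[k]]$basis)
    db <- db + nk[[k]] * (2 * p - 2 * sum(crossprod(Qmk, Qm)^2))
    wk <- if (weighting == "paper") nk[[k]] else 1
    for (i in which(data$labels == k)) {
      Qx <- orthof(data$points[[i]]$basis)
      dw <- dw + wk * (2 * p - 2 * sum(crossprod(Qx, Qmk)^2))
    }
  }
  db <- max(db, 0)
  dw <- max(dw, 0)
  # dw ~ 0 with db > 0: genuinely separated (unbounded objective);
  # both ~ 0: the map collapses every point together -- worthless.
  ratio <- if (dw > 1e-12) db / dw else if (db > 1e-12) Inf else 0
  list(db = db, dw = dw, ratio = ratio)
}

#' Iterative trace-ratio solver
#'
#' Maximizes \eqn{tr(A^T B A) / tr(A^T Q A)} over matrices A with d
#' orthonormal columns by the standard fixed-point scheme: repeat
#' \eqn{\lambda \leftarrow tr(A^T B A)/tr(A^T Q A)}, then replace A by
#' the top-d eigenvectors of \eqn{B - \lambda Q}, until \eqn{\lambda}
#' stalls. The \eqn{\lambda} sequence is non-decreasing.
#'
#' @param B,Q Symmetric positive-semidefinite matrices of equal size.
#'   `Q` must not be (numerically) zero.
#' @param d Number of columns of the solution.
#' @param A0 Optional D x d starting matrix with orthonormal columns;
#'   default: first d columns of the identity.
#' @param tol Convergence tolerance on \eqn{\lambda} (default `1e-8`).
#' @param max_iter Maximum iterations (default 50).
#' @return List with `A` (D x d, orthonormal columns), `lambda` (the
#'   attained ratio) and `lambda_trace` (per-iteration values).
#' @export
solve_trace_ratio <- function(B, Q, d, A0 = NULL, tol = 1e-8,
                              max_iter = 50L) {
  if (!is_symmetric_tol(B) || !is_symmetric_tol(Q)) {
    stop("B and Q must be symmetric matrices", call. = FALSE)
  }
  D <- nrow(B)
  stopifnot(nrow(Q) == D, d >= 1L, d <= D)
  if (trace_of(Q) < 1e-12) {
    stop("degenerate trace-ratio problem: Q is numerically zero; ",
         "regularize Q (e.g. add a small ridge) before solving",
         call. = FALSE)
  }
  A <- if (is.null(A0)) diag(D)[, seq_len(d), drop = FALSE] else as.matrix(A0)
  lam_trace <- numeric(0)
  lam <- -Inf
  for (it in seq_len(max_iter)) {
    num <- trace_of(crossprod(A, B %*% A))
    den <- trace_of(crossprod(A, Q %*% A))
    if (den <= 0) den <- .Machine$double.eps
    lam_new <- num / den
    lam_trace <- c(lam_trace, lam_new)
    if (is.finite(lam) && abs(lam_new - lam) < tol) {
      lam <- lam_new
      break
    }
    lam <- lam_new
    e <- eigen(B - lam * Q, symmetric = TRUE)
    A <- e$vectors[, seq_len(d), drop = FALSE]
  }
  list(A = A, lambda = lam, lambda_trace = lam_trace)
}

#' Fit a Fréchet-mean Grassmann discriminant model
#'
#' Learns a linear map \eqn{A \in R^{D \times d}} sending points of
#' \eqn{\mathcal{G}(p, D)} to \eqn{\mathcal{G}(p, d)} so that, after
#' QR re-orthonormalization of \eqn{A^T X}, between-class projection
#' distances (class Fréchet means to the global mean) are large
#' relative to within-class distances (points to their class mean).
#' The objective \eqn{d_b(A)/d_w(A)} is maximized by alternating two
#' steps: freeze the QR normalizations at the current A and build the
#' scatter surrogates ([scatter_surrogates()]), then solve the
#' resulting trace-ratio problem ([solve_trace_ratio()]). Class means
#' are Fréchet means under the projection metric and are computed once.
#'
#' @param data A [grassmann_set()] with at least two classes (a single
#'   class is allowed but gives a zero between-class scatter).
#' @param target_dim Integer d with p <= d < D.
#' @param within_weighting `"paper"` keeps the class-size factor inside
#'   the within-class double sum; `"uniform"` drops it (the classical
#'   LDA convention). Default `"paper"`.
#' @param outer_iters Maximum alternations (default 20).
#' @param trace_ratio_iters Maximum inner trace-ratio iterations
#'   (default 50).
#' @param tol Relative change of the exact objective that stops the
#'   outer loop (default `1e-6`).
#' @param inner_tol Tolerance on \eqn{\lambda} in the inner solver
#'   (default `1e-8`).
#' @param init Initialization of the map. `"mean"` (default): the top
#'   d eigenvectors of the summed projectors \eqn{\sum_i X_i X_i^T} —
#'   deterministic and data-adaptive, so \eqn{A^T X_i} starts
#'   well-conditioned (coordinate-block starts can be near-singular
#'   when the data concentrate away from the leading coordinates, as
#'   smooth spectrogram features do). `"identity"`: first d columns of
#'   the identity. `"random"`: seeded Haar orthonormal start.
#' @param seed Seed used when `init = "random"`.
#' @return Object of class `fmgda`: the map `A`, `class_means`,
#'   `global_mean`, per-outer-iteration `objective_trace` (exact
#'   \eqn{d_b/d_w}, first entry at initialization), `db_trace`,
#'   `dw_trace`, inner `lambda_trace`s, the configuration, and
#'   `converged`. The surrogate coincides with the exact objective
#'   only at the expansion point, so the trace need not be monotone;
#'   the returned `A` is the best iterate (`best_iteration`,
#'   `objective`), which is therefore never worse than the
#'   initialization.
#' @examples
#' set.seed(1)
#' d <- gen_grassmann_classes(K = 2, n_per_class = 5, D = 8, p = 2,
#'                            noise = 0.1, seed = 1)
#' fit <- fmgda(d, target_dim = 4)
#' fit$objective_trace
#' @export
fmgda <- function(data, target_dim,
                  within_weighting = c("paper", "uniform"),
                  outer_iters = 20L, trace_ratio_iters = 50L,
                  tol = 1e-6, inner_tol = 1e-8,
                  init = c("mean", "identity", "random"), seed = NULL) {
  within_weighting <- match.arg(within_weighting)
  init <- match.arg(init)
  stopifnot(inherits(data, "grassmann_set"))
  D <- data$ambient_dim
  p <- data$subspace_dim
  d <- as.integer(target_dim)
  if (d < p || d >= D) {
    stop("target_dim must satisfy p <= d < D (p = ", p, ", D = ", D,
         ", d = ", d, ")", call. = FALSE)
  }
  stopifnot(outer_iters >= 1L, trace_ratio_iters >= 1L, tol > 0)

  means <- class_frechet_means(data)
  A <- switch(init,
    mean = {
      Ball <- do.call(cbind, lapply(data$points, `[[`, "basis"))
      eigen(tcrossprod(Ball), symmetric = TRUE)$vectors[, seq_len(d),
                                                        drop = FALSE]
    },
    identity = diag(D)[, seq_len(d), drop = FALSE],
    random = with_local_seed(seed, random_orthonormal(D, d))
  )

  obj0 <- exact_objective(data, means, A, within_weighting)
  objective_trace <- obj0$ratio
  db_trace <- obj0$db
  dw_trace <- obj0$dw
  lambda_traces <- list()
  converged <- FALSE
  guard_hit <- FALSE
  # The surrogate matches the exact objective only at the expansion
  # point, so the exact trace need not be monotone; keep the best
  # iterate seen (including the initialization).
  best_A <- A
  best_obj <- obj0$ratio
  best_iter <- 0L

  for (t in seq_len(outer_iters)) {
    S <- scatter_surrogates(data, means, A, within_weighting)
    Bt <- S$B
    Qt <- S$Q
    if (trace_of(crossprod(A, Qt %*% A)) < 1e-12) {
      # perfectly (or numerically) separated classes: ridge Q
      guard_hit <- TRUE
      trq <- trace_of(Qt)
      eps <- if (trq > 1e-12) 1e-10 * trq / D else 1e-10
      Qt <- Qt + diag(eps, D)
    }
    tr <- solve_trace_ratio(Bt, Qt, d, A0 = A, tol = inner_tol,
                            max_iter = trace_ratio_iters)
    A <- tr$A
    lambda_traces[[t]] <- tr$lambda_trace
    ob <- exact_objective(data, means, A, within_weighting)
    if (is.nan(ob$ratio)) {
      stop("non-finite objective at outer iteration ", t, call. = FALSE)
    }
    prev <- objective_trace[length(objective_trace)]
    objective_trace <- c(objective_trace, ob$ratio)
    db_trace <- c(db_trace, ob$db)
    dw_trace <- c(dw_trace, ob$dw)
    if (ob$ratio > best_obj || (is.infinite(ob$ratio) && ob$ratio > 0)) {
      best_A <- A
      best_obj <- ob$ratio
      best_iter <- t
    }
    if (!is.finite(ob$ratio)) {
      # zero within-class distance at the new map: objective unbounded
      guard_hit <- TRUE
      converged <- TRUE
      break
    }
    if (is.finite(prev) && prev > 0 &&
        abs(ob$ratio - prev) / abs(prev) < tol) {
      converged <- TRUE
      break
    }
  }
  A <- best_A

  structure(
    list(
      A = A,
      class_means = means$class_means,
      global_mean = means$global_mean,
      objective_trace = objective_trace,
      db_trace = db_trace,
      dw_trace = dw_trace,
      lambda_traces = lambda_traces,
      converged = converged,
      separability_guard = guard_hit,
      best_iteration = best_iter,
      objective = best_obj,
      config = list(
        target_dim = d, ambient_dim = D, subspace_dim = p,
        within_weighting = within_weighting,
        outer_iters = outer_iters, trace_ratio_iters = trace_ratio_iters,
        tol = tol, inner_tol = inner_tol, init = init, seed = seed
      ),
      levels = levels(data$labels),
      n = length(data)
    ),
    class = "fmgda"
  )
}

#' @export
print.fmgda <- function(x, ...) {
  cat("<fmgda> map G(", x$config$subspace_dim, ",", x$config$ambient_dim,
      ") -> G(", x$config$subspace_dim, ",", x$config$target_dim, "); ",
      length(x$levels), " classes, n = ", x$n, "\n", sep = "")
  cat("  objective d_b/d_w:", format(x$objective, digits = 6),
      "at outer iteration", x$best_iteration,
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  invisible(x)
}

#' Map Grassmann points through a fitted model
#'
#' Applies the learned map: for a point with basis X, returns the
#' orthonormal Q factor of \eqn{A^T X} as a point of
#' \eqn{\mathcal{G}(p, d)}. Basis-rotation invariant as a subspace.
#'
#' @param object A fitted [fmgda()] model.
#' @param newdata A [grassmann_point()] or [grassmann_set()] with
#'   ambient dimension matching the model.
#' @param ... Unused.
#' @return A `grassmann_point` or `grassmann_set` in ambient dimension
#'   d.
#' @export
predict.fmgda <- function(object, newdata, ...) {
  A <- object$A
  tf <- function(pt) {
    if (pt$ambient_dim != object$config$ambient_dim) {
      stop("ambient dimension mismatch: point has D = ", pt$ambient_dim,
           ", model expects ", object$config$ambient_dim, call. = FALSE)
    }
    grassmann_point(orthonormalize(crossprod(A, pt$basis))$Q,
                    check = FALSE)
  }
  if (is_grassmann_point(newdata)) return(tf(newdata))
  if (inherits(newdata, "grassmann_set")) {
    return(grassmann_set(lapply(newdata$points, tf), newdata$labels))
  }
  stop("newdata must be a grassmann_point or grassmann_set",
       call. = FALSE)
}

# Classical LDA on plain vectors: generalized eigenproblem
# S_b a = lambda S_t a with S_t = S_b + S_w (uniform within weighting).
# Test oracle for the trace-ratio machinery; not a user-facing feature.
euclidean_lda_reference <- function(x, labels, out_dim) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  mu <- colMeans(x)
  lv <- levels(labels)
  Db <- ncol(x)
  Sb <- matrix(0, Db, Db)
  Sw <- matrix(0, Db, Db)
  for (k in lv) {
    xk <- x[labels == k, , drop = FALSE]
    muk <- colMeans(xk)
    Sb <- Sb + nrow(xk) * tcrossprod(muk - mu)
    xc <- sweep(xk, 2L, muk)
    Sw <- Sw + crossprod(xc)
  }
  St <- Sb + Sw
  Sti <- tryCatch(solve(St), error = function(e) {
    warning("singular total scatter; using pseudo-inverse",
            call. = FALSE)
    MASS::ginv(St)
  })
  e <- eigen(Sti %*% Sb)
  ord <- order(Re(e$values), decreasing = TRUE)
  Re(e$vectors[, ord[seq_len(out_dim)], drop = FALSE])
}
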