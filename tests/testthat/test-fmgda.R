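test_that("class Fréchet means reduce to the points for singleton classes", {
  set.seed(21)
  pts <- lapply(1:3, function(i) rand_point(6, 2))
  s <- grassmann_set(pts, c("a", "b", "c"))
  ms <- class_frechet_means(s)
  for (k in 1:3) {
    expect_lt(projection_distance(ms$class_means[[k]], pts[[k]]), 1e-10)
  }
  # one class of identical points: class mean = global mean = the point
  s1 <- grassmann_set(rep(list(pts[[1]]), 4), rep("a", 4))
  ms1 <- class_frechet_means(s1)
  expect_lt(projection_distance(ms1$class_means[[1]], pts[[1]]), 1e-10)
  expect_lt(projection_distance(ms1$global_mean, pts[[1]]), 1e-10)
})

test_that("global mean of two orthogonal line classes beats the sphere grid", {
  set.seed(22)
  Q <- orthonormalize(matrix(rnorm(8), 4, 2))$Q
  a <- grassmann_point(Q[, 1, drop = FALSE])
  b <- grassmann_point(Q[, 2, drop = FALSE])
  s <- grassmann_set(rep(list(a, b), each = 3),
                     rep(c("a", "b"), each = 3))
  suppressWarnings(ms <- class_frechet_means(s))  # balanced tie is real
  gcost <- frechet_cost(s$points, ms$global_mean)
  expect_lte(gcost, sphere_grid_min_cost(s$points, 5000) + 1e-10)
  # the global mean lies in span(a, b)
  P <- Q %*% t(Q)
  expect_lt(norm(P %*% ms$global_mean$basis - ms$global_mean$basis, "F"),
            1e-8)
})

test_that("scatter surrogates vanish in the degenerate configurations", {
  set.seed(23)
  # every point equals its class mean -> zero within-scatter
  a <- rand_point(6, 2); b <- rand_point(6, 2)
  s <- grassmann_set(rep(list(a, b), each = 3), rep(c("a", "b"), each = 3))
  means <- class_frechet_means(s)
  A <- diag(6)[, 1:3]
  S <- scatter_surrogates(s, means, A)
  expect_lt(norm(S$Q, "F"), 1e-10)
  # a single class -> zero between-scatter
  s1 <- grassmann_set(lapply(1:4, function(i) rand_point(6, 2)),
                      rep("a", 4))
  S1 <- scatter_surrogates(s1, class_frechet_means(s1), A)
  expect_lt(norm(S1$B, "F"), 1e-10)
})

test_that("surrogate trace ratio equals the exact objective at A_prev", {
  set.seed(24)
  for (i in 1:8) {
    D <- 6; p <- sample(1:2, 1); K <- sample(2:3, 1)
    s <- rand_labeled_set(4, K, D, p)
    means <- class_frechet_means(s)
    # d > p: at d = p the target Grassmannian G(p, p) is a single
    # point and the exact ratio degenerates to 0/0
    d <- sample((p + 1):(D - 1), 1)
    A <- orthonormalize(matrix(rnorm(D * d), D, d))$Q
    for (w in c("paper", "uniform")) {
      S <- scatter_surrogates(s, means, A, weighting = w)
      sur <- trace_ratio_value(A, S$B, S$Q)
      ex <- fmgda:::exact_objective(s, means, A, w)
      expect_lt(abs(sur - ex$ratio) / ex$ratio, 1e-8)
      # numerator alone matches d_b as well
      num <- sum(diag(crossprod(A, S$B %*% A)))
      expect_lt(abs(num - ex$db) / max(ex$db, 1e-12), 1e-8)
    }
  }
})

test_that("trace-ratio solver recovers the diagonal closed form", {
  res <- solve_trace_ratio(diag(c(4, 1, 0)), diag(3), d = 1)
  expect_equal(res$lambda, 4, tolerance = 1e-12)
  expect_equal(abs(res$A[, 1]), c(1, 0, 0), tolerance = 1e-10)
  # general diagonal pencil, d = 1: optimum is max_i b_i / q_i
  b <- c(3, 7, 2, 5); q <- c(2, 4, 1, 10)
  res2 <- solve_trace_ratio(diag(b), diag(q), d = 1)
  expect_equal(res2$lambda, max(b / q), tolerance = 1e-10)
  # d = D: any orthogonal basis gives tr(B)/tr(Q)
  set.seed(25)
  B <- rand_psd(4); Q <- rand_psd(4)
  res3 <- solve_trace_ratio(B, Q, d = 4)
  expect_equal(res3$lambda, sum(diag(B)) / sum(diag(Q)), tolerance = 1e-10)
})

test_that("trace-ratio lambda sequence is non-decreasing", {
  set.seed(26)
  for (i in 1:10) {
    D <- sample(4:8, 1); d <- sample(seq_len(D - 1), 1)
    res <- solve_trace_ratio(rand_psd(D), rand_psd(D) + diag(0.1, D), d)
    expect_true(all(diff(res$lambda_trace) >= -1e-10))
  }
})

test_that("trace-ratio solver rejects degenerate or malformed input", {
  expect_error(solve_trace_ratio(diag(3), matrix(0, 3, 3), 1),
               "degenerate")
  expect_error(solve_trace_ratio(matrix(rnorm(9), 3), diag(3), 1),
               "symmetric")
})

test_that("fit with outer_iters = 1 is one surrogate plus one solve", {
  set.seed(27)
  s <- gen_grassmann_classes(K = 2, n_per_class = 5, D = 10, p = 2,
                             noise = 0.2, seed = 5)
  fit1 <- fmgda(s, target_dim = 4, outer_iters = 1, init = "identity")
  means <- class_frechet_means(s)
  A0 <- diag(10)[, 1:4]
  S <- scatter_surrogates(s, means, A0, "paper")
  manual <- solve_trace_ratio(S$B, S$Q, 4, A0 = A0)
  ob_manual <- fmgda:::exact_objective(s, means, manual$A, "paper")$ratio
  ob0 <- fmgda:::exact_objective(s, means, A0, "paper")$ratio
  # best-iterate rule: the model keeps whichever of {init, step-1} wins
  expect_equal(fit1$objective, max(ob0, ob_manual), tolerance = 1e-10)
  expect_length(fit1$lambda_traces, 1)
})

test_that("perfectly separated classes trigger the d_w guard and classify exactly", {
  set.seed(28)
  Q <- orthonormalize(matrix(rnorm(8 * 4), 8, 4))$Q
  a <- grassmann_point(Q[, 1:2]); b <- grassmann_point(Q[, 3:4])
  s <- grassmann_set(rep(list(a, b), each = 4), rep(c("a", "b"), each = 4))
  # balanced orthogonal classes: the global-mean eigenvalue tie is real
  suppressWarnings(fit <- fmgda(s, target_dim = 5))
  expect_true(fit$separability_guard)
  tr <- predict(fit, s)
  expect_equal(mean(knn_predict(tr, tr) == s$labels), 1)
})

test_that("fitted objective never falls below the initialization", {
  set.seed(29)
  s <- gen_grassmann_classes(K = 3, n_per_class = 8, D = 15, p = 2,
                             noise = 0.25, seed = 9)
  for (w in c("paper", "uniform")) {
    fit <- fmgda(s, target_dim = 6, within_weighting = w)
    expect_gte(fit$objective, fit$objective_trace[1] - 1e-10)
    expect_equal(fit$objective, max(fit$objective_trace))
  }
})

test_that("the fitted objective is invariant to label permutation", {
  set.seed(30)
  s <- gen_grassmann_classes(K = 3, n_per_class = 6, D = 12, p = 2,
                             noise = 0.2, seed = 3)
  fit0 <- fmgda(s, target_dim = 5)
  perm <- c(class_1 = "class_3", class_2 = "class_1",
            class_3 = "class_2")
  s2 <- grassmann_set(s$points, unname(perm[as.character(s$labels)]))
  fit2 <- fmgda(s2, target_dim = 5)
  expect_equal(fit0$objective, fit2$objective, tolerance = 1e-8)
  expect_equal(fit0$objective_trace, fit2$objective_trace,
               tolerance = 1e-8)
})

test_that("predict maps points to valid, rotation-invariant subspaces", {
  set.seed(31)
  s <- gen_grassmann_classes(K = 2, n_per_class = 5, D = 10, p = 2,
                             noise = 0.2, seed = 6)
  fit <- fmgda(s, target_dim = 4)
  x <- rand_point(10, 2)
  y <- predict(fit, x)
  expect_equal(y$ambient_dim, 4)
  expect_lt(norm(crossprod(y$basis) - diag(2), "F"), 1e-8)
  yr <- predict(fit, grassmann_point(x$basis %*% rand_rotation(2),
                                     check = FALSE))
  expect_lt(projection_distance(y, yr), 1e-10)
  expect_error(predict(fit, rand_point(9, 2)), "ambient dimension")
})

test_that("a coordinate-block map embeds contained subspaces unchanged", {
  # craft a model whose A is the first d columns of the identity
  D <- 6; d <- 4; p <- 2
  basis <- rbind(diag(p), matrix(0, d - p, p), matrix(0, D - d, p))
  x <- grassmann_point(basis)
  fake <- structure(list(A = diag(D)[, 1:d],
                         config = list(ambient_dim = D, target_dim = d,
                                       subspace_dim = p)),
                    class = "fmgda")
  y <- predict(fake, x)
  expect_equal(y$basis, rbind(diag(p), matrix(0, d - p, p)),
               tolerance = 1e-12)
})

test_that("the Euclidean LDA reference finds the Fisher direction", {
  set.seed(32)
  n <- 60
  x <- rbind(cbind(rnorm(n, -2, 0.5), rnorm(n, 0, 2)),
             cbind(rnorm(n, 2, 0.5), rnorm(n, 0, 2)))
  lab <- rep(c("a", "b"), each = n)
  a <- fmgda:::euclidean_lda_reference(x, lab, 1)[, 1]
  a <- a / sqrt(sum(a^2))
  # angle-grid oracle over the Rayleigh quotient
  mu <- colMeans(x); Sb <- matrix(0, 2, 2); Sw <- matrix(0, 2, 2)
  for (k in c("a", "b")) {
    xk <- x[lab == k, ]; muk <- colMeans(xk)
    Sb <- Sb + nrow(xk) * tcrossprod(muk - mu)
    Sw <- Sw + crossprod(sweep(xk, 2, muk))
  }
  St <- Sb + Sw
  ths <- seq(0, pi, length.out = 2001)
  ratio <- vapply(ths, function(t) {
    v <- c(cos(t), sin(t))
    (v %*% Sb %*% v) / (v %*% St %*% v)
  }, numeric(1))
  vbest <- c(cos(ths[which.max(ratio)]), sin(ths[which.max(ratio)]))
  expect_gt(abs(sum(a * vbest)), 0.999)
  # two well-separated classes: 1-NN on the projected line is perfect
  z <- x %*% a
  pred <- vapply(seq_len(nrow(x)), function(i) {
    lab[-i][which.min(abs(z[-i] - z[i]))]
  }, character(1))
  expect_equal(mean(pred == lab), 1)
})
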