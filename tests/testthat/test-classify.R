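test_that("1-NN returns the label of the closest training subspace", {
  set.seed(51)
  tr <- rand_labeled_set(3, 2, 5, 1)
  # query equal to a training point
  pred <- knn_predict(tr, tr$points[[4]], k = 1)
  expect_equal(as.character(pred), as.character(tr$labels[4]))
  # query strictly closer to one of two training points
  e1 <- grassmann_point(matrix(c(1, 0, 0), 3, 1))
  e2 <- grassmann_point(matrix(c(0, 1, 0), 3, 1))
  near1 <- grassmann_point(orthonormalize(matrix(c(1, 0.1, 0), 3, 1))$Q)
  tiny <- grassmann_set(list(e1, e2), c("one", "two"))
  expect_equal(as.character(knn_predict(tiny, near1)), "one")
  expect_error(knn_predict(tiny, near1, k = 3), "k")
})

test_that("k = 3 vote matches a brute-force neighbour list", {
  set.seed(52)
  angs <- c(0.05, 0.1, 0.5, 0.9, 1.2, 1.4)
  pts <- lapply(angs, function(a) {
    grassmann_point(matrix(c(cos(a), sin(a), 0), 3, 1))
  })
  labs <- c("x", "x", "x", "y", "y", "y")
  tr <- grassmann_set(pts, labs)
  for (qa in seq(0, 1.5, by = 0.11)) {
    q <- grassmann_point(matrix(c(cos(qa), sin(qa), 0), 3, 1))
    d <- vapply(pts, projection_distance, numeric(1), x2 = q)
    nb <- order(d)[1:3]
    tallies <- table(labs[nb])
    want <- names(tallies)[which.max(tallies)]
    expect_equal(as.character(knn_predict(tr, q, k = 3)), want)
  }
})

test_that("vote ties break by summed distance, then label order", {
  e1 <- grassmann_point(matrix(c(1, 0, 0), 3, 1))
  e2 <- grassmann_point(matrix(c(0, 1, 0), 3, 1))
  q <- grassmann_point(orthonormalize(matrix(c(1, 0.5, 0), 3, 1))$Q)
  tr <- grassmann_set(list(e1, e2), c("b", "a"))
  # k = 2: one vote each; e1 is closer, so its label wins despite order
  expect_equal(as.character(knn_predict(tr, q, k = 2)), "b")
  # exactly equidistant: lowest label id (factor order) wins
  q45 <- grassmann_point(orthonormalize(matrix(c(1, 1, 0), 3, 1))$Q)
  expect_equal(as.character(knn_predict(tr, q45, k = 2)), "a")
})

test_that("stratified splits have the stated per-class sizes", {
  set.seed(53)
  s <- rand_labeled_set(100, 2, 4, 1)
  sp <- stratified_split(s, 0.8, seed = 99)
  expect_equal(unname(tabulate(sp$train$labels)), c(80, 80))
  expect_equal(unname(tabulate(sp$test$labels)), c(20, 20))
  sp10 <- stratified_split(s, 0.1, seed = 99)
  expect_equal(unname(tabulate(sp10$train$labels)), c(10, 10))
  # round half up
  s15 <- rand_labeled_set(15, 1, 4, 1)
  expect_equal(length(stratified_split(s15, 0.1, seed = 1)$train), 2)
  # determinism and disjointness
  spA <- stratified_split(s, 0.4, seed = 7)
  spB <- stratified_split(s, 0.4, seed = 7)
  expect_identical(spA$train_idx, spB$train_idx)
  expect_length(intersect(spA$train_idx, spA$test_idx), 0)
  # a class too small to give at least one training item
  s3 <- rand_labeled_set(3, 1, 4, 1)
  expect_error(stratified_split(s3, 0.1, seed = 1), "class")
})

test_that("task presets subset and merge the Bonn groups", {
  set.seed(54)
  pts <- lapply(1:10, function(i) rand_point(6, 2))
  s <- grassmann_set(pts, rep(c("A", "B", "C", "D", "E"), 2))
  expect_equal(levels(select_task(s, "five_class")$labels),
               c("A", "B", "C", "D", "E"))
  ab <- select_task(s, "binary_AB")
  expect_equal(length(ab), 4)
  he <- select_task(s, "healthy_vs_epileptic")
  expect_equal(sort(levels(he$labels)), c("epileptic", "healthy"))
  expect_equal(unname(tabulate(he$labels)[levels(he$labels) == "healthy"]), 4)
  ae <- select_task(s, list(groups = c("A", "E"), merge = NULL))
  expect_equal(length(ae), 4)
  expect_error(select_task(s[1:4], "multiclass_CDE"), "absent")
  expect_error(select_task(s, "nonsense"), "unknown task")
})

test_that("run_grid validates dims against the subspace dimension", {
  set.seed(55)
  s <- gen_grassmann_classes(K = 2, n_per_class = 6, D = 12, p = 3,
                             noise = 0.2, seed = 2)
  expect_error(run_grid(s, ratios = 0.5, dims = 2, repeats = 1),
               "configuration error")
  expect_error(run_grid(s, ratios = 0.5, dims = 12, repeats = 1),
               "configuration error")
})

test_that("run_grid fills one cell per setting and is seed-reproducible", {
  set.seed(56)
  s <- gen_grassmann_classes(K = 2, n_per_class = 8, D = 12, p = 2,
                             noise = 0.15, seed = 4)
  g1 <- run_grid(s, ratios = c(0.4, 0.6), dims = c(4, 6), repeats = 2,
                 seed = 10, outer_iters = 3)
  expect_s3_class(g1, "accuracy_table")
  fm <- dplyr::filter(g1$raw, method == "fmgda")
  expect_equal(nrow(fm), 2 * 2 * 2)
  expect_true(all(fm$accuracy >= 0 & fm$accuracy <= 1))
  # mean cells equal the mean of the stored raw accuracies
  for (r in c(0.4, 0.6)) {
    for (d in c(4, 6)) {
      cell <- dplyr::filter(g1$cells, method == "fmgda", ratio == r,
                            dim == d)
      expect_equal(cell$accuracy,
                   mean(fm$accuracy[fm$ratio == r & fm$dim == d]))
    }
  }
  g2 <- run_grid(s, ratios = c(0.4, 0.6), dims = c(4, 6), repeats = 2,
                 seed = 10, outer_iters = 3)
  expect_identical(g1$cells, g2$cells)
  # single-cell spec
  g3 <- run_grid(s, ratios = 0.5, dims = 5, repeats = 1, seed = 1,
                 baseline = FALSE, outer_iters = 2)
  expect_equal(nrow(g3$cells), 1)
})

test_that("separable classes score perfectly across the grid", {
  set.seed(57)
  s <- gen_grassmann_classes(K = 2, n_per_class = 8, D = 10, p = 2,
                             noise = 0, prototype_separation = 2,
                             seed = 8)
  # balanced orthogonal classes: the global-mean eigenvalue tie is real
  suppressWarnings(
    g <- run_grid(s, ratios = c(0.4, 0.6), dims = c(4, 6), repeats = 1,
                  seed = 3, outer_iters = 2))
  expect_true(all(g$cells$accuracy == 1))
})

test_that("accuracy matrices and CSV export have the ratio-by-dim layout", {
  set.seed(58)
  s <- gen_grassmann_classes(K = 2, n_per_class = 6, D = 10, p = 2,
                             noise = 0.2, seed = 5)
  g <- run_grid(s, ratios = c(0.4, 0.6), dims = c(4, 6, 8), repeats = 1,
                seed = 2, outer_iters = 2)
  m <- accuracy_matrix(g)
  expect_equal(dim(m), c(2, 3))
  expect_equal(colnames(m), c("4", "6", "8"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_accuracy_csv(g, path)
  csv <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(csv), 2)
  expect_equal(colnames(csv), c("ratio", "4", "6", "8"))
  mb <- accuracy_matrix(g, method = "knn_raw")
  expect_equal(colnames(mb), "none")
})
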