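#' Nearest-neighbour prediction under the projection metric
#'
#' Classifies a query subspace by majority vote among its k nearest
#' training points in projection distance. Ties in the vote are broken
#' by the smallest summed distance to the query, then by the lowest
#' label (factor-level order); both rules are deterministic.
#'
#' @param train A [grassmann_set()] of labeled training points.
#' @param query A [grassmann_point()] or a [grassmann_set()] of
#'   queries.
#' @param k Number of neighbours (default 1); at most `length(train)`.
#' @return A factor of predicted labels (length 1 for a single point),
#'   with the training set's levels.
#' @export
knn_predict <- function(train, query, k = 1L) {
  stopifnot(inherits(train, "grassmann_set"))
  if (length(train) == 0L) stop("empty training set", call. = FALSE)
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= length(train))
  qset <- if (is_grassmann_point(query)) {
    grassmann_set(list(query), factor("q"))
  } else {
    stopifnot(inherits(query, "grassmann_set"))
    query
  }
  dm <- projection_distance_matrix(train, qset)  # n_train x n_query
  lv <- levels(train$labels)
  preds <- vapply(seq_len(ncol(dm)), function(j) {
    d <- dm[, j]
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(train$labels[nb], levels = lv))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(l) {
        sum(d[nb][train$labels[nb] == l])
      }, numeric(1))
      top <- top[sums == min(sums)]
    }
    top[1L]  # lowest label id among remaining ties
  }, character(1))
  factor(preds, levels = lv)
}

#' Stratified train/test split
#'
#' Samples `round(ratio * n_k)` items (round half up) without
#' replacement from every class, deterministically for a given seed;
#' the rest form the test set.
#'
#' @param data A [grassmann_set()].
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed; the split is a pure function of
#'   (data order, ratio, seed).
#' @return List with `train` and `test` ([grassmann_set()]s) and the
#'   index vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(data, ratio, seed = 1L) {
  stopifnot(inherits(data, "grassmann_set"), ratio > 0, ratio < 1)
  lv <- levels(data$labels)
  train_idx <- integer(0)
  with_local_seed(seed, {
    for (g in lv) {
      idx <- which(data$labels == g)
      ntr <- floor(ratio * length(idx) + 0.5)  # round half up
      if (ntr < 1L) {
        stop("class '", g, "' too small for ratio ", ratio,
             " (", length(idx), " items)", call. = FALSE)
      }
      if (ntr >= length(idx)) {
        stop("class '", g, "' leaves no test items at ratio ", ratio,
             call. = FALSE)
      }
      train_idx <- c(train_idx, sample(idx, ntr))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(data$labels), train_idx)
  list(train = data[train_idx], test = data[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

# Task presets: which Bonn groups enter and how they are relabeled.
task_definition <- function(task) {
  switch(task,
    five_class = list(groups = c("A", "B", "C", "D", "E"), merge = NULL),
    binary_AB = list(groups = c("A", "B"), merge = NULL),
    healthy_vs_epileptic = list(
      groups = c("A", "B", "C", "D", "E"),
      merge = c(A = "healthy", B = "healthy", C = "epileptic",
                D = "epileptic", E = "epileptic")),
    ABCD_vs_E = list(
      groups = c("A", "B", "C", "D", "E"),
      merge = c(A = "non_seizure", B = "non_seizure", C = "non_seizure",
                D = "non_seizure", E = "seizure")),
    multiclass_CDE = list(groups = c("C", "D", "E"), merge = NULL),
    stop("unknown task: ", task, call. = FALSE)
  )
}

#' Select and relabel a task subset
#'
#' Maps a labeled feature set onto one of the classification tasks:
#' `"five_class"` (A-E), `"binary_AB"`, `"healthy_vs_epileptic"`
#' (A+B vs C+D+E), `"ABCD_vs_E"`, `"multiclass_CDE"`, or a custom
#' `list(groups = ..., merge = ...)` where `merge` is a named vector
#' mapping original labels to task labels (the group-subset mechanism
#' also covers two-group seizure contrasts such as A-vs-E).
#'
#' @param features A [grassmann_set()].
#' @param task Task name or definition list; `NULL` keeps labels as-is.
#' @return A relabeled [grassmann_set()].
#' @export
select_task <- function(features, task = NULL) {
  stopifnot(inherits(features, "grassmann_set"))
  if (is.null(task)) return(features)
  def <- if (is.character(task)) task_definition(task) else task
  keep <- features$labels %in% def$groups
  if (!any(keep)) {
    stop("no features match task groups ",
         paste(def$groups, collapse = ","), call. = FALSE)
  }
  sub <- features[which(keep)]
  missing <- setdiff(def$groups, levels(sub$labels))
  if (length(missing) > 0L) {
    stop("task groups absent from the data: ",
         paste(missing, collapse = ","), call. = FALSE)
  }
  if (!is.null(def$merge)) {
    newlab <- unname(def$merge[as.character(sub$labels)])
    sub <- grassmann_set(sub$points, newlab)
  }
  sub
}

#' Run a train-ratio by target-dimension experiment grid
#'
#' The evaluation protocol behind the accuracy tables: for every
#' (ratio, dim, repeat) cell, draw a stratified split, fit the
#' discriminant map at `target_dim = dim` on the training points, map
#' both splits, and score 1-NN (projection metric) accuracy on the
#' test points. A no-reduction 1-NN baseline is scored once per split.
#' The whole grid is a deterministic function of `seed`.
#'
#' @param features A [grassmann_set()] (e.g. from
#'   [featurize_dataset()] or [gen_grassmann_classes()]).
#' @param task Optional task preset or definition (see
#'   [select_task()]); `NULL` uses the labels as-is.
#' @param ratios Training fractions (default `c(0.1, 0.2, 0.4, 0.6,
#'   0.8)`).
#' @param dims Target dimensions (default `c(4, 6, 8, 10, 15, 20, 25,
#'   30, 35, 40, 45, 50, 55, 60)`). Every dim must be at least the
#'   subspace dimension p of the features; otherwise a configuration
#'   error is raised before any fitting.
#' @param repeats Repetitions per cell (default 10).
#' @param seed Integer master seed.
#' @param k Neighbours for the classifier (default 1).
#' @param baseline Also score 1-NN without dimensionality reduction
#'   (default `TRUE`).
#' @param ... Further arguments passed to [fmgda()] (e.g.
#'   `within_weighting`, `outer_iters`).
#' @return Object of class `accuracy_table`: a list with `raw` (tibble
#'   of per-repeat results: method, ratio, dim, repeat, accuracy,
#'   n_train, n_test), `cells` (tibble of per-cell means) and the grid
#'   settings.
#' @export
run_grid <- function(features, task = NULL,
                     ratios = c(0.1, 0.2, 0.4, 0.6, 0.8),
                     dims = c(4, 6, 8, 10, 15, 20, 25, 30, 35, 40, 45,
                              50, 55, 60),
                     repeats = 10L, seed = 1L, k = 1L, baseline = TRUE,
                     ...) {
  data <- select_task(features, task)
  p <- data$subspace_dim
  D <- data$ambient_dim
  stopifnot(all(ratios > 0), all(ratios < 1), repeats >= 1L)
  dims <- as.integer(dims)
  if (any(dims < p)) {
    stop("configuration error: dims ",
         paste(dims[dims < p], collapse = ","),
         " are smaller than the subspace dimension p = ", p,
         call. = FALSE)
  }
  if (any(dims >= D)) {
    stop("configuration error: dims must be < ambient dimension D = ",
         D, call. = FALSE)
  }

  rows <- list()
  for (ri in seq_along(ratios)) {
    for (rep_i in seq_len(repeats)) {
      sseed <- derive_seed(seed, ri, rep_i)
      sp <- stratified_split(data, ratios[ri], seed = sseed)
      ntr <- length(sp$train)
      nte <- length(sp$test)
      if (baseline) {
        acc0 <- mean(knn_predict(sp$train, sp$test, k = k) ==
                       sp$test$labels)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = "knn_raw", ratio = ratios[ri], dim = NA_integer_,
          rep = rep_i, accuracy = acc0, n_train = ntr, n_test = nte)
      }
      for (d in dims) {
        fit <- fmgda(sp$train, target_dim = d, ...)
        tr_lo <- predict(fit, sp$train)
        te_lo <- predict(fit, sp$test)
        acc <- mean(knn_predict(tr_lo, te_lo, k = k) == te_lo$labels)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = "fmgda", ratio = ratios[ri], dim = d, rep = rep_i,
          accuracy = acc, n_train = ntr, n_test = nte)
      }
    }
  }
  raw <- dplyr::bind_rows(rows)
  cells <- raw |>
    dplyr::group_by(.data$method, .data$ratio, .data$dim) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     n_repeats = dplyr::n(), .groups = "drop")
  structure(
    list(raw = raw, cells = cells,
         settings = list(ratios = ratios, dims = dims, repeats = repeats,
                         seed = seed, k = k, task = task)),
    class = "accuracy_table"
  )
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat("<accuracy_table>", nrow(x$cells), "cells (",
      length(x$settings$ratios), "ratios x", length(x$settings$dims),
      "dims x", x$settings$repeats, "repeats )\n")
  print(accuracy_matrix(x))
  invisible(x)
}

#' Mean accuracies as a ratio-by-dimension matrix
#'
#' @param x An `accuracy_table` from [run_grid()].
#' @param method `"fmgda"` (default) or `"knn_raw"`.
#' @return Numeric matrix, rows = train ratios, columns = target dims
#'   (one `none` column for the baseline).
#' @export
accuracy_matrix <- function(x, method = "fmgda") {
  stopifnot(inherits(x, "accuracy_table"))
  sub <- dplyr::filter(x$cells, .data$method == !!method)
  wide <- sub |>
    dplyr::mutate(dim = ifelse(is.na(.data$dim), "none",
                               as.character(.data$dim))) |>
    tidyr::pivot_wider(id_cols = "ratio", names_from = "dim",
                       values_from = "accuracy")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- format(wide$ratio)
  ord <- order(suppressWarnings(as.numeric(colnames(m))))
  m[, ord, drop = FALSE]
}

#' Write an accuracy table as CSV (ratios x dims)
#'
#' Writes the mean-accuracy matrix in the conventional layout: one row
#' per train ratio, one column per target dimension.
#'
#' @inheritParams accuracy_matrix
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(x, path, method = "fmgda") {
  m <- accuracy_matrix(x, method = method)
  df <- data.frame(ratio = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
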