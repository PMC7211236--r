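#' Write a Grassmann set to a JSON container
#'
#' Portable plain-text serialization: shape metadata (D, p, n), labels,
#' and every basis flattened row-major.
#'
#' @param x A [grassmann_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grassmann_set <- function(x, path) {
  stopifnot(inherits(x, "grassmann_set"))
  obj <- list(
    container = "grassmann_set",
    ambient_dim = x$ambient_dim,
    subspace_dim = x$subspace_dim,
    n = length(x),
    labels = as.character(x$labels),
    bases = lapply(x$points, function(pt) as.vector(t(pt$basis)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# jsonlite's simplification may turn a list of equal-length numeric
# vectors into a matrix; normalize back to a list of rows.
row_vectors <- function(x) {
  if (is.matrix(x)) {
    out <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    names(out) <- rownames(x)
    out
  } else {
    x
  }
}

#' Read a Grassmann set written by [write_grassmann_set()]
#'
#' @param path Input path.
#' @return A [grassmann_set()].
#' @export
read_grassmann_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "grassmann_set")) {
    stop("not a grassmann_set container: ", path, call. = FALSE)
  }
  D <- obj$ambient_dim
  p <- obj$subspace_dim
  bases <- row_vectors(obj$bases)
  pts <- lapply(seq_len(obj$n), function(i) {
    grassmann_point(matrix(bases[[i]], D, p, byrow = TRUE))
  })
  grassmann_set(pts, obj$labels)
}

#' Write a fitted model to a JSON container
#'
#' Stores the map A, the class and global mean bases, the
#' configuration and the diagnostic traces; [read_fmgda()] restores
#' the model.
#'
#' @param model A fitted [fmgda()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fmgda <- function(model, path) {
  stopifnot(inherits(model, "fmgda"))
  obj <- list(
    container = "fmgda_model",
    config = model$config,
    levels = model$levels,
    n = model$n,
    A = as.vector(t(model$A)),
    A_dim = dim(model$A),
    class_means = lapply(model$class_means,
                         function(m) as.vector(t(m$basis))),
    global_mean = as.vector(t(model$global_mean$basis)),
    objective_trace = model$objective_trace,
    db_trace = model$db_trace,
    dw_trace = model$dw_trace,
    lambda_traces = model$lambda_traces,
    converged = model$converged,
    separability_guard = model$separability_guard,
    best_iteration = model$best_iteration,
    objective = model$objective
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_fmgda()]
#'
#' @param path Input path.
#' @return A fitted `fmgda` object.
#' @export
read_fmgda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "fmgda_model")) {
    stop("not an fmgda model container: ", path, call. = FALSE)
  }
  D <- obj$config$ambient_dim
  p <- obj$config$subspace_dim
  cm <- lapply(row_vectors(obj$class_means), function(v) {
    grassmann_point(matrix(unlist(v), D, p, byrow = TRUE))
  })
  lt <- obj$lambda_traces
  if (is.matrix(lt)) lt <- lapply(seq_len(nrow(lt)), function(i) lt[i, ])
  structure(
    list(
      A = matrix(obj$A, obj$A_dim[1], obj$A_dim[2], byrow = TRUE),
      class_means = cm,
      global_mean = grassmann_point(matrix(obj$global_mean, D, p,
                                           byrow = TRUE)),
      objective_trace = obj$objective_trace,
      db_trace = obj$db_trace,
      dw_trace = obj$dw_trace,
      lambda_traces = lt,
      converged = obj$converged,
      separability_guard = obj$separability_guard,
      best_iteration = obj$best_iteration,
      objective = obj$objective,
      config = obj$config,
      levels = obj$levels,
      n = obj$n
    ),
    class = "fmgda"
  )
}

#' Export a pairwise-distance matrix as CSV
#'
#' @param dm Matrix from [projection_distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.csv(as.data.frame(dm), path, row.names = FALSE)
  invisible(path)
}
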