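#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the optimization trace of a fitted model
#'
#' One row per outer iteration (iteration 0 is the initialization):
#' the exact objective \eqn{d_b/d_w}, its numerator and denominator,
#' and the number of inner trace-ratio iterations used.
#'
#' @param x A fitted [fmgda()] model.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `objective`, `d_between`,
#'   `d_within`, `inner_iters`.
#' @export
tidy.fmgda <- function(x, ...) {
  nit <- length(x$objective_trace)
  tibble::tibble(
    iteration = seq_len(nit) - 1L,
    objective = x$objective_trace,
    d_between = x$db_trace,
    d_within = x$dw_trace,
    inner_iters = c(NA_integer_,
                    vapply(x$lambda_traces, length, integer(1)),
                    rep(NA_integer_,
                        max(0L, nit - 1L - length(x$lambda_traces))))[seq_len(nit)]
  )
}

#' One-row summary of a fitted model
#'
#' @param x A fitted [fmgda()] model.
#' @param ... Unused.
#' @return A tibble with the problem size, final objective,
#'   iteration count and convergence flag.
#' @export
glance.fmgda <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_classes = length(x$levels),
    ambient_dim = x$config$ambient_dim,
    subspace_dim = x$config$subspace_dim,
    target_dim = x$config$target_dim,
    objective = x$objective,
    best_iteration = x$best_iteration,
    outer_iterations = length(x$objective_trace) - 1L,
    converged = x$converged,
    separability_guard = x$separability_guard
  )
}

#' Tidy an accuracy table
#'
#' @param x An `accuracy_table` from [run_grid()].
#' @param ... Unused.
#' @return The per-repeat results as a tibble (`method`, `ratio`,
#'   `dim`, `rep`, `accuracy`, `n_train`, `n_test`).
#' @export
tidy.accuracy_table <- function(x, ...) x$raw

#' Plot the optimization trace of a fitted model
#'
#' @param object A fitted [fmgda()] model.
#' @param ... Unused.
#' @return A ggplot of the exact objective per outer iteration.
#' @export
autoplot.fmgda <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$objective), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "outer iteration",
                  y = expression(d[b] / d[w]),
                  title = "Discriminant objective trace") +
    ggplot2::theme_minimal()
}

#' Plot an experiment grid
#'
#' Mean accuracy against target dimension, one line per train ratio;
#' the no-reduction baseline (if present) is drawn as a dashed
#' horizontal reference per ratio.
#'
#' @param object An `accuracy_table` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_table <- function(object, ...) {
  cells <- object$cells
  red <- dplyr::filter(cells, .data$method == "fmgda")
  base <- dplyr::filter(cells, .data$method == "knn_raw")
  gg <- ggplot2::ggplot(red, ggplot2::aes(x = .data$dim,
                                          y = .data$accuracy,
                                          colour = factor(.data$ratio))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "target dimension d", y = "mean accuracy",
                  colour = "train ratio") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (nrow(base) > 0) {
    gg <- gg + ggplot2::geom_hline(
      data = base,
      ggplot2::aes(yintercept = .data$accuracy,
                   colour = factor(.data$ratio)),
      linetype = "dashed", alpha = 0.6)
  }
  gg
}
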