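#' Tidy a fusion result
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return Tibble with one row per view: `view`, `alpha`, `cross_entropy`.
#' @method tidy fusion_result
#' @export
tidy.fusion_result <- function(x, ...) {
  tibble::tibble(
    view = names(x$alpha),
    alpha = unname(x$alpha),
    cross_entropy = unname(x$cross_entropy)
  )
}

#' Glance at a fusion result
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return One-row tibble: `eta`, `k`, `objective`, `iterations`,
#'   `converged`, `seed`, `n_views`, `n_compounds`.
#' @method glance fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  tibble::tibble(
    eta = x$eta, k = x$model$k, objective = x$objective,
    iterations = x$iterations, converged = x$converged, seed = x$seed,
    n_views = length(x$alpha), n_compounds = nrow(x$fused_S)
  )
}

#' Tidy a stability report
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return The per-eta report tibble: `eta`, `amd`, `adi_mean`, `adi_var`.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  x$report
}

#' Glance at a stability report
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return One-row tibble: `recommendation`, `n_eta`, `n_subsets`,
#'   `k_min`, `k_max`.
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    recommendation = x$recommendation, n_eta = nrow(x$report),
    n_subsets = x$n_subsets, k_min = x$k_range[1], k_max = x$k_range[2]
  )
}

#' Plot the convergence trace of a fusion run
#'
#' Outer-iteration objective per random restart.
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fusion_result
#' @export
autoplot.fusion_result <- function(object, ...) {
  ggplot2::ggplot(
    object$trace,
    ggplot2::aes(x = .data$iteration, y = .data$objective,
                 colour = factor(.data$restart))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "outer iteration", y = "objective",
                  colour = "restart",
                  title = sprintf("Fusion alternation (eta = %g)", object$eta)) +
    ggplot2::theme_minimal()
}

#' Plot a stability report
#'
#' AMD and ADI (with its variance band) against eta on a log axis, the view
#' used to pick the sparseness parameter.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$report, c("amd", "adi_mean"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$recommendation,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "eta", y = NULL,
                  title = "Leave-one-out stability across eta") +
    ggplot2::theme_minimal()
}

#' Plot common-target degree curves
#'
#' Mean within-class average degree against class count, one line per
#' similarity source.
#'
#' @param object A `target_curve` tibble ([common_target_curve()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot target_curve
#' @export
autoplot.target_curve <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$k, y = .data$mean_degree, colour = .data$source)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "number of classes k",
                  y = "mean within-class average degree",
                  colour = "similarity") +
    ggplot2::theme_minimal()
}
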