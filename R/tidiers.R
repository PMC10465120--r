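#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an omnibus embedding into a long tibble
#'
#' @param x an `omni_embedding`.
#' @param ... unused.
#' @return A tibble with columns `graph_index`, `vertex_id` (both
#'   1-based) and `dim_1 .. dim_d`.
#' @method tidy omni_embedding
#' @export
tidy.omni_embedding <- function(x, ...) {
  purrr::map_dfr(seq_len(x$m), function(s) {
    blk <- x$blocks[[s]]
    colnames(blk) <- paste0("dim_", seq_len(x$d))
    dplyr::bind_cols(
      tibble::tibble(graph_index = s, vertex_id = seq_len(x$n)),
      tibble::as_tibble(blk)
    )
  })
}

#' @method glance omni_embedding
#' @export
glance.omni_embedding <- function(x, ...) {
  tibble::tibble(
    design = x$design, m = x$m, n = x$n, d = x$d,
    min_eigenvalue = min(x$eigenvalues),
    max_eigenvalue = max(x$eigenvalues)
  )
}

#' @method glance omni_coef_check
#' @export
glance.omni_coef_check <- function(x, ...) {
  tibble::tibble(
    m = x$m, convexity = x$convexity, symmetry = x$symmetry,
    dominance = x$dominance, valid = x$valid,
    first_violation = x$first_violation
  )
}

#' Tidy a weight profile
#'
#' @param x a [weight_profile()] matrix.
#' @param ... unused.
#' @return A long tibble with columns `block_row`, `graph`, `alpha`.
#' @method tidy weight_profile
#' @export
tidy.weight_profile <- function(x, ...) {
  a <- unclass(x)
  tibble::tibble(
    block_row = rep(seq_len(nrow(a)), ncol(a)),
    graph = rep(seq_len(ncol(a)), each = nrow(a)),
    alpha = as.vector(a)
  )
}

#' Tidy a timeseries pipeline result
#'
#' @param x a `timeseries_pipeline` result.
#' @param ... unused.
#' @return A tibble with one row per graph: `graph_index`, MDS
#'   coordinates `mds_1..`, and `cluster`.
#' @method tidy timeseries_pipeline
#' @export
tidy.timeseries_pipeline <- function(x, ...) {
  conf <- x$configuration
  colnames(conf) <- paste0("mds_", seq_len(ncol(conf)))
  dplyr::bind_cols(
    tibble::tibble(graph_index = seq_along(x$labels)),
    tibble::as_tibble(conf),
    tibble::tibble(cluster = as.integer(x$labels))
  )
}

#' Plot an omnibus embedding
#'
#' Scatter of the first two embedding dimensions, faceted by graph.
#'
#' @param object an `omni_embedding`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot omni_embedding
#' @export
autoplot.omni_embedding <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim_1, .data$dim_2)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~graph_index) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = "Omnibus embedding blocks")
}

#' Plot a timeseries pipeline: MDS configuration colored by cluster
#'
#' @param object a `timeseries_pipeline` result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot timeseries_pipeline
#' @export
autoplot.timeseries_pipeline <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mds_1, .data$mds_2,
                                   color = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$graph_index),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", color = "cluster",
                  title = "Graph time series, scaled and clustered")
}

#' Plot a community-detection experiment
#'
#' Mean clustering error per cell with 2-standard-error bars, by method.
#'
#' @param object a tibble from [run_community_detection_experiment()].
#' @param x_var grid variable for the x axis (`"rho"`, `"eps"` or `"n"`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_community_experiment <- function(object, x_var = "rho", ...) {
  summ <- object |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(x_var, "method")))) |>
    dplyr::summarise(
      mean_error = mean(.data$error),
      se = stats::sd(.data$error) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(.data[[x_var]], .data$mean_error,
                                     color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_error - 2 * .data$se,
      ymax = .data$mean_error + 2 * .data$se
    )) +
    ggplot2::labs(y = "clustering error", title = "Community detection")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
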