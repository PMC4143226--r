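#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

time_axis <- function(n, dt) (seq_len(n) - 1) * if (is.na(dt)) 1 else dt

#' Tidy a potential recording into a long tibble
#'
#' @param x a [potential_recording()].
#' @param ... unused.
#' @return A tibble with columns `depth_um`, `time_ms`, `potential_mv`.
#' @export
tidy.potential_recording <- function(x, ...) {
  tibble::tibble(
    depth_um = rep(x$array$depths, times = ncol(x$values)),
    time_ms = rep(time_axis(ncol(x$values), x$dt), each = nrow(x$values)),
    potential_mv = as.vector(x$values))
}

#' Tidy a CSD estimate into a long tibble
#'
#' @param x a [csd_estimate()].
#' @param ... unused.
#' @return A tibble with columns `depth_um`, `time_ms`, `csd`.
#' @export
tidy.csd_estimate <- function(x, ...) {
  tibble::tibble(
    depth_um = rep(x$grid, times = ncol(x$values)),
    time_ms = rep(time_axis(ncol(x$values), x$dt), each = nrow(x$values)),
    csd = as.vector(x$values))
}

#' Tidy a PCA result
#'
#' @param x a [pca_result][pca_truncate()].
#' @param ... unused.
#' @return A tibble with one row per retained component: `component`,
#'   `singular_value`, `energy_fraction`.
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$K),
    singular_value = x$singular_values,
    energy_fraction = x$singular_values^2 / sum(x$all_singular_values^2))
}

#' @rdname tidy.pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    energy_retained = sum(x$singular_values^2) /
      sum(x$all_singular_values^2),
    rank = sum(x$all_singular_values >
                 1e-12 * x$all_singular_values[1]))
}

#' Tidy an ICA result
#'
#' @param x an [ica_result][spatial_ica()].
#' @param type "spatial" returns the unit-norm depth profiles, "temporal"
#'   the amplitude-carrying time courses.
#' @param ... unused.
#' @return A long tibble keyed by `component`.
#' @export
tidy.ica_result <- function(x, type = c("spatial", "temporal"), ...) {
  type <- match.arg(type)
  if (type == "spatial") {
    axis <- if (is.null(x$grid)) seq_len(ncol(x$spatial)) else x$grid
    tibble::tibble(
      component = rep(seq_len(x$K), each = ncol(x$spatial)),
      depth_um = rep(axis, times = x$K),
      value = as.vector(t(x$spatial)))
  } else {
    tibble::tibble(
      component = rep(seq_len(x$K), each = ncol(x$temporal)),
      time_ms = rep(time_axis(ncol(x$temporal), x$dt), times = x$K),
      value = as.vector(t(x$temporal)))
  }
}

#' @rdname tidy.ica_result
#' @export
glance.ica_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, alpha = x$alpha, K = x$K,
                 objective = x$objective, converged = x$converged,
                 seed = x$seed, backend = x$backend)
}

#' Tidy a population assignment
#'
#' @param x a [population_assignment][assign_components()].
#' @param ... unused.
#' @return A long tibble `population`, `component`, `coefficient` with the
#'   nonzero coefficients.
#' @export
tidy.population_assignment <- function(x, ...) {
  long <- tidyr::pivot_longer(x$coefficients, -"population",
                              names_to = "component",
                              values_to = "coefficient")
  dplyr::filter(long, .data$coefficient != 0)
}

#' @rdname tidy.population_assignment
#' @export
glance.population_assignment <- function(x, ...) {
  x$scores
}

#' @rdname tidy.population_assignment
#' @param x an object.
#' @export
glance.lampop_analysis <- function(x, ...) {
  dplyr::mutate(x$scores, K = x$K, lambda = x$lambda, mode = x$mode)
}

#' @export
tidy.experiment_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.experiment_result <- function(x, ...) summary(x)

#' Heat map of a CSD estimate
#'
#' Depth-time image with the conventional diverging color scale: red for
#' sources (positive), blue for sinks (negative), depth increasing
#' downward.
#'
#' @param object a [csd_estimate()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.csd_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$depth_um,
                                   fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "time (ms)", y = "depth (um)", fill = "CSD") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.csd_estimate
#' @export
autoplot.potential_recording <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$depth_um,
                                   fill = .data$potential_mv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "time (ms)", y = "depth (um)", fill = "LFP (mV)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.csd_estimate
#' @export
autoplot.ica_result <- function(object, ...) {
  maps <- components_to_maps(object)
  axis <- if (is.null(object$grid)) seq_len(ncol(object$spatial)) else
    object$grid
  df <- dplyr::bind_rows(lapply(seq_along(maps), function(k) {
    tibble::tibble(
      component = k,
      depth_um = rep(axis, times = ncol(maps[[k]])),
      time_ms = rep(time_axis(ncol(maps[[k]]), object$dt),
                    each = length(axis)),
      value = as.vector(maps[[k]]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$depth_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (ms)", y = "depth (um)", fill = "CSD") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.csd_estimate
#' @export
autoplot.experiment_result <- function(object, ...) {
  fac <- attr(object, "factor_name")
  df <- summary(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[fac]], y = .data$mean_score,
                                   color = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_score - .data$sd_score,
      ymax = .data$mean_score + .data$sd_score), width = 0) +
    ggplot2::labs(x = fac, y = "recovery correlation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
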