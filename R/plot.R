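#' Plot a bubble trace
#'
#' Radius versus time for a `bubble_trace` tibble (from [run_collapse()],
#' [rp_integrate()] or [run_near_wall()]).
#'
#' @param object a `bubble_trace`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bubble_trace <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  rcol <- if ("R" %in% names(object)) "R" else "R_eq"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t * 1e3,
                               y = .data[[rcol]] * 1e3)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t [ms]", y = "bubble radius [mm]") +
    ggplot2::theme_minimal()
}

#' Plot a 1D density field
#'
#' @param state a [density_field()].
#' @param eos optionally a [fluid_eos()]; adds the interface threshold.
#' @return a ggplot object.
#' @export
plot_density_field <- function(state, eos = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- tibble::tibble(r = state$grid$centers, rho = state$rho)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r * 1e3, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r [mm]", y = expression(rho ~ "[kg/m"^3 * "]")) +
    ggplot2::theme_minimal()
  if (!is.null(eos))
    p <- p + ggplot2::geom_hline(yintercept = eos$rho_c, linetype = 2)
  p
}

#' Plot a 2D axisymmetric field
#'
#' Heat map of a per-cell scalar (density by default) over the `(r, z)`
#' cut plane of a [coupled_state()].
#'
#' @param state a [coupled_state()].
#' @param field per-cell values (defaults to the density).
#' @param name legend label.
#' @return a ggplot object.
#' @export
plot_field_2d <- function(state, field = state$rho, name = "rho") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  m <- state$mesh
  df <- tibble::tibble(r = m$cell_r * 1e3, z = m$cell_z * 1e3, v = field)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$z,
                                   fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r [mm]", y = "z [mm]", fill = name) +
    ggplot2::theme_minimal()
}

#' @importFrom stats uniroot
NULL
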