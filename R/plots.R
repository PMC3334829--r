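#' Plot the free-energy trace of a Metropolis chain
#'
#' @param object A `metropolis_chain`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metropolis_chain <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration, y = .data$F)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = dplyr::filter(object$trace, .data$accepted),
                        size = 0.6, colour = "grey30") +
    ggplot2::labs(x = "iteration", y = "free energy",
                  title = "Metropolis free-energy trace") +
    ggplot2::theme_minimal()
}

#' Plot free-energy traces and convergence history of a head search
#'
#' @param object A `head_search`.
#' @param what `"trace"` (free energy per chain) or `"rhat"` (diagnostic
#'   history).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.head_search <- function(object, what = c("trace", "rhat"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    d <- tidy(object)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$F,
                                    colour = factor(.data$chain))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration", y = "free energy", colour = "chain") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$rhat_history,
                    ggplot2::aes(x = .data$samples_per_chain, y = .data$rhat)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(x = "samples per chain", y = expression(hat(R))) +
      ggplot2::theme_minimal()
  }
}

#' Plot the hyperparameter profile of a fitted inversion
#'
#' Component weights against patch centre, with pruned components marked.
#'
#' @param object An `msp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msp_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$weight,
                                  colour = .data$pruned)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$component, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "grey70")) +
    ggplot2::labs(x = "covariance component", y = "weight exp(lambda)") +
    ggplot2::theme_minimal()
}

#' Plot a BMA source map
#'
#' Mean time-integrated power (and peak posterior mass) per vertex.
#'
#' @param object A `bma_result`.
#' @param mesh Optional [cortical_mesh()] for a glass-brain style x-y
#'   scatter; without it the map is drawn against vertex index.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bma_result <- function(object, mesh = NULL, ...) {
  d <- tidy(object)
  if (!is.null(mesh)) {
    d <- dplyr::mutate(d, x = mesh$vertices[, 1], y = mesh$vertices[, 2])
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$mean_power,
                                    size = .data$peak_mass)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::scale_colour_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "mean power",
                    size = "peak mass") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$vertex, y = .data$mean_power)) +
      ggplot2::geom_col(width = 1, fill = "steelblue") +
      ggplot2::labs(x = "vertex", y = "mean power") +
      ggplot2::theme_minimal()
  }
}

#' Plot a fiducial posterior cloud
#'
#' @param object A `fiducial_posterior`.
#' @param ... Unused.
#' @return A ggplot of the sampled fiducial positions in the x-y plane.
#' @export
autoplot.fiducial_posterior <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$x, y = .data$y,
                                               colour = .data$fiducial)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
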