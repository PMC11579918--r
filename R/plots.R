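#' Plot a number-density profile
#'
#' @param object A `density_profile`.
#' @param fit Optional `gaussian_fit` to overlay as a dashed curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_col(width = diff(attr(object, "bin_edges"))[1],
                      fill = "grey70", colour = NA) +
    ggplot2::labs(x = "z (Å)",
                  y = expression(density ~ (beads ~ ring(A)^-3)),
                  title = attr(object, "selection_descriptor")) +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !is.null(fit$components)) {
    zz <- seq(min(object$z), max(object$z), length.out = 400)
    yy <- gaussian_mixture_value(fit, zz)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(z = zz, density = yy),
      ggplot2::aes(x = .data$z, y = .data$density),
      linetype = "dashed", colour = "firebrick")
  }
  p
}

gaussian_mixture_value <- function(fit, z) {
  comp <- fit$components
  Reduce(`+`, lapply(seq_len(nrow(comp)), function(k) {
    comp$amplitude[k] * exp(-(z - comp$mean[k])^2 / (2 * comp$sigma[k]^2))
  }))
}

#' Plot per-replicate thicknesses with the aggregate mean and SEM
#'
#' @param object A `thickness_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thickness_result <- function(object, ...) {
  d <- object$per_replicate
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$replicate),
                                  y = .data$thickness)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$mean, colour = "firebrick") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$mean - object$sem,
                      ymax = object$mean + object$sem,
                      alpha = 0.15, fill = "firebrick") +
    ggplot2::labs(x = "replicate", y = "thickness (Å)",
                  title = sprintf("%s (%s fit): %.2f ± %.2f Å",
                                  object$region, object$method,
                                  object$mean, object$sem)) +
    ggplot2::theme_minimal()
}

#' Plot an RMSF profile
#'
#' @param object An `rmsf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bead, y = .data$rmsf))
  if ("replicate_sd" %in% names(object) && !all(is.na(object$replicate_sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$rmsf - .data$replicate_sd,
                   ymax = .data$rmsf + .data$replicate_sd),
      alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "bead", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a cleavage profile (mean +/- SD vs N-length)
#'
#' @param object A `cleavage_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cleavage_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_length, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "N-length (residues)", y = "cleavage (%)",
                  title = attr(object, "strain")) +
    ggplot2::theme_minimal()
}

#' Plot a profile comparison (p-values with significance stars)
#'
#' @param object A `cleavage_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cleavage_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_length,
                                       y = -log10(.data$p_value))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), vjust = -0.6) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "N-length (residues)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Plot planted vs recovered thickness for a validation report
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$systems,
                           cols = c("planted", "recovered"),
                           names_to = "kind", values_to = "thickness")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$system, y = .data$thickness,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      data = object$systems,
      ggplot2::aes(x = .data$system, ymin = .data$recovered - .data$sem,
                   ymax = .data$recovered + .data$sem),
      inherit.aes = FALSE, width = 0.2,
      position = ggplot2::position_nudge(x = 0.22)) +
    ggplot2::labs(x = NULL, y = "thickness (Å)", fill = NULL) +
    ggplot2::theme_minimal()
}
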