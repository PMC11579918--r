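#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Gaussian leaflet fit
#'
#' @param x A `gaussian_fit` from [fit_leaflet_gaussians()].
#' @param ... Unused.
#' @return One row per Gaussian component: `component`, `amplitude`, `mean`,
#'   `sigma` and their standard errors.
#' @export
tidy.gaussian_fit <- function(x, ...) {
  if (is.null(x$components)) {
    return(tibble::tibble(component = integer(0), amplitude = numeric(0),
                          mean = numeric(0), sigma = numeric(0)))
  }
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = 1)
}

#' @rdname tidy.gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, converged = x$converged,
                 r_squared = x$r_squared, residual_norm = x$residual_norm,
                 thickness = if (isTRUE(x$converged)) thickness_from_fit(x) else NA_real_)
}

#' Tidy a thickness result
#'
#' @param x A `thickness_result` from [thickness_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: the per-replicate table; `glance()`: one row with the
#'   aggregate mean, SEM and replicate count.
#' @export
tidy.thickness_result <- function(x, ...) x$per_replicate

#' @rdname tidy.thickness_result
#' @export
glance.thickness_result <- function(x, ...) {
  tibble::tibble(region = x$region, method = x$method, mean = x$mean,
                 sem = x$sem, n_replicates = x$n_replicates)
}

#' Tidy a validation report
#'
#' @param x A `validation_report` from [run_validation()].
#' @param ... Unused.
#' @return `tidy()`: the per-system recovery table; `glance()`: the derived
#'   thinning/difference quantities in wide form.
#' @export
tidy.validation_report <- function(x, ...) x$systems

#' @rdname tidy.validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tidyr::pivot_wider(x$derived, names_from = "quantity",
                     values_from = "value")
}
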