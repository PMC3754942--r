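#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the parameters of a binding-model fit
#'
#' @param x An `itc_fit`, `competition_fit`, `dsc_fit` or `spr_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) x$params

#' @rdname tidy.binding_fit
#' @exportS3Method generics::tidy
tidy.itc_fit <- function(x, ...) tidy.binding_fit(x, ...)

#' @rdname tidy.binding_fit
#' @exportS3Method generics::tidy
tidy.competition_fit <- function(x, ...) tidy.binding_fit(x, ...)

#' @rdname tidy.binding_fit
#' @exportS3Method generics::tidy
tidy.dsc_fit <- function(x, ...) tidy.binding_fit(x, ...)

#' @rdname tidy.binding_fit
#' @exportS3Method generics::tidy
tidy.spr_fit <- function(x, ...) tidy.binding_fit(x, ...)

.glance_nls <- function(fit, n) {
  rss <- sum(stats::residuals(fit)^2)
  tibble(sigma = sqrt(rss / max(n - length(stats::coef(fit)), 1)),
         rss = rss, nobs = n, converged = TRUE)
}

#' One-row fit summary of a binding-model fit
#'
#' @param x A fit object.
#' @param ... Unused.
#' @return Tibble with `sigma`, `rss`, `nobs`, `converged`.
#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  if (inherits(x$fit, "nls")) return(.glance_nls(x$fit, nrow(x$data)))
  rss <- sum(stats::residuals(x$fit$kon)^2) + sum(stats::residuals(x$fit$koff)^2)
  tibble(sigma = sqrt(rss / nrow(x$data)), rss = rss,
         nobs = nrow(x$data), converged = TRUE)
}

#' @rdname glance.binding_fit
#' @exportS3Method generics::glance
glance.itc_fit <- function(x, ...) glance.binding_fit(x, ...)

#' @rdname glance.binding_fit
#' @exportS3Method generics::glance
glance.competition_fit <- function(x, ...) glance.binding_fit(x, ...)

#' @rdname glance.binding_fit
#' @exportS3Method generics::glance
glance.dsc_fit <- function(x, ...) glance.binding_fit(x, ...)

#' @rdname glance.binding_fit
#' @exportS3Method generics::glance
glance.spr_fit <- function(x, ...) glance.binding_fit(x, ...)

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("%s fit\n", x$model))
  print(x$params)
  invisible(x)
}

#' @export
print.itc_fit <- function(x, ...) print.binding_fit(x, ...)
#' @export
print.competition_fit <- function(x, ...) print.binding_fit(x, ...)
#' @export
print.dsc_fit <- function(x, ...) print.binding_fit(x, ...)
#' @export
print.spr_fit <- function(x, ...) print.binding_fit(x, ...)

#' Plot an ITC fit: measured heats and fitted isotherm
#'
#' @param object An `itc_fit` or `competition_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.itc_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat_per_mol)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "molar ratio (injectant / cell)",
                  y = "heat (kcal / mol injectant)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.itc_fit
#' @exportS3Method ggplot2::autoplot
autoplot.competition_fit <- function(object, ...) autoplot.itc_fit(object, ...)

#' Plot a DSC fit: thermogram and fitted two-state curve
#'
#' @param object A `dsc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dsc_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_c)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cp), size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "temperature (°C)",
                  y = "excess Cp (kcal / mol / K)") +
    ggplot2::theme_minimal()
}

#' Plot SPR sensorgrams coloured by analyte concentration
#'
#' @param object An `spr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spr_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time, y = .data$response,
                               colour = factor(.data$concentration))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  colour = "analyte (M)") +
    ggplot2::theme_minimal()
}
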