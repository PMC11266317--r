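#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for analysis results
#'
#' `tidy()` on a `noise_analysis` returns the per-repetition means; `glance()`
#' the one-row summary (grand mean, SD, COV). `tidy()` on a `stats_report`
#' returns the location-test row; `glance()` adds the normality gate outcome.
#'
#' @param x A `noise_analysis` or `stats_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.noise_analysis <- function(x, ...) x$rep_means

#' @rdname tidiers
#' @export
glance.noise_analysis <- function(x, ...) {
  tibble::tibble(mu_mean = x$mu_mean, mu_sd = x$mu_sd, cov = x$cov,
                 n_repetitions = x$n_repetitions, n_vois = x$n_vois)
}

#' @rdname tidiers
#' @export
tidy.stats_report <- function(x, ...) x$test

#' @rdname tidiers
#' @export
glance.stats_report <- function(x, ...) {
  dplyr::mutate(x$test, all_groups_normal = all(x$normality$normal),
                n_groups = nrow(x$normality))
}
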