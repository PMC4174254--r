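#' Plot an ABC posterior
#'
#' Weighted posterior densities of the adjusted draws, one facet per
#' parameter, with the posterior mean marked.
#'
#' @param object An `abc_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abc_posterior
#' @export
autoplot.abc_posterior <- function(object, ...) {
  df <- tibble::as_tibble(object$draws) |>
    dplyr::mutate(.w = object$weights) |>
    tidyr::pivot_longer(-".w", names_to = "parameter",
                        values_to = "value")
  means <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   weight = .data$.w)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "parameter value (log scale)", y = "posterior density")
}

#' Plot a pod validation report
#'
#' One panel per reliability metric, one point per parameter.
#'
#' @param object A `validation_report` from [validate_with_pods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"parameter",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Compare mean pairwise differences across regions and loci
#'
#' Dot-and-error-bar plot of mpd with its standard error, per region,
#' coloured by locus; the standard companion figure to the per-region
#' diversity table.
#'
#' @param diversity A diversity report with columns `locus`, `group`,
#'   `mpd`, `mpd_se` (e.g. from [run_pipeline()] or [diversity_by()]).
#' @return A ggplot object.
#' @export
plot_mpd <- function(diversity) {
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = .data$group, y = .data$mpd,
                               colour = .data$locus)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(.data$mpd - .data$mpd_se, 0),
                   ymax = .data$mpd + .data$mpd_se),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "mean pairwise differences") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
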