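#' Plot the noise/dose trade-off
#'
#' Coefficient of variation of the mu-map against CTDI_vol for each scan
#' setting, the summary figure of the noise experiment.
#'
#' @param noise Tibble from [run_noise_cov()] (`$noise`): columns `kvp`,
#'   `qrm`, `cov`, `ctdi_mgy`.
#' @return A ggplot object.
#' @export
plot_noise_tradeoff <- function(noise) {
  ggplot2::ggplot(noise,
                  ggplot2::aes(x = .data$ctdi_mgy, y = .data$cov,
                               colour = factor(.data$kvp),
                               shape = factor(.data$qrm))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = expression(CTDI[vol] ~ "(mGy)"),
                  y = expression("COV of" ~ mu ~ "map"),
                  colour = "kVp", shape = "QRM (mAs)") +
    ggplot2::theme_minimal()
}

#' Plot per-insert relative attenuation errors
#'
#' @param insert_stats Tibble from [run_mu_comparison()] (`$insert_stats`).
#' @return A ggplot object.
#' @export
plot_mu_errors <- function(insert_stats) {
  ggplot2::ggplot(insert_stats,
                  ggplot2::aes(x = .data$material, y = .data$rel_error_pct,
                               fill = interaction(.data$kvp, .data$qrm))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(Delta * mu ~ "(%)"),
                  fill = "kVp.QRM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the activity-recovery error matrix
#'
#' @param recovery Tibble from [run_quantification()] (`$recovery`).
#' @return A ggplot object.
#' @export
plot_recovery_matrix <- function(recovery) {
  ggplot2::ggplot(recovery,
                  ggplot2::aes(x = interaction(.data$kvp, .data$qrm),
                               y = .data$source,
                               fill = .data$rel_error_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$rel_error_pct)), size = 3) +
    ggplot2::scale_fill_gradient2(name = "error (%)") +
    ggplot2::labs(x = "kVp.QRM", y = NULL) +
    ggplot2::theme_minimal()
}
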