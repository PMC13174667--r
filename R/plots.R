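#' Plot scaled mutation rate estimates per context
#'
#' Point-range plot of `muT` with 95% intervals, contexts ordered by
#' descending unmethylated rate, one colour per methylation state.
#'
#' @param object a `cpg_rates` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cpg_rates
#' @export
autoplot.cpg_rates <- function(object, ...) {
  df <- as_tibble(object)
  ord <- df |>
    filter(is.na(.data$state) | .data$state == 0) |>
    arrange(dplyr::desc(.data$muT)) |>
    pull(.data$context)
  df <- mutate(df,
               context = factor(.data$context, levels = unique(c(ord, df$context))),
               state_lab = dplyr::case_when(
                 is.na(.data$state) ~ "context only",
                 .data$state == 0 ~ "unmethylated",
                 TRUE ~ "methylated"
               ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$muT,
                                   colour = .data$state_lab)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5),
                             linewidth = 0.4, size = 0.3) +
    ggplot2::labs(x = "sequence context", y = expression(mu * T),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heatmap of 4-mer rates by flanking bases
#'
#' Arranges the 16 4-mer contexts on an upstream-base x downstream-base
#' grid, one panel per methylation state, making marginal flank effects
#' visible as row/column structure.
#'
#' @param rates a `cpg_rates` tibble from a 4-mer-context fit.
#' @return A ggplot object.
#' @export
plot_rate_heatmap <- function(rates) {
  df <- as_tibble(rates) |>
    filter(nchar(.data$context) == 4L) |>
    mutate(
      U1 = substr(.data$context, 1L, 1L),
      D1 = substr(.data$context, 4L, 4L),
      state_lab = dplyr::case_when(
        is.na(.data$state) ~ "context only",
        .data$state == 0 ~ "unmethylated",
        TRUE ~ "methylated"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$D1, y = .data$U1, fill = .data$muT)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~state_lab, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "downstream base (3')", y = "upstream base (5')",
                  fill = expression(mu * T)) +
    ggplot2::theme_minimal()
}

#' Plot methylation-binned polymorphism rates
#'
#' The model-free saturation view: observed polymorphism rate against
#' methylation bin midpoint with Wilson intervals.
#'
#' @param object a `cpg_bins` tibble from [binned_rates()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cpg_bins
#' @export
autoplot.cpg_bins <- function(object, ...) {
  df <- filter(as_tibble(object), .data$n > 0L)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$m_low + .data$m_high) / 2,
                                   y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                             size = 0.3) +
    ggplot2::labs(x = "methylation level", y = "polymorphism rate") +
    ggplot2::theme_minimal()
}

#' Plot within-CpG mutational asymmetry
#'
#' Rate difference between reverse-complement context pairs with propagated
#' 95% intervals, per methylation state.
#'
#' @param object a `cpg_asymmetry` tibble from [test_asymmetry()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cpg_asymmetry
#' @export
autoplot.cpg_asymmetry <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(
      pair = paste(.data$context_a, .data$context_b, sep = ":"),
      state_lab = dplyr::case_when(
        is.na(.data$state) ~ "context only",
        .data$state == 0 ~ "unmethylated",
        TRUE ~ "methylated"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$delta,
                                   fill = .data$state_lab)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta - 1.96 * .data$se_delta,
                   ymax = .data$delta + 1.96 * .data$se_delta),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "reverse-complement context pair",
                  y = expression(Delta * mu * T ~ "(a - b)"), fill = NULL) +
    ggplot2::theme_minimal()
}
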