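#' MA-style plot of induction-filter results
#'
#' Mean expression (x, log10 of the two conditions' geometric-mean RPKM)
#' against log2 fold change, colouring genes that pass the induction filter.
#' Infinite fold changes (zero baseline) are drawn at the panel's fold-change
#' ceiling with a distinct shape.
#'
#' @param object A `de_result` from [apply_induction_filter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(
      mean_rpkm = sqrt(pmax(.data$rpkm_baseline, 0.01) * pmax(.data$rpkm_target, 0.01)),
      log2_fc = log2(.data$fold_change),
      zero_baseline = !is.finite(.data$log2_fc)
    )
  cap <- max(df$log2_fc[is.finite(df$log2_fc)], 1, na.rm = TRUE) + 1
  df$log2_fc[df$zero_baseline] <- cap
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_rpkm, y = .data$log2_fc,
    colour = .data$passes_filter, shape = .data$zero_baseline
  )) +
    ggplot2::geom_hline(yintercept = log2(attr(object, "fold_threshold")), linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17), guide = "none") +
    ggplot2::labs(
      x = "geometric mean RPKM", y = "log2 fold change (target / baseline)",
      colour = "passes filter"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of category-family mRNA shares
#'
#' @param shares Output of [family_shares()].
#' @return A ggplot object.
#' @export
plot_family_shares <- function(shares) {
  shares <- shares %>% mutate(family = factor(.data$family, levels = .data$family))
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$family, y = .data$share_pct, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of category mRNA", fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Antisense:sense ratio comparison between two conditions
#'
#' Scatter of per-gene AS:S ratios in two conditions on log scales; the
#' quadrant with ratio > 1 in one condition and < 1 in the other holds the
#' switch candidates.
#'
#' @param records An `antisense_records` tibble from [as_s_ratios()].
#' @param cond_a,cond_b Condition labels for the axes.
#' @return A ggplot object.
#' @export
plot_as_ratios <- function(records, cond_a, cond_b) {
  wide <- as_tibble(records) %>%
    filter(.data$ratio_defined) %>%
    select("gene_id", "condition", "ratio") %>%
    pivot_wider(names_from = "condition", values_from = "ratio") %>%
    filter(!is.na(.data[[cond_a]]), !is.na(.data[[cond_b]]))
  ggplot2::ggplot(wide, ggplot2::aes(
    x = pmax(.data[[cond_a]], 1e-4),
    y = pmax(.data[[cond_b]], 1e-4)
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = paste("AS:S ratio,", cond_a),
      y = paste("AS:S ratio,", cond_b)
    ) +
    ggplot2::theme_minimal()
}
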