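#' Plot a deamination damage profile
#'
#' Substitution frequency against distance from the fragment end, one
#' panel per end, with exact binomial confidence ribbons; the interior
#' baseline is drawn as a dashed line. Positions with no observations are
#' absent, not drawn at zero.
#'
#' @param object A [damage_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot damage_profile
autoplot.damage_profile <- function(object, ...) {
  ends <- object %>%
    filter(.data$end != "interior", !is.na(.data$freq)) %>%
    mutate(end = factor(.data$end, c("five_prime", "three_prime"),
                        c("5' end", "3' end")))
  interior <- object %>% filter(.data$end == "interior", !is.na(.data$freq))
  p <- ggplot2::ggplot(ends, ggplot2::aes(x = .data$i, y = .data$freq,
                                          colour = .data$substitution,
                                          fill = .data$substitution)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~end) +
    ggplot2::labs(x = "distance from fragment end (bp)",
                  y = "substitution frequency",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (nrow(interior) > 0L) {
    p <- p + ggplot2::geom_hline(data = interior,
                                 ggplot2::aes(yintercept = .data$freq),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a calibrated radiocarbon posterior
#'
#' The posterior over calendar age with the HPD intervals shaded.
#'
#' @param object A [calibrate_date()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot cal_result
autoplot.cal_result <- function(object, ...) {
  post <- object$posterior
  shade <- object$intervals %>%
    mutate(level = factor(sprintf("%.1f%%", 100 * .data$level)))
  ggplot2::ggplot(post, ggplot2::aes(x = .data$cal_bp, y = .data$prob)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$to_cal_bp, xmax = .data$from_cal_bp,
                                    ymin = 0, ymax = Inf, alpha = .data$level),
                       inherit.aes = FALSE, fill = "steelblue") +
    ggplot2::scale_alpha_manual(values = c(0.35, 0.15)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "calendar age (cal BP)", y = "posterior probability",
                  alpha = "HPD level",
                  title = sprintf("%s ± %s 14C BP (%s)",
                                  format(object$age_bp, big.mark = ","),
                                  object$sigma, object$curve_name)) +
    ggplot2::theme_minimal()
}

#' Plot derived-state support per branch
#'
#' Side-by-side bars of the unfiltered and deamination-filtered support
#' percentages with derived/total counts as labels.
#'
#' @param support A [branch_support()] table.
#' @return A ggplot.
#' @export
plot_branch_support <- function(support) {
  long <- support %>%
    tidyr::pivot_longer(cols = c("percent_derived", "percent_derived_filtered"),
                        names_to = "set", values_to = "percent") %>%
    mutate(set = ifelse(.data$set == "percent_derived",
                        "all sequences", "deaminated only"),
           n_lab = ifelse(.data$set == "all sequences",
                          sprintf("%d/%d", .data$n_derived, .data$n_total),
                          sprintf("%d/%d", .data$n_derived_filtered,
                                  .data$n_total_filtered)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$branch, y = .data$percent,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_lab),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.3, size = 3) +
    ggplot2::ylim(0, 105) +
    ggplot2::labs(x = NULL, y = "% sequences supporting the derived state",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
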