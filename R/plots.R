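#' Scatter plot of instrument effects with fitted causal slopes
#'
#' Per-variant exposure effects against outcome effects with +-1 SE bars,
#' overlaid with one line per fitted method (through the origin for IVW and
#' weighted median, with intercept for MR-Egger).
#'
#' @param h A `harmonized` tibble.
#' @param fits A named list of `mr_fit` objects (names become the legend).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, fits = list()) {
  lines <- if (length(fits) > 0) {
    list_rbind(imap(fits, function(f, nm) tibble(
      method = nm,
      intercept = if (is.finite(f$egger_intercept)) f$egger_intercept else 0,
      slope = f$beta
    )))
  } else {
    NULL
  }
  p <- ggplot2::ggplot(as_tibble(h),
                       ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(lines)) {
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$method)
    ) + ggplot2::labs(colour = NULL)
  }
  p
}

#' Forest plot of per-variant Wald ratios or leave-one-out fits
#'
#' @param tbl Either the output of [mr_wald_ratios()] (columns `ratio`,
#'   `se_ratio`) or of [mr_leave_one_out()] (columns `beta`, `se`).
#' @param summary Optional `mr_fit` drawn as a reference line and a summary
#'   row.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(tbl, summary = NULL) {
  if ("ratio" %in% names(tbl)) {
    d <- tibble(label = tbl$variant_id, est = tbl$ratio, se = tbl$se_ratio)
  } else {
    d <- tibble(label = tbl$excluded_variant, est = tbl$beta, se = tbl$se)
  }
  if (!is.null(summary)) {
    d <- bind_rows(d, tibble(label = paste0("All (", summary$method, ")"),
                             est = summary$beta, se = summary$se))
  }
  d$label <- factor(d$label, levels = rev(d$label))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$est, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$est - 1.96 * .data$se,
                                         xmax = .data$est + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal estimate (log odds per SD)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(summary)) {
    p <- p + ggplot2::geom_vline(xintercept = summary$beta,
                                 colour = "steelblue", linetype = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a harmonized instrument set
#' @param object A `harmonized` tibble.
#' @param ... Named `mr_fit` objects passed to [plot_mr_scatter()].
#' @return A ggplot object.
#' @export
autoplot.harmonized <- function(object, ...) {
  plot_mr_scatter(object, fits = list(...))
}
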