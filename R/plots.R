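#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of editing-site sequence context
#'
#' @param object A `cp_context_profile`.
#' @param ... Unused.
#' @return A ggplot: 5' and 3' base frequencies side by side.
#' @export
autoplot.cp_context_profile <- function(object, ...) {
  dat <- tidy(object) %>%
    filter(side != "joint") %>%
    mutate(side = factor(side, levels = c("preceding", "following"),
                         labels = c("5' base", "3' base")))
  ggplot2::ggplot(dat, ggplot2::aes(x = base, y = freq)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~side) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "frequency among editing sites",
                  title = "Sequence context of editing sites") +
    ggplot2::theme_minimal()
}

#' Hydropathy profile with called TM segments
#'
#' @param object A `cp_tm_map`.
#' @param ... Unused.
#' @return A ggplot: windowed hydropathy per residue, threshold line, and
#'   shaded called segments.
#' @export
autoplot.cp_tm_map <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = residue, y = hydropathy)) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "windowed hydropathy",
                  title = if (is.na(object$protein_id)) "Hydropathy profile"
                          else paste("Hydropathy profile:", object$protein_id)) +
    ggplot2::theme_minimal()
  if (nrow(object$segments)) {
    p <- p + ggplot2::geom_rect(
      data = object$segments,
      ggplot2::aes(xmin = start, xmax = end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2
    )
  }
  p
}

#' Bar chart of editing sites per codon position
#'
#' @param sites A site tibble (or a `cp_position_summary`).
#' @return A ggplot.
#' @export
plot_codon_positions <- function(sites) {
  ps <- if (inherits(sites, "cp_position_summary")) sites else summarise_codon_positions(sites)
  ggplot2::ggplot(ps, ggplot2::aes(x = factor(codon_pos), y = n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(pct), "", sprintf("%.2f%%", pct))),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "codon position", y = "editing sites",
                  title = "Editing sites by codon position") +
    ggplot2::theme_minimal()
}
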