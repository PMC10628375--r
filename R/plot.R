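# ggplot2 displays for the result types.

#' Plot per-field percentages of a case report
#'
#' Points for each field's percentage with the case mean drawn as a line;
#' undefined fields are omitted.
#'
#' @param object A `case_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot case_report
#' @export
autoplot.case_report <- function(object, ...) {
  df <- object$fields[!is.na(object$fields$percent), ]
  df$field_id <- factor(df$field_id, levels = unique(df$field_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$field_id, y = .data$percent)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$mean_percent, linetype = "dashed") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(
      x = "field", y = paste0(object$parameter, " (%)"),
      title = sprintf("%s: mean %.2f%%, reportable %d%%, score %d",
                      object$parameter, object$mean_percent,
                      object$reportable_percent, object$score)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the rater cross-tabulation of an agreement result
#'
#' Tile plot of the two raters' score contingency table; the diagonal is the
#' agreement mass.
#'
#' @param object An `agreement_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot agreement_result
#' @export
autoplot.agreement_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater_a, y = .data$rater_b,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "rater A score", y = "rater B score",
      title = sprintf("kappa %.3f (%s), agreement %.1f%%, n = %d",
                      object$kappa, object$interpretation,
                      object$percent_agreement, object$n_items)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cell compositions of a classified field
#'
#' Tile map of the grid with each cell colored by its label; useful for
#' eyeballing a [classify_field()] result against the source image.
#'
#' @param cells A [classify_field()] tibble.
#' @return A ggplot.
#' @export
plot_cell_labels <- function(cells) {
  pal <- c(T = "#b2182b", S = "#1b7837", L = "#2166ac", `NA` = "grey70")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$label)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "label") +
    ggplot2::theme_minimal()
}
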