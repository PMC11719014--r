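#' Plot disabling mutations along the exonic alignment
#'
#' Draws one horizontal lane per screened taxon with its disabling
#' mutations placed at their reported exonic positions, colored by kind
#' and shaped by certainty — the graphical analogue of the stop-position
#' table.
#'
#' @param object A `pseudoscan_screen` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pseudoscan_screen
#' @export
autoplot.pseudoscan_screen <- function(object, ...) {
  muts <- tibble::as_tibble(object) |>
    select("taxon", "call", "mutations") |>
    tidyr::unnest("mutations")
  taxa <- rev(object$taxon)
  p <- ggplot2::ggplot(
    muts,
    ggplot2::aes(x = .data$aln_nt_pos,
                 y = factor(.data$taxon, levels = taxa),
                 colour = .data$kind, shape = .data$certainty)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "exonic position (nt, reference frame)", y = NULL,
                  colour = "lesion", shape = "certainty") +
    ggplot2::theme_minimal()
  p
}

#' @rdname autoplot.pseudoscan_screen
#' @param statuses A `pseudoscan_screen` result.
#' @export
plot_stop_map <- function(statuses) {
  autoplot.pseudoscan_screen(statuses)
}

#' Plot fold changes of a ddCt panel
#'
#' Fold change (log2 scale) per target/reference analysis, with the
#' significance flag mapped to color.
#'
#' @param object A `ddct_panel` tibble from [run_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddct_panel
#' @export
autoplot.ddct_panel <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$target, y = .data$fold_change,
                 fill = .data$significant)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(~reference) +
    ggplot2::labs(x = NULL, y = "fold change (2^-ddCt, log2 scale)") +
    ggplot2::theme_minimal()
}

#' Plot peptide coverage along proteins
#'
#' One lane per protein with the matched peptide spans drawn as segments,
#' showing which parts of each sequence the peptide evidence covers.
#'
#' @param hits Result of [locate_peptides()].
#' @return A ggplot object.
#' @export
plot_peptide_coverage <- function(hits) {
  ggplot2::ggplot(
    hits,
    ggplot2::aes(x = .data$start, xend = .data$end,
                 y = .data$protein, yend = .data$protein)
  ) +
    ggplot2::geom_segment(linewidth = 3, alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = "residue (1-based)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
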