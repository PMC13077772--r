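# ggplot2 views of the main result types.

#' Plot per-position binder contacts for one or more designs
#'
#' @param metrics Tibble of [engagement_metrics()] rows.
#' @return A ggplot: peptide position vs contact count, faceted by design.
#' @export
plot_engagement <- function(metrics) {
  long <- metrics |>
    dplyr::mutate(pp = purrr::map(.data$per_position_contacts, function(v) {
      tibble::tibble(position = as.integer(names(v)), contacts = as.integer(v))
    })) |>
    dplyr::select("design_id", "pp") |>
    tidyr::unnest("pp")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position),
                                     y = .data$contacts)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$design_id)) +
    ggplot2::labs(x = "peptide position", y = "binder heavy-atom contacts") +
    ggplot2::theme_minimal()
}

#' Plot anchor/outward classification of peptide positions
#'
#' @param position_classes Output of [classify_peptide_positions()].
#' @return A ggplot of contact fraction vs relative side-chain SASA,
#'   coloured by class.
#' @export
plot_position_classes <- function(position_classes) {
  ggplot2::ggplot(position_classes,
                  ggplot2::aes(x = .data$sidechain_mhc_contact_fraction,
                               y = .data$relative_sidechain_sasa,
                               colour = .data$class,
                               label = .data$position)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::lims(x = c(0, 1)) +
    ggplot2::labs(x = "side-chain MHC contact fraction",
                  y = "relative side-chain SASA", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a proteome-scan similarity ranking
#'
#' @param hits Output of [scan_proteome()].
#' @param highlight Optional sequence to highlight (e.g. the query).
#' @return A ggplot of similarity by rank.
#' @export
plot_scan <- function(hits, highlight = NULL) {
  hits <- dplyr::mutate(hits, hit = !is.null(highlight) &
                          .data$sequence == highlight)
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$rank, y = .data$similarity)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hit),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "rank", y = "weighted similarity") +
    ggplot2::theme_minimal()
}

#' Plot activation fold-changes over control
#'
#' @param summary Output of [activation_summary()].
#' @return A ggplot of fold-over-control per condition with SD error bars
#'   (propagated on the fold scale).
#' @export
plot_activation <- function(summary) {
  s <- dplyr::mutate(summary,
                     rel_sd = .data$sd_mfi / .data$mean_mfi *
                       .data$fold_over_control)
  ggplot2::ggplot(s, ggplot2::aes(x = stats::reorder(.data$condition,
                                                     -.data$fold_over_control),
                                  y = .data$fold_over_control)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold_over_control -
                                          .data$rel_sd,
                                        ymax = .data$fold_over_control +
                                          .data$rel_sd),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "CD69 MFI fold over control") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
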