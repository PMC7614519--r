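#' Plot catalog summary distributions
#'
#' A three-panel overview of a [catalog_summary()]: variants per
#' backsplice junction, mature-length classes, and mean exon length by
#' exon count.
#'
#' @param object A `circ_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circ_summary <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$variants_per_bsj |>
      dplyr::transmute(panel = "variants per BSJ",
                       x = as.character(.data$size), y = .data$n_bsj),
    object$length_classes |>
      dplyr::transmute(panel = "mature length (nt)",
                       x = .data$length_class, y = .data$n),
    object$exon_stats |>
      dplyr::transmute(panel = "mean exon length by exon count",
                       x = as.character(.data$exon_count),
                       y = .data$mean_exon_length)
  )
  df$x <- factor(df$x, levels = unique(df$x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "count / nt") +
    ggplot2::theme_minimal()
}

#' Plot a polysome fraction profile
#'
#' Percentage of a target's signal in each of the 6 pooled sucrose
#' gradient fractions; pools 1-3 are the ribosome-free/monosome region,
#' pools 4-6 the translating polysomes.
#'
#' @param object A `fraction_profile` (see [fraction_distribution()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fraction_profile <- function(object, ...) {
  tg <- attr(object, "target")
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$pool),
                                       y = .data$percent)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "pooled fraction", y = "% of signal",
      title = if (!is.na(tg)) tg else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Map ORFs around a circular sequence
#'
#' Linearized view of an ORF table from [find_circ_orfs()]: each ORF drawn
#' from its start over its length, with the backsplice junction at
#' position 0/L marked. Infinite ORFs are drawn over one repeat unit.
#'
#' @param orfs ORF tibble for one sequence.
#' @param L Circle length in nt.
#' @return A ggplot object.
#' @export
plot_orf_map <- function(orfs, L) {
  if (nrow(orfs) == 0) abort("no ORFs to plot")
  df <- orfs |>
    dplyr::mutate(
      len = ifelse(.data$is_infinite, 3L * .data$peptide_aa, .data$length_nt),
      orf = sprintf("%d (%d aa%s)", .data$start, .data$peptide_aa,
                    ifelse(.data$is_infinite, ", infinite", "")),
      y = dplyr::row_number()
    )
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$start + .data$len,
      y = .data$y, yend = .data$y, colour = .data$is_infinite
    ), linewidth = 2) +
    ggplot2::geom_vline(xintercept = c(0, L), linetype = "dashed") +
    ggplot2::scale_y_continuous(breaks = df$y, labels = df$orf) +
    ggplot2::labs(x = "circular position (nt; junction at 0/L)", y = NULL,
                  colour = "infinite") +
    ggplot2::theme_minimal()
}
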