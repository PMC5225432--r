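# ggplot2 displays for the main result types.

#' Plot the motif-length composition of a mining run
#'
#' Bar chart of microsatellite counts by motif type, labelled with the
#' class frequencies.
#'
#' @param object An `ssr_composition` tibble from [composition_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssr_composition <- function(object, ...) {
  object$motif_type <- factor(object$motif_type, levels = object$motif_type)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$motif_type, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$frequency)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Microsatellites detected",
                  title = "SSR motif-length composition") +
    ggplot2::theme_minimal()
}

#' Plot per-locus heterozygosity and inbreeding
#'
#' Observed versus expected heterozygosity per locus; the gap between the
#' two is the within-population heterozygote deficit that the inbreeding
#' coefficient summarizes, so strongly inbred populations show H_O far
#' below H_E at most loci.
#'
#' @param object A `locus_stats` tibble from [locus_stats()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.locus_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("locus", "H_O", "H_E")],
    c("H_O", "H_E"), names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(H_E = "grey60", H_O = "grey20")) +
    ggplot2::labs(x = NULL, y = "Heterozygosity", fill = NULL,
                  title = paste0("Heterozygosity by locus",
                                 if (!is.null(attr(object, "population"))) {
                                   paste0(" (", attr(object, "population"), ")")
                                 })) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a sib-mating fit on the F-to-alpha curve
#'
#' The haplodiploid mapping `alpha = 4F/(3F+1)` with each population's
#' multilocus estimate marked on it.
#'
#' @param object A `sibmating_fit` from [infer_sibmating()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sibmating_fit <- function(object, ...) {
  curve <- tibble::tibble(F = seq(0, 1, by = 0.005))
  curve$alpha <- sibmating_from_F(curve$F)
  est <- tidy(object)
  est$F_plot <- pmin(pmax(est$F_multilocus, 0), 1)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$F, y = .data$alpha)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = est, ggplot2::aes(x = .data$F_plot, y = sibmating_from_F(.data$F_plot)),
      colour = "firebrick", size = 2) +
    ggplot2::geom_text(
      data = est,
      ggplot2::aes(x = .data$F_plot, y = sibmating_from_F(.data$F_plot),
                   label = .data$population),
      vjust = 1.8, size = 3) +
    ggplot2::labs(x = "Multilocus inbreeding coefficient F",
                  y = "Sib-mating frequency α",
                  title = "α = 4F / (3F + 1)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
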