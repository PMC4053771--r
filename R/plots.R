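#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Marey map
#'
#' Genetic position against physical position, with masked intervals shaded
#' and imputed grid points drawn in a distinct colour.
#'
#' @param object A `marey_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marey_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  masks <- marey_masks(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_mbp, y = .data$gen_cm))
  if (nrow(masks) > 0) {
    pl <- pl + ggplot2::geom_rect(
      data = masks,
      ggplot2::aes(xmin = .data$start_mbp, xmax = .data$end_mbp,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  pl +
    ggplot2::geom_line(ggplot2::aes(colour = .data$provenance)) +
    ggplot2::scale_colour_manual(
      values = c(observed = "steelblue4", imputed = "firebrick")
    ) +
    ggplot2::labs(x = "Physical position (Mbp)", y = "Genetic position (cM)",
                  title = attr(object, "chrom"))
}

#' Plot a recombination landscape
#'
#' @param object A `recombination_landscape`.
#' @param ... Unused.
#' @return A ggplot of local rate (cM/Mbp) along the chromosome.
#' @export
autoplot.recombination_landscape <- function(object, ...) {
  ylab <- if (isTRUE(attr(object, "normalized"))) {
    "Relative recombination rate"
  } else "Recombination rate (cM/Mbp)"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pos_mbp, y = .data$rate_cm_per_mbp)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Physical position (Mbp)", y = ylab,
                  title = attr(object, "chrom"))
}

#' Plot a segregation-distortion profile
#'
#' A-allele frequency along a chromosome with its null confidence band;
#' distorted markers are highlighted.
#'
#' @param profile Output of [distortion_profile()], one chromosome.
#' @return A ggplot.
#' @export
plot_distortion <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bp / 1e6)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey88") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq_a, colour = .data$distorted),
                        size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Physical position (Mbp)", y = "A-allele frequency")
}

#' Heat map of a pairwise comparison matrix
#'
#' @param pm Result of [pairwise_matrix()].
#' @return A ggplot tile map in clustering order.
#' @export
plot_pairwise_matrix <- function(pm) {
  m <- pm$matrix
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "neglog10_p"))
  names(df)[1:2] <- c("row", "col")
  df$row <- factor(df$row, levels = pm$order)
  df$col <- factor(df$col, levels = pm$order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$neglog10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}
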