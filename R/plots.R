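#' Plot dN versus dS for a set of ortholog pairs
#'
#' Scatter of per-gene dN against dS with point radius proportional to ORF
#' size; genes at or above the relaxed-selection threshold are drawn in
#' red, the rest in green, and the mean dN/dS ratio is shown as a dotted
#' grey line through the origin.
#'
#' @param estimates Tibble from [dnds_pairs()] or the `estimates` element
#'   of a [screen_cryptic()] result.
#' @param threshold Flagging threshold on omega (default 0.3).
#' @return A ggplot object.
#' @export
plot_dnds <- function(estimates, threshold = 0.3) {
  d <- dplyr::filter(estimates, !is.na(.data$dS), !is.na(.data$dN))
  d$set <- ifelse(!is.na(d$omega) & d$omega >= threshold,
                  sprintf("omega >= %.1f", threshold),
                  sprintf("omega < %.1f", threshold))
  mean_omega <- mean(d$omega[is.finite(d$omega)], na.rm = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dS, y = .data$dN)) +
    ggplot2::geom_abline(slope = mean_omega, intercept = 0,
                         linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$orf_len_nt,
                                     colour = .data$set), alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = setNames(c("#d7301f", "#238b45"),
                        c(sprintf("omega >= %.1f", threshold),
                          sprintf("omega < %.1f", threshold)))) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = "dS", y = "dN", size = "ORF length (nt)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of synteny blocks
#'
#' Reference versus derived coordinates of each block, coloured by strand
#' orientation (and line-typed by symmetry class when present); the visual
#' analogue of a whole-genome match plot.
#'
#' @param blocks Tibble from [chain_blocks()] or [synteny_map()].
#' @return A ggplot object.
#' @export
plot_synteny <- function(blocks) {
  b <- blocks
  p <- ggplot2::ggplot(b) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ref_start, xend = .data$ref_end,
                   y = ifelse(.data$orientation == "same_strand",
                              .data$der_start, .data$der_end),
                   yend = ifelse(.data$orientation == "same_strand",
                                 .data$der_end, .data$der_start),
                   colour = .data$orientation),
      linewidth = 1.2) +
    ggplot2::scale_colour_manual(
      values = c(same_strand = "#6a51a3", opposite_strand = "#ec7014")) +
    ggplot2::labs(x = "reference position (bp)",
                  y = "derived position (bp)", colour = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Plot a GC skew track
#'
#' Windowed skew with positive windows in red and negative in blue;
#' optional ori/ter marks.
#'
#' @param track Tibble from [gc_skew()].
#' @param ori,ter Optional positions to mark.
#' @return A ggplot object.
#' @export
plot_gc_skew <- function(track, ori = NULL, ter = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = .data$skew)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$skew > 0), width = 1,
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#cb181d",
                                          `FALSE` = "#2171b5")) +
    ggplot2::labs(x = "position (bp)", y = "(G - C)/(G + C)") +
    ggplot2::theme_minimal()
  if (!is.null(ori)) p <- p + ggplot2::geom_vline(xintercept = ori,
                                                  linetype = "dashed")
  if (!is.null(ter)) p <- p + ggplot2::geom_vline(xintercept = ter,
                                                  linetype = "dotted")
  p
}
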