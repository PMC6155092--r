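#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a k-mer occurrence histogram
#'
#' @param object a `kmer_hist`.
#' @param peaks optional [find_peaks()] result to annotate.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.kmer_hist <- function(object, peaks = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth,
                                        y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = "occurrence depth", y = "distinct k-mers",
                  title = sprintf("%d-mer histogram", attr(object, "k"))) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    vl <- tidy(peaks)
    vl <- vl[!is.na(vl$depth), ]
    p <- p + ggplot2::geom_vline(data = vl,
                                 ggplot2::aes(xintercept = .data$depth),
                                 linetype = "dashed", colour = "red3")
  }
  p
}

#' Dot plot of pairwise alignment blocks
#'
#' Forward blocks rise (bluish), reverse blocks fall (reddish), matching
#' the usual rendering of whole-locus comparisons.
#'
#' @param object an `alignment_blocks` tibble.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.alignment_blocks <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$y1 <- ifelse(df$orientation == "forward", df$s_start, df$s_end)
  df$y2 <- ifelse(df$orientation == "forward", df$s_end, df$s_start)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$q_start,
                                       xend = .data$q_end,
                                       y = .data$y1, yend = .data$y2,
                                       colour = .data$orientation),
                          linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(forward = "steelblue4",
                                            reverse = "red3")) +
    ggplot2::labs(x = "query (bp)", y = "subject (bp)") +
    ggplot2::theme_minimal()
}

#' Window-link heat map for mate-pair validation
#'
#' @param object a [window_link_matrix()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.window_links <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df2 <- df[df$window_i != df$window_j,
            c("window_j", "window_i", "links")]
  names(df2) <- c("window_i", "window_j", "links")
  ggplot2::ggplot(dplyr::bind_rows(df, df2),
                  ggplot2::aes(x = .data$window_i, y = .data$window_j,
                               fill = .data$links)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "window", y = "window",
                  fill = sprintf(">= %d links",
                                 attr(object, "min_links"))) +
    ggplot2::theme_minimal()
}

#' Marker association plot along a scaffold
#'
#' @param object an `association_records` tibble.
#' @param interval optional [delimit_region()] result to shade.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.association_records <- function(object, interval = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos,
                                        y = .data$recombinant_count,
                                        colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(complete = "forestgreen",
                                            incomplete = "grey40")) +
    ggplot2::labs(x = "position (bp)", y = "recombinants") +
    ggplot2::theme_minimal()
  if (!is.null(interval)) {
    p <- p + ggplot2::annotate("rect", xmin = interval$start,
                               xmax = interval$end, ymin = -Inf,
                               ymax = Inf, alpha = 0.15,
                               fill = "forestgreen")
  }
  p
}
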