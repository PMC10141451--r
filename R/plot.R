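#' Plot track items along the genome
#'
#' Draws each track item's blocks as segments along its chromosome, one facet
#' per chromosome, colored by strand; multi-miRNA (asterisked) regions are
#' labelled. A quick visual check that projected binding sites land where
#' expected.
#'
#' @param object a track-item tibble (`mirtrack_track`) or `mirtrack_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mirtrack_track
#' @export
autoplot.mirtrack_track <- function(object, ...) {
  if (nrow(object) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no track items"))
  }
  d <- object %>%
    dplyr::mutate(row = dplyr::row_number()) %>%
    dplyr::mutate(blocks = purrr::map2(.data$block_sizes, .data$block_starts,
                                       parse_bed_blocks),
                  g0 = .data$start) %>%
    tidyr::unnest("blocks") %>%
    dplyr::mutate(bs = .data$g0 + .data$rel_start,
                  be = .data$bs + .data$size)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$bs, xend = .data$be, y = .data$label,
                   yend = .data$label, color = .data$strand),
      linewidth = 3
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "genomic position (bp)", y = NULL,
                  title = "Consensus miRNA binding-site track") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mirtrack_track
#' @method autoplot mirtrack_result
#' @export
autoplot.mirtrack_result <- function(object, ...) {
  autoplot.mirtrack_track(object$items, ...)
}

parse_bed_blocks <- function(sizes, starts) {
  tibble::tibble(
    size = as.integer(strsplit(sizes, ",", fixed = TRUE)[[1]]),
    rel_start = as.integer(strsplit(starts, ",", fixed = TRUE)[[1]])
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
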