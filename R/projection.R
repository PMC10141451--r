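#' Transcript-order exon offset table
#'
#' For each exon, in transcript order (5'->3' along the mature transcript,
#' which is reverse genomic order on the minus strand), gives its cumulative
#' transcript-space start offset. The offsets' total equals the spliced
#' length.
#'
#' @param model one row of a transcript model tibble.
#' @return a tibble with genomic `start`/`end` and `t_offset` per exon, in
#'   transcript order.
#' @export
build_coordinate_map <- function(model) {
  stopifnot(nrow(model) == 1L)
  exons <- model$exons[[1]]
  if (model$strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  len <- exons$end - exons$start
  tibble::tibble(
    start = exons$start,
    end = exons$end,
    t_offset = cumsum(c(0L, len[-length(len)]))
  )
}

#' Project a transcript interval onto genome blocks
#'
#' Maps a 0-based half-open interval on the mature transcript to the genomic
#' blocks it covers, splitting at every exon junction inside the interval.
#' On the minus strand, transcript offset 0 maps to the model's highest
#' genomic coordinate. Blocks are returned in genomic ascending order (as BED
#' requires) regardless of transcript order.
#'
#' @param model one row of a transcript model tibble.
#' @param t_start,t_end transcript interval, 0-based half-open.
#' @return a list with `chrom`, `strand`, `blocks` (tibble of genomic
#'   `start`/`end`) and `block_count`.
#' @export
transcript_to_genome <- function(model, t_start, t_end) {
  if (t_start < 0L || t_end > model$spliced_length || t_start >= t_end) {
    abort(sprintf("interval [%d,%d) out of range for transcript '%s' (length %d)",
                  t_start, t_end, model$transcript_id, model$spliced_length),
          class = "mirtrack_bounds_error")
  }
  map <- build_coordinate_map(model)
  len <- map$end - map$start
  minus <- model$strand == "-"
  blocks <- purrr::pmap(map, function(start, end, t_offset) {
    lo <- max(t_start, t_offset)
    hi <- min(t_end, t_offset + (end - start))
    if (lo >= hi) return(NULL)
    if (!minus) {
      gs <- start + (lo - t_offset)
      ge <- start + (hi - t_offset)
    } else {
      # transcript runs 3'->5' in genome space: offset 0 is the exon's end
      gs <- end - (hi - t_offset)
      ge <- end - (lo - t_offset)
    }
    tibble::tibble(start = gs, end = ge)
  })
  blocks <- dplyr::bind_rows(purrr::compact(blocks))
  blocks <- dplyr::arrange(blocks, .data$start)
  if (nrow(blocks) > 2L) {
    warn(sprintf("site [%d,%d) on '%s' spans %d exons (blockCount > 2)",
                 t_start, t_end, model$transcript_id, nrow(blocks)))
  }
  list(chrom = model$chrom, strand = model$strand,
       blocks = blocks, block_count = nrow(blocks))
}

#' Map a genomic position back to a transcript offset
#'
#' Exact inverse of the per-base forward map; returns `NA` for intronic or
#' extragenic positions.
#'
#' @param model one row of a transcript model tibble.
#' @param g_pos 0-based genomic position.
#' @return 0-based transcript offset, or `NA_integer_`.
#' @export
genome_to_transcript <- function(model, g_pos) {
  map <- build_coordinate_map(model)
  hit <- which(g_pos >= map$start & g_pos < map$end)
  if (length(hit) == 0L) return(NA_integer_)
  i <- hit[[1]]
  if (model$strand == "+") {
    as.integer(map$t_offset[i] + (g_pos - map$start[i]))
  } else {
    as.integer(map$t_offset[i] + (map$end[i] - 1L - g_pos))
  }
}

#' Project consensus sites onto the genome
#'
#' Applies [transcript_to_genome()] to every consensus core and attaches gene
#' metadata from the transcript models.
#'
#' @param consensus consensus-site tibble from [consensus_all()].
#' @param models transcript model tibble.
#' @return `consensus` with `gene_id`, `gene_name`, `chrom`, `strand`,
#'   `g_start`, `g_end`, `block_count` and a `blocks` list-column.
#' @export
project_consensus <- function(consensus, models) {
  if (nrow(consensus) == 0L) {
    return(dplyr::mutate(consensus, gene_id = character(), gene_name = character(),
                         chrom = character(), strand = character(),
                         g_start = integer(), g_end = integer(),
                         block_count = integer(), blocks = list()))
  }
  idx <- match(consensus$transcript_id, models$transcript_id)
  if (anyNA(idx)) {
    abort(sprintf("no model for transcript '%s'",
                  consensus$transcript_id[which(is.na(idx))[1]]),
          class = "mirtrack_contract_error")
  }
  proj <- purrr::pmap(list(idx, consensus$core_start, consensus$core_end),
                      function(i, s, e) transcript_to_genome(models[i, ], s, e))
  consensus %>%
    dplyr::mutate(
      gene_id = models$gene_id[idx],
      gene_name = models$gene_name[idx],
      chrom = purrr::map_chr(proj, "chrom"),
      strand = purrr::map_chr(proj, "strand"),
      g_start = purrr::map_int(proj, ~ min(.x$blocks$start)),
      g_end = purrr::map_int(proj, ~ max(.x$blocks$end)),
      block_count = purrr::map_int(proj, "block_count"),
      blocks = purrr::map(proj, "blocks")
    )
}
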