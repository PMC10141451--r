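#' Default canonical chromosome set
#'
#' chr1-chr22, chrX, chrY and chrM, matching common GRCh38 practice. The
#' canonical set is configuration: pass any character vector to
#' [filter_canonical()].
#'
#' @return character vector of chromosome names.
#' @export
canonical_chromosomes <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY", "chrM")
}

# Validate the raw GTF text cheaply so malformed lines can be reported with
# their line number (rtracklayer's parser does not).
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nfields <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nfields < 9L)) {
    bad <- which(keep)[which(nfields < 9L)[1]]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  bad, nfields[which(nfields < 9L)[1]]),
          class = "mirtrack_format_error")
  }
  invisible(TRUE)
}

#' Read transcript models from a GTF file
#'
#' Parses exon features and assembles one model per `transcript_id`. GTF
#' 1-based closed coordinates are converted to the package's internal 0-based
#' half-open convention on read. Exons are sorted in genomic ascending order.
#' Transcripts whose exons mix chromosomes or strands are rejected with a
#' warning naming the transcript.
#'
#' @param path path to a GTF file whose exon features carry `transcript_id`,
#'   `gene_id` and `gene_name` attributes.
#' @return a tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `exons` (list-column of tibbles with
#'   0-based half-open `start`/`end`), and `spliced_length`.
#' @export
read_transcript_models <- function(path) {
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ex <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GRanges keeps GTF 1-based closed; internal convention is 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    gene_name = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  )
  models <- ex %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::group_map(function(d, key) {
      tid <- key$transcript_id[[1]]
      if (dplyr::n_distinct(d$chrom) > 1L || dplyr::n_distinct(d$strand) > 1L) {
        warn(sprintf("transcript '%s' rejected: exons on mixed chromosomes or strands", tid))
        return(NULL)
      }
      exons <- d %>%
        dplyr::arrange(.data$start) %>%
        dplyr::select("start", "end")
      if (any(exons$end[-nrow(exons)] > exons$start[-1])) {
        warn(sprintf("transcript '%s' rejected: overlapping exons", tid))
        return(NULL)
      }
      slen <- sum(exons$end - exons$start)
      tibble::tibble(
        transcript_id = tid,
        gene_id = d$gene_id[[1]],
        gene_name = d$gene_name[[1]],
        chrom = d$chrom[[1]],
        strand = d$strand[[1]],
        exons = list(exons),
        spliced_length = slen
      )
    }) %>%
    purrr::compact() %>%
    dplyr::bind_rows()
  dplyr::arrange(models, .data$chrom,
                 purrr::map_int(.data$exons, ~ .x$start[[1]]),
                 .data$transcript_id)
}

#' Keep only transcripts on canonical chromosomes
#'
#' @param models transcript model tibble from [read_transcript_models()].
#' @param canonical_chroms character vector of accepted chromosome names
#'   (default [canonical_chromosomes()]).
#' @return the subset of `models` on canonical chromosomes, order preserved.
#' @export
filter_canonical <- function(models, canonical_chroms = canonical_chromosomes()) {
  if (length(canonical_chroms) == 0L) {
    abort("`canonical_chroms` must be non-empty", class = "mirtrack_contract_error")
  }
  dplyr::filter(models, .data$chrom %in% canonical_chroms)
}

#' Extract a model's mature spliced sequence from a genome
#'
#' Concatenates exon subsequences in transcript order and transliterates to
#' RNA. On the minus strand the transcript reads the reverse complement of the
#' descending-order exon concatenation.
#'
#' @param model one row of a transcript model tibble.
#' @param genome named character vector of chromosome DNA sequences.
#' @return the mature transcript RNA sequence (character scalar).
#' @export
spliced_sequence <- function(model, genome) {
  stopifnot(nrow(model) == 1L)
  chrom_seq <- genome[[model$chrom]]
  if (is.null(chrom_seq)) {
    abort(sprintf("chromosome '%s' absent from genome", model$chrom),
          class = "mirtrack_bounds_error")
  }
  exons <- model$exons[[1]]
  if (max(exons$end) > nchar(chrom_seq)) {
    abort(sprintf("transcript '%s' exon exceeds chromosome '%s' length",
                  model$transcript_id, model$chrom),
          class = "mirtrack_bounds_error")
  }
  pieces <- substring(chrom_seq, exons$start + 1L, exons$end)
  plus <- dna_to_rna(paste(pieces, collapse = ""))
  if (model$strand == "+") plus else rc_rna(plus)
}

#' Assemble a validated transcriptome
#'
#' Joins transcript models with their mature sequences and checks that every
#' sequence length equals its model's spliced length.
#'
#' @param models transcript model tibble.
#' @param sequences tibble with `id`, `seq` (RNA) as from [read_fasta()], ids
#'   matching `transcript_id`s.
#' @return `models` with an additional `seq` column.
#' @export
build_transcriptome <- function(models, sequences) {
  out <- dplyr::inner_join(models,
                           dplyr::rename(sequences, transcript_id = "id"),
                           by = "transcript_id")
  bad <- nchar(out$seq) != out$spliced_length
  if (any(bad)) {
    abort(sprintf("transcript '%s': sequence length %d != spliced length %d",
                  out$transcript_id[which(bad)[1]],
                  nchar(out$seq[which(bad)[1]]),
                  out$spliced_length[which(bad)[1]]),
          class = "mirtrack_contract_error")
  }
  missing <- setdiff(models$transcript_id, sequences$id)
  if (length(missing) > 0L) {
    warn(sprintf("%d transcript model(s) had no sequence record (e.g. '%s') and were dropped",
                 length(missing), missing[[1]]))
  }
  out
}

#' Serialize transcript models to GTF
#'
#' Writes one exon feature per exon, converting back to GTF 1-based closed
#' coordinates. Round-trips with [read_transcript_models()].
#'
#' @param models transcript model tibble.
#' @param path output path.
#' @param source feature source field.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "mirtrack") {
  lines <- purrr::pmap(models, function(transcript_id, gene_id, gene_name,
                                        chrom, strand, exons, spliced_length, ...) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     gene_id, transcript_id, gene_name)
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
            chrom, source, exons$start + 1L, exons$end, strand, attrs)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}
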