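#' Run all three predictor engines over a transcriptome
#'
#' For every (miRNA, transcript) pair, runs the seed classifier
#' ([scan_seed_sites()]), the complementarity aligner ([align_miranda()]) and
#' the accessibility scorer ([scan_pita_sites()]), pooling their candidate
#' sites into one tibble. Engines can be restricted, and native predictor
#' output parsed with [parse_native_output()] can be substituted for any
#' engine by binding rows before [consensus_all()].
#'
#' @param transcriptome tibble from [build_transcriptome()] (models + `seq`).
#' @param mirnas tibble from [read_mirnas()].
#' @param engines subset of `c("targetscan", "miranda", "pita")`.
#' @param miranda_params parameters for the aligner.
#' @param flank flanking width for the accessibility backend.
#' @return a pooled candidate-site tibble.
#' @export
predict_sites <- function(transcriptome, mirnas,
                          engines = c("targetscan", "miranda", "pita"),
                          miranda_params = mirtrack::miranda_params(),
                          flank = 35L) {
  engines <- match.arg(engines, several.ok = TRUE)
  pairs <- tidyr::expand_grid(
    ti = seq_len(nrow(transcriptome)),
    mi = seq_len(nrow(mirnas))
  )
  out <- purrr::pmap(pairs, function(ti, mi) {
    tid <- transcriptome$transcript_id[[ti]]
    tseq <- transcriptome$seq[[ti]]
    mid <- mirnas$mirna_id[[mi]]
    mseq <- mirnas$seq[[mi]]
    res <- list()
    if ("targetscan" %in% engines) {
      res$ts <- scan_seed_sites(mid, mseq, tid, tseq)
    }
    if ("miranda" %in% engines) {
      res$mi <- align_miranda(mid, mseq, tid, tseq, params = miranda_params)
    }
    if ("pita" %in% engines) {
      res$pi <- scan_pita_sites(mid, mseq, tid, tseq, flank = flank)
    }
    dplyr::bind_rows(res)
  })
  dplyr::bind_rows(out)
}

#' Run the full binding-site pipeline on input files
#'
#' End-to-end convenience wrapper: parses the GTF and FASTA inputs, applies
#' the canonical-chromosome filter, predicts candidate sites with the three
#' engines, calls consensus, projects consensus cores onto the genome and
#' merges them into track items; optionally writes the bedDetail track, the
#' flat CSV and the per-item HTML detail pages.
#'
#' @param gtf path to the transcript-model GTF.
#' @param transcripts_fasta path to mature transcript sequences (FASTA).
#' @param mirnas_fasta path to mature miRNA sequences (FASTA).
#' @param canonical_chroms canonical chromosome set.
#' @param thresholds retention thresholds from [threshold_config()].
#' @param miranda_params aligner parameters.
#' @param bed,csv,details_dir optional output paths; written when non-NULL.
#' @return an object of class `mirtrack_result`: a list with `items` (track
#'   tibble), `consensus`, `sites`, `models` and `config`.
#' @export
run_pipeline <- function(gtf, transcripts_fasta, mirnas_fasta,
                         canonical_chroms = canonical_chromosomes(),
                         thresholds = threshold_config(),
                         miranda_params = mirtrack::miranda_params(),
                         bed = NULL, csv = NULL, details_dir = NULL) {
  models <- read_transcript_models(gtf) %>%
    filter_canonical(canonical_chroms)
  transcriptome <- build_transcriptome(models,
                                       read_fasta(transcripts_fasta, "RNA"))
  mirnas <- read_mirnas(mirnas_fasta)
  sites <- predict_sites(transcriptome, mirnas,
                         miranda_params = miranda_params)
  consensus <- consensus_all(sites, thresholds)
  projected <- project_consensus(consensus, models)
  items <- merge_identical_regions(projected)
  if (!is.null(bed)) write_beddetail(items, bed)
  if (!is.null(csv)) write_track_csv(items, csv)
  if (!is.null(details_dir)) write_detail_pages(items, details_dir)
  structure(
    list(items = items, consensus = consensus, sites = sites,
         models = models, config = thresholds),
    class = "mirtrack_result"
  )
}

#' @export
print.mirtrack_result <- function(x, ...) {
  cat("Consensus miRNA binding-site track\n")
  cat(sprintf("  transcripts: %d\n", nrow(x$models)))
  cat(sprintf("  candidate sites (all engines): %d\n", nrow(x$sites)))
  cat(sprintf("  consensus sites: %d\n", nrow(x$consensus)))
  cat(sprintf("  track items (deduplicated regions): %d\n", nrow(x$items)))
  invisible(x)
}

#' Tidy the per-pair evidence behind a pipeline result
#'
#' One row per (miRNA, transcript) member pair of every track item, i.e. the
#' flat CSV as a tibble with the item's genomic region attached.
#'
#' @param x a `mirtrack_result`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy mirtrack_result
#' @export
tidy.mirtrack_result <- function(x, ...) {
  items <- x$items
  if (nrow(items) == 0L) {
    return(tibble::tibble(item_id = character()))
  }
  items %>%
    dplyr::select("item_id", "chrom", "strand", "start", "end",
                  "block_count", "members") %>%
    tidyr::unnest("members")
}

#' One-row summary of a pipeline result
#'
#' @param x a `mirtrack_result`.
#' @param ... unused.
#' @return a one-row tibble with counts of transcripts, miRNAs observed in
#'   consensus, candidate sites, consensus sites, track items and multi-miRNA
#'   (asterisked) items.
#' @method glance mirtrack_result
#' @export
glance.mirtrack_result <- function(x, ...) {
  tibble::tibble(
    n_transcripts = nrow(x$models),
    n_mirnas = dplyr::n_distinct(x$consensus$mirna_id),
    n_candidate_sites = nrow(x$sites),
    n_consensus_sites = nrow(x$consensus),
    n_track_items = nrow(x$items),
    n_shared_regions = sum(grepl("\\*$", x$items$label))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
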