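#' Merge projected consensus sites into deduplicated track items
#'
#' Sites whose projections give exactly the same genomic region — same
#' chromosome, strand and block tuple — are annotated as a single track item,
#' whatever mix of transcripts (of the same gene or not) and miRNAs they come
#' from. The item label is the lexicographically first member miRNA name,
#' with a trailing `*` when two or more distinct miRNAs share the region.
#' Items are numbered `MBS` + 8-digit zero-padded ordinal in sorted genomic
#' order; the id keys the item's detail record.
#'
#' @param projected projected consensus tibble from [project_consensus()].
#' @return a track-item tibble (class `mirtrack_track`): one row per distinct
#'   region with `item_id`, `chrom`, `start`, `end`, `strand`, `label`,
#'   `block_count`, BED-style `block_sizes`/`block_starts` strings, `mirnas`
#'   (comma-separated distinct member miRNAs) and a `members` list-column
#'   holding the per-(miRNA, transcript) evidence rows.
#' @export
merge_identical_regions <- function(projected) {
  if (nrow(projected) == 0L) {
    return(new_track(tibble::tibble(
      item_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), label = character(),
      block_count = integer(), block_sizes = character(),
      block_starts = character(), mirnas = character(), members = list()
    )))
  }
  projected <- dplyr::mutate(projected,
    region_key = paste(.data$chrom, .data$strand,
                       purrr::map_chr(.data$blocks, block_signature),
                       sep = "|"))
  items <- projected %>%
    dplyr::group_by(.data$region_key) %>%
    dplyr::group_map(function(d, key) {
      blocks <- d$blocks[[1]]
      members <- d %>%
        dplyr::select("mirna_id", "transcript_id", "gene_id", "gene_name",
                      "core_start", "core_end",
                      "ts_start", "ts_end", "site_type",
                      "pi_start", "pi_end", "ddg",
                      "mi_start", "mi_end", "binding_energy",
                      "alignment_score", "alignment_text") %>%
        dplyr::arrange(.data$mirna_id, .data$transcript_id)
      tibble::tibble(
        chrom = d$chrom[[1]],
        start = min(blocks$start),
        end = max(blocks$end),
        strand = d$strand[[1]],
        label = item_label(members$mirna_id),
        block_count = nrow(blocks),
        block_sizes = paste0(paste(blocks$end - blocks$start, collapse = ","), ","),
        block_starts = paste0(paste(blocks$start - min(blocks$start), collapse = ","), ","),
        mirnas = paste(sort(unique(members$mirna_id), method = "radix"),
                       collapse = ","),
        members = list(members)
      )
    }) %>%
    dplyr::bind_rows() %>%
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand,
                   .data$block_sizes, .data$block_starts)
  items <- dplyr::mutate(items,
                         item_id = sprintf("MBS%08d", dplyr::row_number()),
                         .before = 1L)
  new_track(items)
}

block_signature <- function(blocks) {
  paste(sprintf("%d-%d", blocks$start, blocks$end), collapse = ",")
}

item_label <- function(mirna_ids) {
  u <- sort(unique(mirna_ids), method = "radix")
  paste0(u[[1]], if (length(u) >= 2L) "*" else "")
}

new_track <- function(x) {
  class(x) <- unique(c("mirtrack_track", class(x)))
  x
}

#' Write track items as a UCSC bedDetail custom track
#'
#' Emits a `track type=bedDetail` header followed by one line per item with
#' 14 tab-separated columns: chrom, chromStart (0-based), chromEnd, label,
#' score (0, unused), strand, thickStart (= chromStart), thickEnd
#' (= chromEnd), RGB `255,255,0`, blockCount, blockSizes, blockStarts, the
#' item id linking to its detail page, and the comma-separated list of all
#' member miRNAs.
#'
#' @param items track-item tibble, sorted by (chrom, start).
#' @param path output file path.
#' @param name,description track header attributes.
#' @return number of data lines written, invisibly.
#' @export
write_beddetail <- function(items, path, name = "miRNA binding sites",
                            description = "Consensus miRNA binding sites") {
  if (nrow(items) > 1L) {
    o <- order(items$chrom, items$start, method = "radix")
    if (!identical(o, seq_len(nrow(items)))) {
      abort("items must be sorted by (chrom, start)", class = "mirtrack_contract_error")
    }
  }
  header <- sprintf('track type=bedDetail name="%s" description="%s" itemRgb="On"',
                    name, description)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t255,255,0\t%d\t%s\t%s\t%s\t%s",
                   items$chrom, items$start, items$end, items$label,
                   items$strand, items$start, items$end, items$block_count,
                   items$block_sizes, items$block_starts, items$item_id,
                   items$mirnas)
  writeLines(c(header, lines), path)
  invisible(length(lines))
}

fmt_energy <- function(x) sprintf("%.2f", x)
fmt_score <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))), sprintf("%.2f", x))
}
# 1-based inclusive range for human display
fmt_range <- function(s, e) sprintf("%d-%d", s + 1L, e)

#' Structured detail rows for a track item
#'
#' The six-column evidence table behind one track item: one row per member
#' (miRNA, transcript) pair with the miRNA, the transcript, the seed engine's
#' details (transcript range, 1-based inclusive, and site type), the
#' accessibility engine's details (range and ddG), the alignment engine's
#' details (range, energy and score) and the miRanda-style alignment
#' schematization.
#'
#' @param item one row of a track-item tibble.
#' @return a tibble with columns `mirna`, `transcript`, `targetscan_details`,
#'   `pita_details`, `miranda_details`, `alignment`.
#' @export
detail_records <- function(item) {
  stopifnot(nrow(item) == 1L)
  m <- item$members[[1]]
  if (nrow(m) == 0L) {
    abort("track item has no members", class = "mirtrack_contract_error")
  }
  tibble::tibble(
    mirna = m$mirna_id,
    transcript = m$transcript_id,
    targetscan_details = sprintf("range %s; site type %s",
                                 fmt_range(m$ts_start, m$ts_end), m$site_type),
    pita_details = sprintf("range %s; ddG %s kcal/mol",
                           fmt_range(m$pi_start, m$pi_end), fmt_energy(m$ddg)),
    miranda_details = sprintf("range %s; energy %s kcal/mol; score %s",
                              fmt_range(m$mi_start, m$mi_end),
                              fmt_energy(m$binding_energy),
                              fmt_score(m$alignment_score)),
    alignment = m$alignment_text
  )
}

#' Render one track item's detail page as an HTML document
#'
#' @param item one row of a track-item tibble.
#' @return a single character scalar of HTML with one table (header plus one
#'   row per member pair, six columns).
#' @export
render_detail_record <- function(item) {
  rec <- detail_records(item)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  headers <- c("miRNA", "Transcript", "TargetScan prediction",
               "PITA prediction", "miRanda prediction", "Alignment")
  head_row <- paste0("<tr>", paste0("<th>", headers, "</th>", collapse = ""), "</tr>")
  body <- purrr::pmap_chr(rec, function(mirna, transcript, targetscan_details,
                                        pita_details, miranda_details, alignment) {
    cells <- c(esc(mirna), esc(transcript), esc(targetscan_details),
               esc(pita_details), esc(miranda_details),
               paste0("<pre>", esc(alignment), "</pre>"))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  })
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>",
    esc(item$item_id), "</title></head>\n<body>\n<h1>", esc(item$item_id),
    "</h1>\n<p>", esc(item$chrom), ":", item$start + 1L, "-", item$end,
    " (", esc(item$strand), ")</p>\n<table border=\"1\">\n",
    head_row, "\n", paste(body, collapse = "\n"), "\n</table>\n</body></html>\n"
  )
}

#' Write one HTML detail page per track item
#'
#' Pages are named `<item_id>.html` in `dir`, mirroring the per-site external
#' pages linked from the bedDetail track.
#'
#' @param items track-item tibble.
#' @param dir output directory (created if needed).
#' @return number of pages written, invisibly.
#' @export
write_detail_pages <- function(items, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(items))) {
    item <- items[i, ]
    writeLines(render_detail_record(item),
               file.path(dir, paste0(item$item_id, ".html")),
               sep = "")
  }
  invisible(nrow(items))
}

#' Write the flat semicolon-separated summary CSV
#'
#' One row per (member pair, item) with 14 semicolon-separated columns:
#' transcript Ensembl ID; gene Ensembl ID; gene name; miRNA; binding-region
#' start and end within the transcript (1-based inclusive); chromosome;
#' strand; genomic start (0-based, as in the bedDetail track) and end; seed
#' site type; ddG; miRanda binding energy; miRanda score. A header row is
#' included.
#'
#' @param items track-item tibble.
#' @param path output file path.
#' @return number of data rows written, invisibly.
#' @export
write_track_csv <- function(items, path) {
  header <- paste(c("transcript_id", "gene_id", "gene_name", "mirna_id",
                    "t_start", "t_end", "chrom", "strand", "g_start", "g_end",
                    "targetscan_site_type", "pita_ddg", "miranda_energy",
                    "miranda_score"), collapse = ";")
  rows <- character()
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    m <- it$members[[1]]
    rows <- c(rows, sprintf("%s;%s;%s;%s;%d;%d;%s;%s;%d;%d;%s;%s;%s;%s",
                            m$transcript_id, m$gene_id, m$gene_name, m$mirna_id,
                            m$core_start + 1L, m$core_end,
                            it$chrom, it$strand, it$start, it$end,
                            m$site_type, fmt_energy(m$ddg),
                            fmt_energy(m$binding_energy),
                            fmt_score(m$alignment_score)))
  }
  writeLines(c(header, rows), path)
  invisible(length(rows))
}

#' Read the flat CSV back into a tibble
#'
#' Inverse of [write_track_csv()] for round-tripping; numeric score fields
#' are kept as the decimal strings that were written.
#'
#' @param path CSV path.
#' @return a tibble with the 14 columns as character.
#' @export
read_track_csv <- function(path) {
  readr::read_delim(path, delim = ";", col_types = readr::cols(.default = "c"),
                    progress = FALSE)
}

#' Filter track items by miRNA and/or gene
#'
#' Retains items having at least one member matching all given filters,
#' prunes members to the matching ones, and recomputes labels (so an asterisk
#' item filtered down to one miRNA loses its asterisk) and the member-miRNA
#' list. Item ids are preserved so links to detail pages stay valid.
#'
#' @param items track-item tibble.
#' @param by_mirna optional character vector of miRNA names.
#' @param by_gene optional character vector of gene names or gene ids.
#' @return the filtered track-item tibble.
#' @export
filter_track <- function(items, by_mirna = NULL, by_gene = NULL) {
  if (is.null(by_mirna) && is.null(by_gene)) {
    abort("give at least one of `by_mirna` or `by_gene`",
          class = "mirtrack_usage_error")
  }
  out <- items %>%
    dplyr::mutate(members = purrr::map(.data$members, function(m) {
      keep <- rep(TRUE, nrow(m))
      if (!is.null(by_mirna)) keep <- keep & m$mirna_id %in% by_mirna
      if (!is.null(by_gene)) {
        keep <- keep & (m$gene_name %in% by_gene | m$gene_id %in% by_gene)
      }
      m[keep, , drop = FALSE]
    })) %>%
    dplyr::filter(purrr::map_int(.data$members, nrow) > 0L) %>%
    dplyr::mutate(
      label = purrr::map_chr(.data$members, ~ item_label(.x$mirna_id)),
      mirnas = purrr::map_chr(.data$members, ~ paste(
        sort(unique(.x$mirna_id), method = "radix"), collapse = ","))
    )
  new_track(out)
}
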