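#' Read a FASTA file into a tibble
#'
#' Thin tidy wrapper around [Biostrings::readBStringSet()]. Record ids are the
#' first whitespace-delimited token of each header; sequences are uppercased
#' and, for the RNA alphabet, T is transliterated to U.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param alphabet `"DNA"` or `"RNA"`. RNA transliterates T to U; both validate
#'   the resulting characters against their alphabet.
#' @return a tibble with columns `id` and `seq`, in order of first occurrence.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x some desc", "acg", "t"), fa)
#' read_fasta(fa, alphabet = "RNA")
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble::tibble(id = character(), seq = character()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (alphabet == "RNA") seqs <- chartr("T", "U", seqs)
  allowed <- if (alphabet == "RNA") "ACGUN" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    abort(sprintf("record '%s' contains characters outside the %s alphabet",
                  ids[which(bad)[1]], alphabet),
          class = "mirtrack_format_error")
  }
  if (any(!nzchar(seqs))) {
    abort(sprintf("record '%s' has an empty sequence", ids[which(!nzchar(seqs))[1]]),
          class = "mirtrack_format_error")
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  lines <- unlist(purrr::map2(x$id, x$seq, function(id, s) {
    body <- substring(s, seq(1L, nchar(s), by = width),
                      pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Load mature miRNAs from FASTA
#'
#' Reads miRBase-style mature miRNA FASTA (ids such as `hsa-miR-330-5p`),
#' transliterates to RNA and derives the seed (positions 2-7 from the 5' end).
#'
#' @param path path to a miRNA FASTA file.
#' @param min_length minimum accepted mature length (shorter records error).
#' @return a tibble with columns `mirna_id`, `seq`, `seed`.
#' @export
read_mirnas <- function(path, min_length = 15L) {
  fa <- read_fasta(path, alphabet = "RNA")
  short <- nchar(fa$seq) < min_length
  if (any(short)) {
    abort(sprintf("miRNA '%s' is shorter than %d nt", fa$id[which(short)[1]],
                  min_length),
          class = "mirtrack_format_error")
  }
  tibble::tibble(
    mirna_id = fa$id,
    seq = fa$seq,
    seed = substr(fa$seq, 2L, 7L)
  )
}
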