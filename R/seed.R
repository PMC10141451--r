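#' Classify an 8-nt target window against a miRNA seed
#'
#' Implements the canonical seed-match taxonomy over an 8-nt target window
#' read 5'->3', whose last base sits opposite miRNA position 1:
#'
#' * `8mer-1a`: window positions 1-7 are the reverse complement of miRNA
#'   positions 2-8 and window position 8 is A;
#' * `7mer-m8`: window positions 1-7 are the reverse complement of miRNA
#'   positions 2-8 and window position 8 is not A;
#' * `7mer-1a`: window positions 2-7 are the reverse complement of miRNA
#'   positions 2-7, window position 8 is A, and the window is not one of the
#'   two types above (i.e. pairing at miRNA position 8 fails).
#'
#' Pairing is strict Watson-Crick; G:U wobbles never count in the seed.
#'
#' @param mirna_seq mature miRNA RNA sequence, 5'->3', length >= 8.
#' @param window 8-nt target RNA window, 5'->3'.
#' @return `"8mer-1a"`, `"7mer-m8"`, `"7mer-1a"`, or `NA_character_` when the
#'   window matches no site type.
#' @examples
#' classify_seed_site("UAGCUUAUCAGACUGAUGUUGA", "AUAAGCUA")  # 8mer-1a
#' @export
classify_seed_site <- function(mirna_seq, window) {
  if (nchar(window) != 8L) {
    abort("`window` must be exactly 8 nt", class = "mirtrack_contract_error")
  }
  if (nchar(mirna_seq) < 8L) {
    abort("`mirna_seq` must be at least 8 nt", class = "mirtrack_contract_error")
  }
  rc_2_8 <- rc_rna(substr(mirna_seq, 2L, 8L))   # 7 nt
  rc_2_7 <- rc_rna(substr(mirna_seq, 2L, 7L))   # 6 nt
  w1_7 <- substr(window, 1L, 7L)
  w2_7 <- substr(window, 2L, 7L)
  w8 <- substr(window, 8L, 8L)
  if (w1_7 == rc_2_8) {
    return(if (w8 == "A") "8mer-1a" else "7mer-m8")
  }
  if (w2_7 == rc_2_7 && w8 == "A") {
    return("7mer-1a")
  }
  NA_character_
}

#' Scan a transcript for seed-match sites
#'
#' Slides an 8-nt window over the entire mature transcript (deliberately not
#' restricted to the 3'UTR) and emits one candidate per classified window.
#' The reported `t_start`/`t_end` delimit the matched target span: 8 nt for
#' `8mer-1a` (window positions 1-8), window positions 1-7 for `7mer-m8`, and
#' window positions 2-8 for `7mer-1a`.
#'
#' @param mirna_id miRNA name carried into the output.
#' @param mirna_seq mature miRNA RNA sequence.
#' @param transcript_id transcript accession carried into the output.
#' @param transcript_seq mature transcript RNA sequence.
#' @return a candidate-site tibble (engine `"targetscan"`) with 0-based
#'   half-open `t_start`/`t_end` and a `site_type` column; zero rows when the
#'   transcript is shorter than 8 nt or has no site.
#' @export
scan_seed_sites <- function(mirna_id, mirna_seq, transcript_id, transcript_seq) {
  n <- nchar(transcript_seq)
  empty <- tibble::tibble(
    mirna_id = character(), transcript_id = character(),
    engine = character(), t_start = integer(), t_end = integer(),
    site_type = character()
  )
  if (n < 8L) return(empty)
  starts <- seq_len(n - 7L)  # 1-based window starts
  windows <- substring(transcript_seq, starts, starts + 7L)

  rc_2_8 <- rc_rna(substr(mirna_seq, 2L, 8L))
  rc_2_7 <- rc_rna(substr(mirna_seq, 2L, 7L))
  w1_7 <- substr(windows, 1L, 7L)
  w2_7 <- substr(windows, 2L, 7L)
  w8 <- substr(windows, 8L, 8L)

  full_seed <- w1_7 == rc_2_8
  type <- rep(NA_character_, length(windows))
  type[full_seed & w8 == "A"] <- "8mer-1a"
  type[full_seed & w8 != "A"] <- "7mer-m8"
  type[!full_seed & w2_7 == rc_2_7 & w8 == "A"] <- "7mer-1a"

  hit <- which(!is.na(type))
  if (length(hit) == 0L) return(empty)
  w0 <- starts[hit] - 1L  # 0-based window start
  t_start <- ifelse(type[hit] == "7mer-1a", w0 + 1L, w0)
  t_end <- ifelse(type[hit] == "7mer-m8", w0 + 7L, w0 + 8L)
  tibble::tibble(
    mirna_id = mirna_id,
    transcript_id = transcript_id,
    engine = "targetscan",
    t_start = as.integer(t_start),
    t_end = as.integer(t_end),
    site_type = type[hit]
  )
}
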