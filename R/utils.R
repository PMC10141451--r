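#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# RNA complement lookup used throughout (Watson-Crick only).
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement (A<->U, C<->G) of an uppercase RNA string, reversed.
#' Vectorised over its input.
#'
#' @param x character vector of uppercase RNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' rc_rna("ACGU")
#' @export
rc_rna <- function(x) {
  vapply(x, function(s) {
    bases <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- RNA_COMPLEMENT[bases]
    if (anyNA(comp)) {
      abort(sprintf("non-RNA character in sequence '%s'", s),
            class = "mirtrack_alphabet_error")
    }
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# DNA -> RNA transliteration (T to U), uppercasing on the way.
dna_to_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# TRUE where target base t pairs Watson-Crick with miRNA base q (both RNA).
is_wc_pair <- function(t, q) {
  unname(RNA_COMPLEMENT[q] == t & !is.na(RNA_COMPLEMENT[q]))
}

# TRUE where (t, q) is a G:U wobble.
is_gu_pair <- function(t, q) {
  (t == "G" & q == "U") | (t == "U" & q == "G")
}

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer", name),
          class = "mirtrack_contract_error")
  }
  as.integer(x)
}
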