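#' Target-site opening energy from flanking self-complementarity
#'
#' The default accessibility backend. It estimates the cost of opening the
#' target region as the strongest antiparallel stem that the site sequence can
#' form with its flanking sequence (up to `flank` nt on either side): stems
#' are contiguous Watson-Crick/G:U paired stretches of at least `min_stem`
#' base pairs, scored with the package's per-pair duplex model
#' ([duplex_energy()]). The opening cost is the absolute value of the most
#' stable stem's energy, or 0 when no stem of the minimum length exists (an
#' unstructured, e.g. poly-A, flank opens for free). This is a documented
#' heuristic stand-in for full RNA secondary-structure folding.
#'
#' @param transcript_seq mature transcript RNA sequence.
#' @param t_start,t_end 0-based half-open site interval on the transcript.
#' @param flank nucleotides of context on each side (default 35).
#' @param min_stem minimum stem length in base pairs (default 4).
#' @return opening free-energy cost in kcal/mol (>= 0).
#' @export
opening_energy_stems <- function(transcript_seq, t_start, t_end,
                                 flank = 35L, min_stem = 4L) {
  n <- nchar(transcript_seq)
  if (t_start < 0L || t_end > n || t_start >= t_end) {
    abort("site interval out of transcript range", class = "mirtrack_bounds_error")
  }
  site <- seq_chars(substr(transcript_seq, t_start + 1L, t_end))
  left <- substr(transcript_seq, max(1L, t_start + 1L - flank), t_start)
  right <- substr(transcript_seq, t_end + 1L, min(n, t_end + flank))
  best <- 0
  for (fl in c(left, right)) {
    if (nchar(fl) < min_stem) next
    best <- max(best, best_stem_energy(site, seq_chars(fl), min_stem))
  }
  best
}

# Strongest antiparallel stem between the site and one flank: over every
# relative offset, find the best run of >= min_stem consecutive paired
# positions (WC or G:U) and score it with the per-pair model. Returns |energy|.
best_stem_energy <- function(site, flank_chars, min_stem) {
  ns <- length(site)
  nf <- length(flank_chars)
  flank_rev <- rev(flank_chars)  # antiparallel pairing
  best <- 0
  for (off in seq(-(ns - min_stem), nf - min_stem)) {
    i <- seq_len(ns)
    j <- i + off
    keep <- j >= 1L & j <= nf
    if (sum(keep) < min_stem) next
    si <- site[i[keep]]
    fj <- flank_rev[j[keep]]
    paired <- is_wc_pair(si, fj) | is_gu_pair(si, fj)
    e <- -pair_energy(si, fj) * paired
    # best contiguous run of paired positions with length >= min_stem
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_stem)) {
      best <- max(best, sum(e[starts[k]:ends[k]]))
    }
  }
  best
}

#' Net interaction energy of a site (duplex gain minus opening cost)
#'
#' Computes the accessibility-corrected score ddG = dG_duplex + dG_open,
#' where dG_duplex (<= 0) is the energy gained by miRNA:target duplex
#' formation over the site and dG_open (>= 0) is the cost of opening local
#' target structure, supplied by a pluggable backend (default
#' [opening_energy_stems()]). More negative ddG means a more favorable,
#' more accessible site.
#'
#' The duplex is formed gaplessly: miRNA position 1 sits opposite the site's
#' 3'-most base and successive miRNA positions pair 5'<-3' along the site;
#' each column contributes its per-pair energy when it forms a Watson-Crick
#' or G:U pair.
#'
#' @param mirna_seq mature miRNA RNA sequence.
#' @param transcript_seq mature transcript RNA sequence.
#' @param t_start,t_end 0-based half-open site interval.
#' @param open_backend function `(transcript_seq, t_start, t_end) -> dG_open`.
#' @param ... passed on to `open_backend`.
#' @return a list with `ddg`, `dg_duplex` and `dg_open` (kcal/mol).
#' @export
pita_ddg <- function(mirna_seq, transcript_seq, t_start, t_end,
                     open_backend = opening_energy_stems, ...) {
  dg_duplex <- site_duplex_dg(mirna_seq, transcript_seq, t_start, t_end)
  dg_open <- tryCatch(
    open_backend(transcript_seq, t_start, t_end, ...),
    error = function(e) {
      abort(sprintf("accessibility backend failed for site [%d,%d): %s",
                    t_start, t_end, conditionMessage(e)),
            class = "mirtrack_backend_error", parent = e)
    }
  )
  if (!is.finite(dg_open) || dg_open < 0) {
    abort("opening energy must be finite and >= 0", class = "mirtrack_backend_error")
  }
  list(ddg = dg_duplex + dg_open, dg_duplex = dg_duplex, dg_open = dg_open)
}

# Gapless antiparallel duplex energy of the miRNA over the site interval.
site_duplex_dg <- function(mirna_seq, transcript_seq, t_start, t_end) {
  site <- seq_chars(substr(transcript_seq, t_start + 1L, t_end))
  mir <- seq_chars(mirna_seq)
  k <- min(length(site), length(mir))
  # miRNA position 1 opposite the site's 3'-most base
  tb <- rev(site)[seq_len(k)]
  qb <- mir[seq_len(k)]
  paired <- is_wc_pair(tb, qb) | is_gu_pair(tb, qb)
  duplex_energy(tibble::tibble(t = tb, q = qb, paired = paired))
}

#' Score seed-anchored sites with the accessibility engine
#'
#' The accessibility engine anchors candidate regions at seed matches (found
#' with [scan_seed_sites()]), extends each to the span the full-length miRNA
#' would cover (miRNA length, 3' end of the site at the seed match's 3' end),
#' and scores it with [pita_ddg()].
#'
#' @inheritParams scan_seed_sites
#' @param flank flanking width for the default opening backend.
#' @return a candidate-site tibble (engine `"pita"`) with a `ddg` column.
#' @export
scan_pita_sites <- function(mirna_id, mirna_seq, transcript_id, transcript_seq,
                            flank = 35L) {
  seeds <- scan_seed_sites(mirna_id, mirna_seq, transcript_id, transcript_seq)
  if (nrow(seeds) == 0L) {
    return(tibble::tibble(
      mirna_id = character(), transcript_id = character(), engine = character(),
      t_start = integer(), t_end = integer(), ddg = numeric()
    ))
  }
  mlen <- nchar(mirna_seq)
  tlen <- nchar(transcript_seq)
  seeds %>%
    dplyr::mutate(
      # anchor the duplex with miRNA position 1 opposite the base 3' of the
      # seed match; the 7mer-m8 span stops at position 2, so extend it by one
      t_end = pmin(tlen, .data$t_end + as.integer(.data$site_type == "7mer-m8")),
      t_start = pmax(0L, .data$t_end - mlen),
      engine = "pita"
    ) %>%
    dplyr::distinct(.data$t_start, .data$t_end, .keep_all = TRUE) %>%
    dplyr::mutate(
      ddg = purrr::map2_dbl(.data$t_start, .data$t_end, function(s, e) {
        pita_ddg(mirna_seq, transcript_seq, s, e, flank = flank)$ddg
      })
    ) %>%
    dplyr::select("mirna_id", "transcript_id", "engine",
                  "t_start", "t_end", "ddg")
}
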