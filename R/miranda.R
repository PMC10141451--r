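#' Alignment parameter set for the complementarity aligner
#'
#' Defaults: Watson-Crick match +5, G:U wobble +1, mismatch -3, gap open -9,
#' gap extend -4 (a gap of length L costs open + extend * (L - 1)), columns
#' pairing miRNA positions 2-8 scaled x2, and alignments reported only at
#' score >= 100. All values are configuration.
#'
#' @param match,wobble,mismatch per-column scores.
#' @param gap_open,gap_extend affine gap penalties (both negative).
#' @param seed_scale multiplier applied to columns pairing miRNA bases 2-8.
#' @param report_threshold minimum alignment score to report a site.
#' @return a named list of validated parameters.
#' @export
miranda_params <- function(match = 5, wobble = 1, mismatch = -3,
                           gap_open = -9, gap_extend = -4,
                           seed_scale = 2, report_threshold = 100) {
  p <- list(match = match, wobble = wobble, mismatch = mismatch,
            gap_open = gap_open, gap_extend = gap_extend,
            seed_scale = seed_scale, report_threshold = report_threshold)
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    abort("alignment parameters must all be finite", class = "mirtrack_config_error")
  }
  if (seed_scale <= 0) {
    abort("`seed_scale` must be positive", class = "mirtrack_config_error")
  }
  p
}

# Column scores for query base qi (reversed-miRNA index i) vs all target bases.
# seed columns (miRNA positions 2-8) are scaled.
miranda_col_scores <- function(tch, qch, i_seed, params) {
  m <- length(qch)
  lapply(seq_len(m), function(i) {
    wc <- is_wc_pair(tch, qch[i])
    gu <- is_gu_pair(tch, qch[i])
    s <- ifelse(wc, params$match, ifelse(gu, params$wobble, params$mismatch))
    if (i_seed[i]) s <- s * params$seed_scale
    s
  })
}

NEG_INF <- -1e9

# Gotoh local alignment of the reversed miRNA (rows) against the transcript
# (columns). Returns the three DP matrices ((m+1) x (n+1), index 1 = boundary).
# `banned` marks target positions that may not be consumed (overlap masking);
# both aligned (M) and gapped (Iy) consumption of a banned base is forbidden.
miranda_dp <- function(scores, m, n, params, banned) {
  M <- matrix(0, m + 1L, n + 1L)
  Ix <- matrix(NEG_INF, m + 1L, n + 1L)
  Iy <- matrix(NEG_INF, m + 1L, n + 1L)
  go <- params$gap_open
  ge <- params$gap_extend
  any_ban <- any(banned)
  for (i in seq_len(m)) {
    s <- scores[[i]]
    if (any_ban) s[banned] <- NEG_INF
    prevM <- M[i, ]
    prevIx <- Ix[i, ]
    prevIy <- Iy[i, ]
    Ix[i + 1L, ] <- pmax(prevM + go, prevIx + ge)
    diag_best <- pmax(prevM, prevIx, prevIy, 0)[seq_len(n)]
    Mrow <- c(0, diag_best + s)
    Mrow[Mrow < 0] <- 0
    M[i + 1L, ] <- Mrow
    if (!any_ban) {
      # closed form of Iy[j] = max(M[j-1] + go, Iy[j-1] + ge) via running max
      b <- Mrow[seq_len(n)] + go - ge * seq(0L, n - 1L)
      Iy[i + 1L, ] <- c(NEG_INF, cummax(b) + ge * (seq_len(n) - 1L))
    } else {
      Iyrow <- rep(NEG_INF, n + 1L)
      for (j in seq_len(n)) {
        if (!banned[j]) {
          Iyrow[j + 1L] <- max(Mrow[j] + go, Iyrow[j] + ge)
        }
      }
      Iy[i + 1L, ] <- Iyrow
    }
  }
  list(M = M, Ix = Ix, Iy = Iy)
}

# Traceback from M[i+1, j+1]. Returns the aligned columns as parallel index
# vectors (NA marks a gap). Deterministic tie-break: local start, then
# diagonal M, then Ix, then Iy.
miranda_traceback <- function(dp, scores, i, j, params, banned) {
  go <- params$gap_open
  cols_q <- integer()   # reversed-miRNA index or NA for gap
  cols_j <- integer()   # target index or NA for gap
  state <- "M"
  near <- function(a, b) abs(a - b) < 1e-6
  repeat {
    if (state == "M") {
      s <- scores[[i]][j]
      if (banned[j]) s <- NEG_INF
      val <- dp$M[i + 1L, j + 1L] - s
      cols_q <- c(i, cols_q)
      cols_j <- c(j, cols_j)
      if (near(val, 0)) break  # alignment starts here
      if (near(val, dp$M[i, j])) state <- "M"
      else if (near(val, dp$Ix[i, j])) state <- "Ix"
      else if (near(val, dp$Iy[i, j])) state <- "Iy"
      else break
      i <- i - 1L
      j <- j - 1L
    } else if (state == "Ix") {
      cols_q <- c(i, cols_q)
      cols_j <- c(NA_integer_, cols_j)
      state <- if (near(dp$Ix[i + 1L, j + 1L], dp$M[i, j + 1L] + go)) "M" else "Ix"
      i <- i - 1L
    } else {  # Iy: target base j aligned to a gap in the miRNA
      cols_q <- c(NA_integer_, cols_q)
      cols_j <- c(j, cols_j)
      state <- if (near(dp$Iy[i + 1L, j + 1L], dp$M[i + 1L, j] + go)) "M" else "Iy"
      j <- j - 1L
    }
    if (i == 0L || j == 0L) break
  }
  list(q_idx = cols_q, t_idx = cols_j)
}

#' Align a miRNA against a transcript by complementarity
#'
#' Smith-Waterman/Gotoh local alignment of the reversed miRNA (so the miRNA
#' reads 3'->5' along the target's 5'->3' direction) against the transcript,
#' scoring complementarity rather than identity: Watson-Crick pairs are
#' rewarded, G:U wobbles weakly rewarded, mismatches and gaps penalised, and
#' columns pairing miRNA positions 2-8 scaled up. Each reported site carries
#' the alignment score, a duplex binding energy over its paired columns (see
#' [duplex_energy()]) and a three-line alignment schematization. Multiple
#' sites per (miRNA, transcript) pair are extracted best-first with overlap
#' masking, so reported sites never share target bases.
#'
#' @param mirna_id,mirna_seq miRNA name and RNA sequence (5'->3').
#' @param transcript_id,transcript_seq transcript accession and RNA sequence.
#' @param params parameter list from [miranda_params()].
#' @return a candidate-site tibble (engine `"miranda"`) with columns
#'   `t_start`, `t_end` (0-based half-open target span), `alignment_score`,
#'   `binding_energy` and `alignment_text`, sorted by `t_start`.
#' @export
align_miranda <- function(mirna_id, mirna_seq, transcript_id, transcript_seq,
                          params = miranda_params()) {
  qch <- rev(seq_chars(mirna_seq))   # reversed miRNA characters
  tch <- seq_chars(transcript_seq)
  m <- length(qch)
  n <- length(tch)
  mir_pos <- m - seq_len(m) + 1L     # miRNA position of each reversed index
  i_seed <- mir_pos >= 2L & mir_pos <= 8L
  empty <- tibble::tibble(
    mirna_id = character(), transcript_id = character(), engine = character(),
    t_start = integer(), t_end = integer(), alignment_score = numeric(),
    binding_energy = numeric(), alignment_text = character()
  )
  if (n == 0L) return(empty)
  scores <- miranda_col_scores(tch, qch, i_seed, params)
  banned <- rep(FALSE, n)
  out <- list()
  repeat {
    dp <- miranda_dp(scores, m, n, params, banned)
    best <- max(dp$M)
    if (best < params$report_threshold) break
    # deterministic argmax: smallest target end, then smallest query end
    hit <- which(dp$M == best, arr.ind = TRUE)
    hit <- hit[order(hit[, "col"], hit[, "row"]), , drop = FALSE]
    i0 <- hit[1, "row"] - 1L
    j0 <- hit[1, "col"] - 1L
    tb <- miranda_traceback(dp, scores, i0, j0, params, banned)
    tpos <- tb$t_idx[!is.na(tb$t_idx)]
    site <- miranda_site_row(tb, tch, qch, mir_pos, best,
                             mirna_id, transcript_id)
    out[[length(out) + 1L]] <- site
    banned[seq(min(tpos), max(tpos))] <- TRUE
    if (all(banned)) break
  }
  if (length(out) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$t_start)
}

# Assemble one reported site row from a traceback.
miranda_site_row <- function(tb, tch, qch, mir_pos, score,
                             mirna_id, transcript_id) {
  tb_t <- ifelse(is.na(tb$t_idx), "-", tch[tb$t_idx])
  tb_q <- ifelse(is.na(tb$q_idx), "-", qch[tb$q_idx])
  gap <- tb_t == "-" | tb_q == "-"
  wc <- !gap & is_wc_pair(tb_t, tb_q)
  gu <- !gap & is_gu_pair(tb_t, tb_q)
  paired <- wc | gu
  energy <- duplex_energy(tibble::tibble(
    t = ifelse(gap, "A", tb_t), q = ifelse(gap, "A", tb_q),
    paired = paired
  ))
  marks <- ifelse(wc, "|", ifelse(gu, ":", " "))
  text <- paste0(
    "target 5' ", paste(tb_t, collapse = ""), " 3'\n",
    "          ", paste(marks, collapse = ""), "\n",
    "mirna  3' ", paste(tb_q, collapse = ""), " 5'"
  )
  tpos <- tb$t_idx[!is.na(tb$t_idx)]
  tibble::tibble(
    mirna_id = mirna_id, transcript_id = transcript_id, engine = "miranda",
    t_start = min(tpos) - 1L, t_end = max(tpos),
    alignment_score = score, binding_energy = energy, alignment_text = text
  )
}
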