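# Independent oracles and tiny builders shared across the suite.

rna_bases <- c("A", "C", "G", "U")

random_rna <- function(n) paste(sample(rna_bases, n, replace = TRUE), collapse = "")

# One-row transcript model without going through GTF parsing.
make_model <- function(exons, strand = "+", chrom = "chr1",
                       transcript_id = "TX1", gene_id = "G1", gene_name = "g1") {
  ex <- tibble::tibble(start = as.integer(exons[, 1]), end = as.integer(exons[, 2]))
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    chrom = chrom, strand = strand, exons = list(ex),
    spliced_length = sum(ex$end - ex$start)
  )
}

# Per-base forward map oracle: transcript offset -> genomic position, built by
# walking exon bases one at a time (independent of build_coordinate_map).
per_base_oracle <- function(exons, strand) {
  g <- unlist(apply(exons, 1, function(e) seq(e[1], e[2] - 1L)))
  if (strand == "-") rev(g) else g
}

# Brute-force seed-site enumeration: classify every 8-nt window one by one.
scan_oracle <- function(mirna_seq, transcript_seq) {
  n <- nchar(transcript_seq)
  if (n < 8L) return(integer(0))
  hits <- list()
  for (w0 in 0:(n - 8L)) {
    window <- substr(transcript_seq, w0 + 1L, w0 + 8L)
    type <- classify_seed_site(mirna_seq, window)
    if (!is.na(type)) hits[[length(hits) + 1L]] <- c(w0 = w0, type = type)
  }
  hits
}

# Independent scalar Gotoh DP: best local-alignment score of the reversed
# miRNA vs the transcript under the same scoring scheme. Deliberately written
# as a plain triple-state cell-by-cell loop.
miranda_score_oracle <- function(mirna_seq, transcript_seq, params = miranda_params()) {
  q <- rev(strsplit(mirna_seq, "")[[1]])
  t <- strsplit(transcript_seq, "")[[1]]
  m <- length(q); n <- length(t)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  colscore <- function(i, j) {
    mirpos <- m - i + 1L
    s <- if (comp[[q[i]]] == t[j]) params$match
         else if ((q[i] == "G" && t[j] == "U") || (q[i] == "U" && t[j] == "G")) params$wobble
         else params$mismatch
    if (mirpos >= 2L && mirpos <= 8L) s * params$seed_scale else s
  }
  M <- matrix(0, m + 1, n + 1); X <- matrix(-Inf, m + 1, n + 1); Y <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 1:m) for (j in 1:n) {
    X[i + 1, j + 1] <- max(M[i, j + 1] + params$gap_open, X[i, j + 1] + params$gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + params$gap_open, Y[i + 1, j] + params$gap_extend)
    M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j])) + colscore(i, j)
    if (M[i + 1, j + 1] < 0) M[i + 1, j + 1] <- 0
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# Per-base triple-intersection oracle: for each (ts, mi, pi) triple, mark the
# bases covered by all three and keep runs >= min_overlap. Returns a tibble of
# candidate cores with the triple's miranda energy (for the collapse step).
intersect_oracle <- function(ts, mi, pi, min_overlap, len = 200L) {
  cores <- list()
  for (a in seq_len(nrow(ts))) for (b in seq_len(nrow(mi))) for (cc in seq_len(nrow(pi))) {
    mask <- rep(0L, len)
    for (iv in list(ts[a, ], mi[b, ], pi[cc, ])) {
      idx <- seq.int(iv$t_start + 1L, iv$t_end)
      mask[idx] <- mask[idx] + 1L
    }
    covered <- which(mask == 3L)
    if (length(covered) >= min_overlap &&
        all(diff(covered) == 1L)) {
      cores[[length(cores) + 1L]] <- tibble::tibble(
        core_start = covered[1] - 1L, core_end = covered[length(covered)],
        binding_energy = mi$binding_energy[[b]]
      )
    }
  }
  dplyr::bind_rows(cores)
}

# Independent greedy collapse mirroring the documented rule.
collapse_oracle <- function(cores) {
  if (nrow(cores) == 0L) return(cores)
  cores <- cores[order(cores$binding_energy, cores$core_start, cores$core_end), ]
  keep <- list()
  for (i in seq_len(nrow(cores))) {
    ok <- TRUE
    for (k in keep) {
      if (cores$core_start[i] < k$core_end && cores$core_end[i] > k$core_start) ok <- FALSE
    }
    if (ok) keep[[length(keep) + 1L]] <- cores[i, ]
  }
  out <- dplyr::bind_rows(keep)
  out[order(out$core_start), ]
}

# Random candidate-site table for one (miRNA, transcript) pair and one engine.
random_engine_sites <- function(engine, k, len = 200L) {
  starts <- sample.int(len - 30L, k, replace = TRUE) - 1L
  widths <- sample(7:25, k, replace = TRUE)
  out <- tibble::tibble(
    mirna_id = "mirX", transcript_id = "txX", engine = engine,
    t_start = starts, t_end = pmin(starts + widths, len)
  )
  if (engine == "targetscan") out$site_type <- sample(c("8mer-1a", "7mer-1a", "7mer-m8"), k, TRUE)
  if (engine == "miranda") {
    out$alignment_score <- sample(140:180, k, TRUE)
    out$binding_energy <- -sample(20:60, k, TRUE) - 0.5
    out$alignment_text <- "t\n|\nq"
  }
  if (engine == "pita") out$ddg <- -sample(10:40, k, TRUE) - 0.25
  out
}

# Shared small fixture, generated once per test run.
shared_fixture_env <- new.env()
shared_fixture <- function() {
  if (is.null(shared_fixture_env$fx)) {
    shared_fixture_env$fx <- generate_fixture(fixture_spec(rng_seed = 42L))
  }
  shared_fixture_env$fx
}
shared_fixture_dir <- function() {
  if (is.null(shared_fixture_env$dir)) {
    d <- tempfile("fixture")
    write_fixture(shared_fixture(), d)
    shared_fixture_env$dir <- d
  }
  shared_fixture_env$dir
}
shared_result <- function() {
  if (is.null(shared_fixture_env$res)) {
    d <- shared_fixture_dir()
    shared_fixture_env$res <- run_pipeline(
      file.path(d, "transcripts.gtf"), file.path(d, "transcripts.fa"),
      file.path(d, "mirnas.fa"),
      bed = file.path(d, "out.bed"), csv = file.path(d, "out.csv"),
      details_dir = file.path(d, "details")
    )
  }
  shared_fixture_env$res
}
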