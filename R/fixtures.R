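#' Default planted-site plan for synthetic fixtures
#'
#' Five triple-confirmed consensus sites (one spanning an exon-exon junction,
#' covering all three seed site types) plus three single-engine decoys: a
#' seed-wobble site no seed classifier calls, a site with non-seed mismatches
#' dropping the alignment score below threshold, and a site whose flank hides
#' a strong complementary stem that inflates the opening cost past the ddG
#' threshold.
#'
#' @return a tibble with columns `kind`, `site_type`, `spans_junction`,
#'   `mirna`, `transcript` (indices recycled over the fixture's miRNAs and
#'   transcripts).
#' @export
default_plant_plan <- function() {
  tibble::tibble(
    kind = c(rep("consensus", 5), "ts_fail", "miranda_fail", "pita_fail"),
    site_type = c("8mer-1a", "8mer-1a", "7mer-m8", "7mer-1a", "8mer-1a",
                  "8mer-1a", "8mer-1a", "8mer-1a"),
    spans_junction = c(TRUE, rep(FALSE, 7)),
    mirna = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L),
    transcript = c(1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L)
  )
}

#' Specification of a synthetic fixture
#'
#' Defines a small multi-chromosome genome with multi-exon genes, two
#' transcripts per gene related by exon skipping (alternative splicing of
#' shared exons), miRNAs with known seeds, and a plan of planted binding
#' sites. Mature miRNAs are drawn 23 nt long with a 5'-terminal U (the
#' canonical miRBase bias) and position 8 in {G, U} so that every seed class,
#' including wobble-at-8 variants, is plantable.
#'
#' @param rng_seed integer seed; the whole fixture is deterministic in it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes genes, laid alternately across chromosomes and strands.
#' @param exons_per_gene range of exon counts per gene.
#' @param exon_length,intron_length ranges, nt.
#' @param n_mirnas,mirna_length miRNA collection shape.
#' @param planted_sites plan tibble, see [default_plant_plan()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(rng_seed = 1L, n_chroms = 2L, chrom_length = 5000L,
                         n_genes = 4L, exons_per_gene = 3:4,
                         exon_length = 90:150, intron_length = 60:140,
                         n_mirnas = 3L, mirna_length = 23L,
                         planted_sites = default_plant_plan()) {
  structure(list(rng_seed = as.integer(rng_seed), n_chroms = n_chroms,
                 chrom_length = chrom_length, n_genes = n_genes,
                 exons_per_gene = exons_per_gene, exon_length = exon_length,
                 intron_length = intron_length, n_mirnas = n_mirnas,
                 mirna_length = mirna_length, planted_sites = planted_sites),
            class = "fixture_spec")
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Builds the genome, transcript models, mature transcript sequences and
#' miRNAs of `spec`, plants the specified binding sites by reverse-complement
#' construction (written back into the genome through the splice map, so
#' transcripts sharing the edited exon inherit the site), engineers the
#' decoys, and verifies every expectation against the package's engines,
#' retrying with fresh randomness a bounded number of times if a random
#' background interferes.
#'
#' @param spec a [fixture_spec()].
#' @return a `mirtrack_fixture` list: `genome` (named DNA strings), `models`,
#'   `transcriptome` (models + `seq`), `mirnas`, `ground_truth` (one row per
#'   (plant, transcript containing it): ids, seed-window `t_start`/`t_end`,
#'   `site_type`, `kind`, `expect_consensus`, expected `block_count`),
#'   `plants` (internal placement table) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  withr::with_seed(spec$rng_seed, {
    for (attempt in seq_len(20L)) {
      fx <- tryCatch(generate_once(spec), mirtrack_plant_error = function(e) NULL)
      if (!is.null(fx)) return(fx)
    }
    abort("fixture generation failed after bounded retries",
          class = "mirtrack_generation_error")
  })
}

plant_fail <- function(msg) abort(msg, class = "mirtrack_plant_error")

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Lay out genes along chromosomes; two transcripts per gene: the full exon
# chain and an exon-skipping isoform (middle exon dropped).
build_models <- function(spec) {
  cursors <- rep(120L, spec$n_chroms)
  rows <- list()
  for (g in seq_len(spec$n_genes)) {
    ci <- ((g - 1L) %% spec$n_chroms) + 1L
    chrom <- paste0("chr", ci)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_ex <- sample(spec$exons_per_gene, 1L)
    lens <- sample(spec$exon_length, n_ex, replace = TRUE)
    gaps <- sample(spec$intron_length, n_ex - 1L, replace = TRUE)
    starts <- cursors[ci] + cumsum(c(0L, lens[-n_ex] + gaps))
    exons <- tibble::tibble(start = as.integer(starts),
                            end = as.integer(starts + lens))
    cursors[ci] <- max(exons$end) + 200L
    if (cursors[ci] > spec$chrom_length - 200L) {
      plant_fail("gene layout exceeds chromosome length")
    }
    gene_id <- sprintf("ENSTESTG%08d", g)
    gene_name <- sprintf("GENE%d", g)
    skip <- ceiling(n_ex / 2)  # middle exon dropped in the second isoform
    for (iso in 1:2) {
      ex <- if (iso == 1L) exons else exons[-skip, , drop = FALSE]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        transcript_id = sprintf("ENSTESTT%08d", (g - 1L) * 2L + iso),
        gene_id = gene_id, gene_name = gene_name,
        chrom = chrom, strand = strand,
        exons = list(ex),
        spliced_length = sum(ex$end - ex$start)
      )
    }
  }
  dplyr::bind_rows(rows)
}

build_mirnas <- function(spec) {
  seqs <- vapply(seq_len(spec$n_mirnas), function(i) {
    body <- random_seq(spec$mirna_length - 1L, c("A", "C", "G", "U"))
    s <- paste0("U", body)
    # positions 5 and 8 drawn from {G, U} so wobble-bearing plants (seed
    # decoys, 7mer-1a sites) are always constructible
    substr(s, 5L, 5L) <- sample(c("G", "U"), 1L)
    substr(s, 8L, 8L) <- sample(c("G", "U"), 1L)
    s
  }, character(1))
  tibble::tibble(
    mirna_id = sprintf("syn-miR-%d-5p", seq_len(spec$n_mirnas)),
    seq = seqs,
    seed = substr(seqs, 2L, 7L)
  )
}

# Per-base transcript -> genome position map (0-based), in transcript order.
per_base_map <- function(model) {
  map <- build_coordinate_map(model)
  unlist(purrr::pmap(map, function(start, end, t_offset) {
    if (model$strand == "+") seq(start, end - 1L) else seq(end - 1L, start)
  }), use.names = FALSE)
}

# Write an RNA string into a transcript's coordinates, propagating through
# the splice map into the (plus-strand, DNA) genome.
write_back <- function(genome, model, t_start, rna) {
  g_of_t <- per_base_map(model)
  bases <- seq_chars(chartr("U", "T", rna))
  if (model$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  pos <- g_of_t[t_start + seq_along(bases)]  # 0-based positions
  s <- genome[[model$chrom]]
  for (k in seq_along(bases)) {
    substr(s, pos[k] + 1L, pos[k] + 1L) <- bases[k]
  }
  genome[[model$chrom]] <- s
  genome
}

wobble_partner <- function(b) switch(b, G = "U", U = "G",
                                     plant_fail("no wobble partner"))
non_pairing_base <- function(b) {
  # breaks both WC and wobble pairing with miRNA base b
  switch(b, A = "C", C = "A", G = "G", U = "U")
}

# Construct the planted site RNA (length = miRNA length): reverse complement
# of miRNA positions 2..L, then the base opposite position 1.
plant_site_seq <- function(mirna_seq, kind, site_type) {
  L <- nchar(mirna_seq)
  core <- rc_rna(substr(mirna_seq, 2L, L))  # opposite positions L..2
  chars <- seq_chars(core)
  opp <- function(p) L + 1L - p  # site index (1-based) opposite miRNA pos p
  if (site_type == "7mer-1a") {
    # wobble opposite position 8: breaks strict Watson-Crick pairing there
    # (so the seed classifier sees a 7mer-1a) at a small alignment-score cost
    chars[opp(8L)] <- wobble_partner(substr(mirna_seq, 8L, 8L))
  }
  if (kind == "ts_fail") {
    # wobble inside the 2-7 seed silences every seed class while keeping the
    # aligner score above threshold
    chars[opp(5L)] <- wobble_partner(substr(mirna_seq, 5L, 5L))
  }
  if (kind == "miranda_fail") {
    for (p in c(11L, 14L, 17L)) {
      chars[opp(p)] <- non_pairing_base(substr(mirna_seq, p, p))
    }
  }
  terminal <- if (site_type == "7mer-m8") "G" else "A"
  paste0(paste(chars, collapse = ""), terminal)
}

# Seed-window span (0-based half-open, scan_seed_sites convention) of a site
# planted at transcript offset p.
plant_window_span <- function(p, L, site_type) {
  w0 <- p + L - 8L
  switch(site_type,
    "8mer-1a" = c(w0, w0 + 8L),
    "7mer-m8" = c(w0, w0 + 7L),
    "7mer-1a" = c(w0 + 1L, w0 + 8L),
    c(w0, w0 + 8L)
  )
}

generate_once <- function(spec) {
  genome <- stats::setNames(
    lapply(seq_len(spec$n_chroms), function(i) random_seq(spec$chrom_length)),
    paste0("chr", seq_len(spec$n_chroms))
  )
  models <- build_models(spec)
  mirnas <- build_mirnas(spec)
  used <- lapply(genome, function(s) logical(nchar(s)))

  plan <- spec$planted_sites
  plants <- list()
  for (r in seq_len(nrow(plan))) {
    row <- plan[r, ]
    ti <- ((row$transcript - 1L) %% nrow(models)) + 1L
    mi <- ((row$mirna - 1L) %% nrow(mirnas)) + 1L
    model <- models[ti, ]
    mseq <- mirnas$seq[[mi]]
    L <- nchar(mseq)
    site <- plant_site_seq(mseq, row$kind, row$site_type)
    extra <- if (row$kind == "pita_fail") 26L else 0L  # room for the stem insert
    p <- place_site(model, L, extra, row$spans_junction, used)
    g_of_t <- per_base_map(model)
    footprint <- g_of_t[(p + 1L):(p + L + extra)]
    used[[model$chrom]][footprint + 1L] <- TRUE
    genome <- write_back(genome, model, p, site)
    if (row$spans_junction) {
      blocked <- block_partial_junction_sites(genome, models, model, p, L,
                                              mseq, used)
      genome <- blocked$genome
      used <- blocked$used
    }
    if (row$kind == "pita_fail") {
      # hide the reverse complement of the site's first 20 nt just
      # downstream: a 20-bp stem whose opening cost sinks the ddG
      stem <- rc_rna(substr(site, 1L, 20L))
      genome <- write_back(genome, model, p + L + 4L, stem)
    }
    span <- plant_window_span(p, L, row$site_type)
    plants[[r]] <- tibble::tibble(
      plant = r, kind = row$kind, site_type = row$site_type,
      spans_junction = row$spans_junction,
      mirna_id = mirnas$mirna_id[[mi]],
      transcript_id = model$transcript_id,
      site_start = p, site_end = p + L,
      t_start = span[[1]], t_end = span[[2]]
    )
  }
  plants <- dplyr::bind_rows(plants)

  transcriptome <- dplyr::mutate(models, seq = purrr::map_chr(
    seq_len(nrow(models)), ~ spliced_sequence(models[.x, ], genome)))

  ground_truth <- propagate_plants(plants, models, transcriptome, genome)
  verify_fixture(ground_truth, transcriptome, mirnas)

  structure(list(genome = genome, models = models,
                 transcriptome = transcriptome, mirnas = mirnas,
                 ground_truth = ground_truth, plants = plants, spec = spec),
            class = "mirtrack_fixture")
}

# Choose a transcript offset for a site of length L (+extra room after it):
# inside one exon, or straddling the first internal junction when requested.
# Avoids genomic positions already claimed by earlier plants.
place_site <- function(model, L, extra, spans_junction, used) {
  g_of_t <- per_base_map(model)
  n <- model$spliced_length
  map <- build_coordinate_map(model)
  for (try in seq_len(60L)) {
    if (spans_junction) {
      if (nrow(map) < 2L) plant_fail("junction plant needs a multi-exon transcript")
      j <- map$t_offset[[2L]]
      off <- sample(2:6, 1L)     # junction strictly inside the seed window
      p <- j + off - 8L - (L - 8L)
    } else {
      # wholly inside one exon
      ex <- which(map$end - map$start >= L + extra + 2L)
      if (length(ex) == 0L) plant_fail("no exon long enough for plant")
      e <- sample(rep(ex, 2L), 1L)
      room <- (map$end[e] - map$start[e]) - (L + extra)
      p <- map$t_offset[e] + sample.int(room, 1L) - 1L
    }
    if (p < 0L || p + L + extra > n) next
    fp <- g_of_t[(p + 1L):(p + L + extra)]
    if (!any(used[[model$chrom]][fp + 1L])) return(p)
  }
  plant_fail("could not place site without collisions")
}

# A transcript that inherits only the 5' part of a junction-spanning site
# (because its splicing skips the downstream exon) could have the site
# completed by chance by its own next exon's bases. Write two bases that can
# pair neither Watson-Crick nor wobble with the continuing miRNA positions
# right after that transcript's junction, so truncated plants stay negative.
block_partial_junction_sites <- function(genome, models, origin, p, L, mirna_seq, used) {
  g_site <- per_base_map(origin)[(p + 1L):(p + L)]
  others <- models[models$chrom == origin$chrom &
                   models$strand == origin$strand &
                   models$transcript_id != origin$transcript_id, ]
  for (k in seq_len(nrow(others))) {
    mdl <- others[k, ]
    tpos <- vapply(g_site, function(g) genome_to_transcript(mdl, g), integer(1))
    run <- 0L
    for (i in seq_along(tpos)) {
      if (is.na(tpos[i]) || (i > 1L && tpos[i] != tpos[i - 1L] + 1L)) break
      run <- i
    }
    if (run == 0L || run == L) next  # absent, or a full carrier
    for (b in 0:1) {
      tb <- tpos[run] + 1L + b
      mp <- L - run - b  # miRNA position the continuation base would pair
      if (tb >= mdl$spliced_length || mp < 1L) next
      gpos <- per_base_map(mdl)[tb + 1L]
      if (used[[mdl$chrom]][gpos + 1L]) plant_fail("junction blocker collides")
      blocker <- non_pairing_base(substr(mirna_seq, mp, mp))
      genome <- write_back(genome, mdl, tb, blocker)
      used[[mdl$chrom]][gpos + 1L] <- TRUE
    }
  }
  list(genome = genome, used = used)
}

# A plant lives in the genome: every transcript whose exons carry the edited
# bases contiguously inherits it. Emit one ground-truth row per carrier.
propagate_plants <- function(plants, models, transcriptome, genome) {
  rows <- list()
  for (r in seq_len(nrow(plants))) {
    pl <- plants[r, ]
    origin <- models[models$transcript_id == pl$transcript_id, ]
    g_window <- per_base_map(origin)[(pl$t_start + 1L):pl$t_end]
    carriers <- models[models$chrom == origin$chrom &
                       models$strand == origin$strand, ]
    for (k in seq_len(nrow(carriers))) {
      mdl <- carriers[k, ]
      tpos <- vapply(g_window, function(g) genome_to_transcript(mdl, g),
                     integer(1))
      if (anyNA(tpos)) next
      if (!identical(sort(tpos), seq(min(tpos), max(tpos)))) next
      if (is.unsorted(tpos)) next  # must read in the same 5'->3' order
      proj <- transcript_to_genome(mdl, min(tpos), max(tpos) + 1L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plant = pl$plant, kind = pl$kind, site_type = pl$site_type,
        spans_junction = pl$spans_junction,
        mirna_id = pl$mirna_id, transcript_id = mdl$transcript_id,
        t_start = min(tpos), t_end = max(tpos) + 1L,
        expect_consensus = pl$kind == "consensus",
        block_count = proj$block_count
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Every expectation is checked against the actual engines over the whole
# fixture; any violation (a missed plant, a decoy or any unplanned site
# reaching consensus) aborts this attempt, and generate_fixture retries.
verify_fixture <- function(ground_truth, transcriptome, mirnas) {
  cons <- consensus_all(predict_sites(transcriptome, mirnas))
  for (r in seq_len(nrow(ground_truth))) {
    gt <- ground_truth[r, ]
    hit <- cons[cons$mirna_id == gt$mirna_id &
                cons$transcript_id == gt$transcript_id &
                cons$core_end > gt$t_start & cons$core_start < gt$t_end, ]
    if (nrow(hit) != as.integer(gt$expect_consensus)) {
      plant_fail(sprintf("%s expectation violated (%s/%s)",
                         gt$kind, gt$mirna_id, gt$transcript_id))
    }
  }
  for (i in seq_len(nrow(cons))) {
    cc <- cons[i, ]
    planted <- any(ground_truth$expect_consensus &
                   ground_truth$mirna_id == cc$mirna_id &
                   ground_truth$transcript_id == cc$transcript_id &
                   ground_truth$t_start < cc$core_end &
                   ground_truth$t_end > cc$core_start)
    if (!planted) {
      plant_fail(sprintf("unplanned consensus site (%s/%s)",
                         cc$mirna_id, cc$transcript_id))
    }
  }
  invisible(TRUE)
}

#' Scramble planted sites into same-composition negative controls
#'
#' Replaces every planted site window by a random permutation of its own
#' bases that no longer classifies as a seed site for its miRNA (verified
#' against [scan_seed_sites()], with bounded retries per site), writes the
#' permuted windows back through the splice map and recomputes all transcript
#' sequences.
#'
#' @param fixture a `mirtrack_fixture` from [generate_fixture()].
#' @param rng_seed seed for the permutations.
#' @return the fixture with scrambled sites; `ground_truth` retains the
#'   original coordinates so callers can assert that nothing is found there.
#' @export
shuffle_negative_control <- function(fixture, rng_seed = fixture$spec$rng_seed + 1L) {
  withr::with_seed(rng_seed, {
    genome <- fixture$genome
    models <- fixture$models
    for (r in seq_len(nrow(fixture$plants))) {
      pl <- fixture$plants[r, ]
      model <- models[models$transcript_id == pl$transcript_id, ]
      tr_seq <- spliced_sequence(model, genome)
      site <- substr(tr_seq, pl$site_start + 1L, pl$site_end)
      mr <- fixture$mirnas[fixture$mirnas$mirna_id == pl$mirna_id, ]
      done <- FALSE
      for (try in seq_len(100L)) {
        perm <- paste(sample(seq_chars(site)), collapse = "")
        cand <- tr_seq
        substr(cand, pl$site_start + 1L, pl$site_end) <- perm
        lo <- max(0L, pl$site_start - 8L)
        hi <- min(nchar(cand), pl$site_end + 8L)
        found <- scan_seed_sites(mr$mirna_id, mr$seq, model$transcript_id,
                                 substr(cand, lo + 1L, hi))
        if (nrow(found) == 0L) {
          genome <- write_back(genome, model, pl$site_start, perm)
          done <- TRUE
          break
        }
      }
      if (!done) {
        abort("could not scramble a planted site away from all seed matches",
              class = "mirtrack_generation_error")
      }
    }
    transcriptome <- dplyr::mutate(models, seq = purrr::map_chr(
      seq_len(nrow(models)), ~ spliced_sequence(models[.x, ], genome)))
    out <- fixture
    out$genome <- genome
    out$transcriptome <- transcriptome
    out
  })
}

#' Write a fixture's files to a directory
#'
#' Emits `genome.fa`, `transcripts.gtf`, `transcripts.fa`, `mirnas.fa` and
#' `ground_truth.tsv` — the complete input set for [run_pipeline()] plus the
#' ground-truth table.
#'
#' @param fixture a `mirtrack_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(tibble::tibble(id = names(fixture$genome),
                             seq = unlist(fixture$genome)),
              file.path(dir, "genome.fa"))
  write_gtf(fixture$models, file.path(dir, "transcripts.gtf"))
  write_fasta(tibble::tibble(id = fixture$transcriptome$transcript_id,
                             seq = fixture$transcriptome$seq),
              file.path(dir, "transcripts.fa"))
  write_fasta(tibble::tibble(id = fixture$mirnas$mirna_id,
                             seq = fixture$mirnas$seq),
              file.path(dir, "mirnas.fa"))
  readr::write_tsv(fixture$ground_truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
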