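write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, start, end, strand, tid, gid = "G1", gname = "g1") {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
          chrom, start, end, strand, gid, tid, gname)
}

test_that("GTF 1-based closed coordinates convert to 0-based half-open models", {
  f <- write_lines_tmp(c(gtf_line("chr1", 101, 150, "+", "T1"),
                         gtf_line("chr1", 201, 260, "+", "T1")), ".gtf")
  m <- read_transcript_models(f)
  expect_equal(nrow(m), 1L)
  expect_equal(m$exons[[1]]$start, c(100L, 200L))
  expect_equal(m$exons[[1]]$end, c(150L, 260L))
  expect_equal(m$spliced_length, 110L)

  f1 <- write_lines_tmp(gtf_line("chr1", 1, 50, "+", "T1"), ".gtf")
  m1 <- read_transcript_models(f1)
  expect_equal(m1$exons[[1]]$start, 0L)
  expect_equal(m1$exons[[1]]$end, 50L)
  expect_equal(m1$spliced_length, 50L)
})

test_that("transcripts sharing exon coordinates but not ids give distinct models", {
  f <- write_lines_tmp(c(gtf_line("chr1", 101, 150, "+", "T1"),
                         gtf_line("chr1", 201, 260, "+", "T1"),
                         gtf_line("chr1", 101, 150, "+", "T2"),
                         gtf_line("chr1", 201, 260, "+", "T2")), ".gtf")
  m <- read_transcript_models(f)
  expect_equal(sort(m$transcript_id), c("T1", "T2"))
  expect_identical(m$exons[[1]], m$exons[[2]])
})

test_that("mixed-chromosome or mixed-strand transcripts are rejected with a reason", {
  f <- write_lines_tmp(c(gtf_line("chr1", 101, 150, "+", "T1"),
                         gtf_line("chr2", 201, 260, "+", "T1"),
                         gtf_line("chr1", 301, 350, "+", "T2")), ".gtf")
  expect_warning(m <- read_transcript_models(f), "mixed chromosomes")
  expect_equal(m$transcript_id, "T2")
})

test_that("malformed GTF lines are reported with their line number", {
  f <- write_lines_tmp(c(gtf_line("chr1", 101, 150, "+", "T1"),
                         "chr1\tonly\tthree"), ".gtf")
  expect_error(read_transcript_models(f), "line 2", class = "mirtrack_format_error")
})

test_that("FASTA reading transliterates, uppercases and concatenates", {
  f <- write_lines_tmp(c(">x", "acgt"))
  expect_equal(read_fasta(f, "RNA"), tibble::tibble(id = "x", seq = "ACGU"))

  f2 <- write_lines_tmp(c(">a desc", "AC", "GU"))
  expect_equal(read_fasta(f2, "RNA")$seq, "ACGU")

  f3 <- write_lines_tmp(c(">a", "ACGT", ">b", "GGCC"))
  r <- read_fasta(f3, "DNA")
  expect_equal(r$id, c("a", "b"))

  f4 <- write_lines_tmp(c(">bad", "ACQT"))
  expect_error(read_fasta(f4, "DNA"), "bad", class = "mirtrack_format_error")
})

test_that("canonical-chromosome filtering is an order-preserving, idempotent subset", {
  m <- dplyr::bind_rows(make_model(rbind(c(0, 50)), chrom = "chr1", transcript_id = "A"),
                        make_model(rbind(c(0, 50)), chrom = "chrUn_x", transcript_id = "B"))
  kept <- filter_canonical(m)
  expect_equal(kept$transcript_id, "A")
  expect_identical(filter_canonical(kept), kept)
  expect_equal(nrow(filter_canonical(m[0, ])), 0L)
  expect_true(all(filter_canonical(m)$transcript_id %in% m$transcript_id))
  expect_error(filter_canonical(m, character(0)), class = "mirtrack_contract_error")
})

test_that("spliced sequences concatenate exons and reverse-complement on minus strand", {
  genome <- list(chr1 = "ACGTTACG")
  m <- make_model(rbind(c(0, 3), c(5, 8)))
  expect_equal(spliced_sequence(m, genome), "ACGACG")

  m2 <- make_model(rbind(c(0, 4)), strand = "-", chrom = "chr1")
  expect_equal(spliced_sequence(m2, list(chr1 = "ACGT")), "ACGU")

  expect_error(spliced_sequence(make_model(rbind(c(0, 99))), genome),
               class = "mirtrack_bounds_error")
})

test_that("fixture transcript sequences equal their spliced extraction and survive a GTF round trip", {
  fx <- shared_fixture()
  for (i in seq_len(nrow(fx$models))) {
    expect_identical(spliced_sequence(fx$models[i, ], fx$genome),
                     fx$transcriptome$seq[[i]])
  }
  d <- shared_fixture_dir()
  reread <- read_transcript_models(file.path(d, "transcripts.gtf"))
  expect_equal(nrow(reread), nrow(fx$models))
  for (tid in fx$models$transcript_id) {
    expect_identical(reread$exons[[which(reread$transcript_id == tid)]],
                     fx$models$exons[[which(fx$models$transcript_id == tid)]])
  }
  # and the written FASTA matches the in-memory transcriptome
  fa <- read_fasta(file.path(d, "transcripts.fa"), "RNA")
  expect_identical(fa$seq[match(fx$models$transcript_id, fa$id)],
                   fx$transcriptome$seq)
})
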