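test_that("planted windows classify as their declared site types", {
  fx <- shared_fixture()
  gt <- fx$ground_truth
  for (i in which(gt$kind == "consensus")) {
    row <- gt[i, ]
    tr_seq <- fx$transcriptome$seq[[which(fx$transcriptome$transcript_id == row$transcript_id)]]
    mir <- fx$mirnas[fx$mirnas$mirna_id == row$mirna_id, ]
    # reconstruct the full 8-nt window around the matched span
    w0 <- if (row$site_type == "7mer-1a") row$t_start - 1L else row$t_start
    window <- substr(tr_seq, w0 + 1L, w0 + 8L)
    expect_identical(classify_seed_site(mir$seq, window), row$site_type)
  }
})

test_that("fixture generation is byte-deterministic per seed", {
  a <- tempfile()
  b <- tempfile()
  write_fixture(generate_fixture(fixture_spec(rng_seed = 99L)), a)
  write_fixture(generate_fixture(fixture_spec(rng_seed = 99L)), b)
  for (f in list.files(a)) {
    expect_identical(readLines(file.path(a, f)), readLines(file.path(b, f)),
                     info = f)
  }
  # a different seed changes the sequences
  c_ <- tempfile()
  write_fixture(generate_fixture(fixture_spec(rng_seed = 100L)), c_)
  expect_false(identical(readLines(file.path(a, "genome.fa")),
                         readLines(file.path(c_, "genome.fa"))))
})

test_that("junction-spanning plants project onto two genomic blocks", {
  fx <- shared_fixture()
  gt <- fx$ground_truth
  j <- gt[gt$spans_junction & gt$kind == "consensus", ]
  expect_gte(nrow(j), 1L)
  expect_true(all(j$block_count == 2L))
  model <- fx$models[fx$models$transcript_id == j$transcript_id[[1]], ]
  b <- transcript_to_genome(model, j$t_start[[1]], j$t_end[[1]])
  expect_equal(b$block_count, 2L)
})

test_that("alternative splicing shares plants between isoforms and drops junction sites", {
  fx <- shared_fixture()
  gt <- fx$ground_truth
  # at least one plant propagated to a second transcript of the same gene
  expect_true(any(duplicated(gt$plant)))
  # the junction plant cannot exist in the exon-skipping isoform
  j <- gt[gt$spans_junction, ]
  expect_equal(nrow(j), 1L)
})

test_that("scrambled negative controls keep composition but lose every planted site", {
  fx <- shared_fixture()
  neg <- shuffle_negative_control(fx)
  for (i in seq_len(nrow(fx$plants))) {
    pl <- fx$plants[i, ]
    tri <- which(fx$transcriptome$transcript_id == pl$transcript_id)
    orig <- substr(fx$transcriptome$seq[[tri]], pl$site_start + 1L, pl$site_end)
    scram <- substr(neg$transcriptome$seq[[tri]], pl$site_start + 1L, pl$site_end)
    expect_false(identical(orig, scram))
    expect_identical(sort(strsplit(orig, "")[[1]]), sort(strsplit(scram, "")[[1]]))
  }
  # the seed scan finds nothing at any planted location
  for (i in seq_len(nrow(neg$ground_truth))) {
    row <- neg$ground_truth[i, ]
    tr <- neg$transcriptome[neg$transcriptome$transcript_id == row$transcript_id, ]
    mir <- neg$mirnas[neg$mirnas$mirna_id == row$mirna_id, ]
    found <- scan_seed_sites(mir$mirna_id, mir$seq, tr$transcript_id, tr$seq)
    overlapping <- found[found$t_end > row$t_start & found$t_start < row$t_end, ]
    expect_equal(nrow(overlapping), 0L)
  }
})

test_that("consensus calls on a fixture recover exactly the planted truth", {
  fx <- shared_fixture()
  sites <- predict_sites(fx$transcriptome, fx$mirnas)
  cons <- consensus_all(sites)
  gt <- fx$ground_truth
  for (i in seq_len(nrow(gt))) {
    row <- gt[i, ]
    hits <- cons[cons$mirna_id == row$mirna_id &
                 cons$transcript_id == row$transcript_id &
                 cons$core_end > row$t_start & cons$core_start < row$t_end, ]
    expect_equal(nrow(hits), as.integer(row$expect_consensus), info = paste("row", i))
  }
  # precision: every consensus site is a planted one
  for (i in seq_len(nrow(cons))) {
    cc <- cons[i, ]
    expect_true(any(gt$expect_consensus & gt$mirna_id == cc$mirna_id &
                    gt$transcript_id == cc$transcript_id &
                    gt$t_start < cc$core_end & gt$t_end > cc$core_start))
  }
})
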