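# Minimal projected-consensus rows for the writer tests.
projected_row <- function(mirna_id = "hsa-miR-aaa", transcript_id = "T1",
                          gene_id = "G1", gene_name = "g1", chrom = "chr1",
                          strand = "+", blocks = tibble::tibble(start = 100L, end = 120L),
                          core_start = 10L, core_end = 30L, energy = -30) {
  tibble::tibble(
    mirna_id = mirna_id, transcript_id = transcript_id,
    core_start = core_start, core_end = core_end,
    ts_start = core_start, ts_end = core_end, site_type = "8mer-1a",
    mi_start = core_start - 2L, mi_end = core_end + 2L,
    alignment_score = 150, binding_energy = energy,
    alignment_text = "target 5' ACGU 3'\n          ||||\nmirna  3' UGCA 5'",
    pi_start = core_start - 2L, pi_end = core_end + 2L, ddg = -15,
    gene_id = gene_id, gene_name = gene_name, chrom = chrom, strand = strand,
    g_start = min(blocks$start), g_end = max(blocks$end),
    block_count = nrow(blocks), blocks = list(blocks)
  )
}

test_that("identical regions merge into one item, asterisked when miRNAs differ", {
  two_mirnas <- dplyr::bind_rows(
    projected_row("hsa-miR-bbb"),
    projected_row("hsa-miR-aaa", transcript_id = "T2")
  )
  items <- merge_identical_regions(two_mirnas)
  expect_equal(nrow(items), 1L)
  expect_equal(items$label, "hsa-miR-aaa*")
  expect_equal(nrow(items$members[[1]]), 2L)

  two_tx <- dplyr::bind_rows(projected_row(transcript_id = "T1"),
                             projected_row(transcript_id = "T2"))
  items2 <- merge_identical_regions(two_tx)
  expect_equal(nrow(items2), 1L)
  expect_equal(items2$label, "hsa-miR-aaa")
  expect_equal(nrow(items2$members[[1]]), 2L)
})

test_that("same span with a different block split stays distinct (exact-tuple keying)", {
  a <- projected_row(blocks = tibble::tibble(start = 100L, end = 120L))
  b <- projected_row(transcript_id = "T2",
                     blocks = tibble::tibble(start = c(100L, 110L), end = c(105L, 120L)))
  items <- merge_identical_regions(dplyr::bind_rows(a, b))
  expect_equal(nrow(items), 2L)
  expect_match(items$item_id, "^MBS\\d{8}$")
  expect_equal(anyDuplicated(items$item_id), 0L)
})

test_that("merging is stable under input permutation and re-merge", {
  set.seed(11)
  rows <- dplyr::bind_rows(
    projected_row(), projected_row("hsa-miR-ccc", transcript_id = "T3"),
    projected_row(blocks = tibble::tibble(start = 500L, end = 520L),
                  transcript_id = "T4")
  )
  a <- merge_identical_regions(rows)
  b <- merge_identical_regions(rows[sample(nrow(rows)), ])
  expect_identical(a, b)
})

test_that("bedDetail lines carry the 14-field schema with BED block closure", {
  single <- merge_identical_regions(projected_row("hsa-miR-x"))
  f <- tempfile()
  expect_equal(write_beddetail(single, f), 1L)
  lines <- readLines(f)
  expect_match(lines[1], "^track type=bedDetail")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_length(fields, 14L)
  expect_equal(fields[1:3], c("chr1", "100", "120"))
  expect_equal(fields[5], "0")
  expect_equal(fields[7:8], fields[2:3])
  expect_equal(fields[9], "255,255,0")
  expect_equal(fields[10:12], c("1", "20,", "0,"))
  expect_equal(fields[14], "hsa-miR-x")

  junction <- merge_identical_regions(projected_row(
    blocks = tibble::tibble(start = c(145L, 200L), end = c(150L, 210L))))
  f2 <- tempfile()
  write_beddetail(junction, f2)
  jf <- strsplit(readLines(f2)[2], "\t")[[1]]
  expect_equal(jf[c(2, 3, 10, 11, 12)], c("145", "210", "2", "5,10,", "0,55,"))
  # block closure: last start + last size = chromEnd - chromStart
  expect_equal(55L + 10L, 210L - 145L)

  unsorted <- dplyr::bind_rows(
    merge_identical_regions(projected_row(blocks = tibble::tibble(start = 900L, end = 920L))),
    merge_identical_regions(projected_row(blocks = tibble::tibble(start = 100L, end = 120L)))
  )
  expect_error(write_beddetail(unsorted, tempfile()), class = "mirtrack_contract_error")
})

test_that("detail records expose six columns per member and pass alignments through", {
  items <- merge_identical_regions(dplyr::bind_rows(
    projected_row("hsa-miR-bbb"), projected_row("hsa-miR-aaa", transcript_id = "T2")))
  rec <- detail_records(items[1, ])
  expect_equal(ncol(rec), 6L)
  expect_equal(nrow(rec), 2L)
  expect_identical(rec$alignment, items$members[[1]]$alignment_text)
  # ranges are printed 1-based inclusive
  expect_match(rec$targetscan_details[1], "range 11-30")

  html <- render_detail_record(items[1, ])
  expect_equal(length(gregexpr("<tr>", html, fixed = TRUE)[[1]]), 3L)  # header + 2

  broken <- items
  broken$members[[1]] <- broken$members[[1]][0, ]
  expect_error(detail_records(broken[1, ]), class = "mirtrack_contract_error")
})

test_that("the flat CSV has one 14-field row per member pair and round-trips", {
  items <- merge_identical_regions(dplyr::bind_rows(
    projected_row("hsa-miR-a", transcript_id = "T1"),
    projected_row("hsa-miR-b", transcript_id = "T2"),
    projected_row("hsa-miR-c", transcript_id = "T3")
  ))
  f <- tempfile(fileext = ".csv")
  n <- write_track_csv(items, f)
  expect_equal(n, sum(purrr::map_int(items$members, nrow)))
  lines <- readLines(f)
  expect_equal(length(lines), n + 1L)
  for (l in lines) expect_length(strsplit(l, ";", fixed = TRUE)[[1]], 14L)

  back <- read_track_csv(f)
  expect_equal(nrow(back), n)
  expect_equal(back$pita_ddg, rep("-15.00", n))
  expect_equal(back$miranda_energy, rep("-30.00", n))
  expect_equal(back$miranda_score, rep("150", n))
})

test_that("track filtering prunes members, recomputes labels and validates usage", {
  items <- merge_identical_regions(dplyr::bind_rows(
    projected_row("hsa-miR-a", gene_name = "LMNB1"),
    projected_row("hsa-miR-b", transcript_id = "T2", gene_name = "ACTB"),
    projected_row("hsa-miR-c", transcript_id = "T3", gene_name = "ACTB",
                  blocks = tibble::tibble(start = 700L, end = 720L))
  ))
  expect_equal(items$label[1], "hsa-miR-a*")

  by_m <- filter_track(items, by_mirna = "hsa-miR-a")
  expect_equal(nrow(by_m), 1L)
  expect_equal(by_m$label, "hsa-miR-a")  # asterisk removed after pruning

  expect_equal(nrow(filter_track(items, by_gene = "NOSUCH")), 0L)
  both <- filter_track(items, by_mirna = "hsa-miR-b", by_gene = "ACTB")
  expect_equal(nrow(both), 1L)
  expect_equal(both$members[[1]]$transcript_id, "T2")
  expect_error(filter_track(items), class = "mirtrack_usage_error")
})
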