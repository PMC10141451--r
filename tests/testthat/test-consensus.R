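site_row <- function(engine, t_start, t_end, mirna_id = "m1", transcript_id = "t1", ...) {
  extra <- list(...)
  base <- tibble::tibble(mirna_id = mirna_id, transcript_id = transcript_id,
                         engine = engine, t_start = as.integer(t_start),
                         t_end = as.integer(t_end))
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

test_that("retention thresholds are inclusive on their printed boundaries", {
  cfg <- threshold_config()
  mi_ok <- site_row("miranda", 0, 20, alignment_score = 140, binding_energy = -20.0,
                    alignment_text = "")
  mi_energy <- site_row("miranda", 0, 20, alignment_score = 200, binding_energy = -19.9,
                        alignment_text = "")
  mi_score <- site_row("miranda", 0, 20, alignment_score = 139.9, binding_energy = -30,
                       alignment_text = "")
  expect_equal(nrow(apply_thresholds(mi_ok, cfg)), 1L)
  expect_equal(nrow(apply_thresholds(mi_energy, cfg)), 0L)
  expect_equal(nrow(apply_thresholds(mi_score, cfg)), 0L)

  expect_equal(nrow(apply_thresholds(site_row("pita", 0, 20, ddg = -10.0), cfg)), 1L)
  expect_equal(nrow(apply_thresholds(site_row("pita", 0, 20, ddg = -9.9), cfg)), 0L)

  expect_equal(nrow(apply_thresholds(site_row("targetscan", 0, 8,
                                              site_type = "8mer-1a"), cfg)), 1L)
  expect_equal(nrow(apply_thresholds(site_row("targetscan", 0, 8,
                                              site_type = "6mer"), cfg)), 0L)
})

ts1 <- function(s, e) site_row("targetscan", s, e, site_type = "8mer-1a")
mi1 <- function(s, e, energy = -30) site_row("miranda", s, e, alignment_score = 150,
                                             binding_energy = energy, alignment_text = "a")
pi1 <- function(s, e) site_row("pita", s, e, ddg = -15)

test_that("three-way intersection emits the common core at or above the overlap minimum", {
  one <- intersect_three(ts1(10, 30), mi1(15, 32), pi1(18, 40), min_overlap = 6)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$core_start, one$core_end), c(18L, 30L))

  none <- intersect_three(ts1(10, 20), mi1(25, 35), pi1(10, 35), min_overlap = 6)
  expect_equal(nrow(none), 0L)

  # common overlap of 5 < 6 is rejected
  short <- intersect_three(ts1(10, 20), mi1(15, 25), pi1(15, 40), min_overlap = 6)
  expect_equal(nrow(short), 0L)
  expect_equal(nrow(intersect_three(ts1(10, 20), mi1(15, 25), pi1(15, 40),
                                    min_overlap = 5)), 1L)
})

test_that("mixed pair identifiers are a contract error", {
  expect_error(intersect_three(ts1(0, 10),
                               site_row("miranda", 0, 10, mirna_id = "OTHER",
                                        alignment_score = 150, binding_energy = -30,
                                        alignment_text = ""),
                               pi1(0, 10)),
               class = "mirtrack_contract_error")
})

test_that("overlapping triples collapse to the lowest miRanda energy, leftmost first", {
  ts <- dplyr::bind_rows(ts1(10, 18), ts1(12, 20))
  mi <- dplyr::bind_rows(mi1(8, 25, energy = -25), mi1(9, 26, energy = -40))
  pi <- pi1(8, 30)
  out <- intersect_three(ts, mi, pi, min_overlap = 6)
  # all cores overlap; the winning triple carries the -40 energy
  expect_true(all(out$binding_energy == -40))
  expect_equal(nrow(out), 1L)
})

test_that("intersection matches a per-base brute-force oracle on random instances", {
  set.seed(505)
  for (rep in 1:200) {
    ts <- random_engine_sites("targetscan", sample(1:6, 1))
    mi <- random_engine_sites("miranda", sample(1:6, 1))
    pi <- random_engine_sites("pita", sample(1:6, 1))
    got <- intersect_three(ts, mi, pi, min_overlap = 6)
    want <- collapse_oracle(intersect_oracle(ts, mi, pi, min_overlap = 6))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$core_start, want$core_start)
      expect_equal(got$core_end, want$core_end)
      expect_equal(got$binding_energy, want$binding_energy)
    }
    expect_true(all(got$core_end - got$core_start >= 6))
  }
})

test_that("consensus over pooled engines is order-invariant and respects decoys", {
  pairs <- list(
    list(id = "A", full = TRUE), list(id = "B", full = TRUE),
    list(id = "C", full = TRUE), list(id = "D", full = TRUE),
    list(id = "E", full = TRUE),
    list(id = "X", full = FALSE, drop = "targetscan"),
    list(id = "Y", full = FALSE, drop = "miranda"),
    list(id = "Z", full = FALSE, drop = "pita")
  )
  sites <- dplyr::bind_rows(lapply(pairs, function(p) {
    s <- dplyr::bind_rows(
      site_row("targetscan", 10, 18, mirna_id = p$id, site_type = "8mer-1a"),
      site_row("miranda", 5, 27, mirna_id = p$id, alignment_score = 150,
               binding_energy = -35, alignment_text = "x"),
      site_row("pita", 5, 27, mirna_id = p$id, ddg = -14)
    )
    if (!p$full) s <- s[s$engine != p$drop, ]
    s
  }))
  out <- consensus_all(sites)
  expect_equal(sort(out$mirna_id), c("A", "B", "C", "D", "E"))
  expect_equal(nrow(consensus_all(sites[0, ])), 0L)

  set.seed(77)
  shuffled <- sites[sample(nrow(sites)), ]
  expect_identical(consensus_all(shuffled), out)
})

test_that("loosening any threshold never loses consensus sites", {
  set.seed(606)
  for (rep in 1:25) {
    sites <- dplyr::bind_rows(
      random_engine_sites("targetscan", 5),
      random_engine_sites("miranda", 5),
      random_engine_sites("pita", 5)
    )
    base_cfg <- threshold_config()
    n0 <- nrow(consensus_all(sites, base_cfg))
    looser <- list(
      threshold_config(miranda_max_energy = -10),
      threshold_config(miranda_min_score = 120),
      threshold_config(pita_max_ddg = -5),
      threshold_config(min_overlap = 3)
    )
    for (cfg in looser) {
      expect_gte(nrow(consensus_all(sites, cfg)), n0)
    }
  }
})
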