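#' Retention thresholds for the three predictor engines
#'
#' The high-confidence filter: miRanda sites are kept when binding energy
#' <= -20 kcal/mol and alignment score >= 140; accessibility (PITA) sites
#' when ddG <= -10 kcal/mol; seed (TargetScan) sites when the site type is
#' one of 8mer-1a, 7mer-1a, 7mer-m8. A consensus site additionally requires
#' all three engines to overlap by at least `min_overlap` nucleotides in
#' transcript space. All comparisons are inclusive.
#'
#' @param miranda_max_energy maximum (most positive) accepted miRanda binding
#'   energy, kcal/mol.
#' @param miranda_min_score minimum accepted miRanda alignment score.
#' @param pita_max_ddg maximum accepted ddG, kcal/mol.
#' @param allowed_site_types accepted seed site types.
#' @param min_overlap minimum three-way overlap, nt (>= 1).
#' @return a named list of validated thresholds.
#' @export
threshold_config <- function(miranda_max_energy = -20,
                             miranda_min_score = 140,
                             pita_max_ddg = -10,
                             allowed_site_types = c("8mer-1a", "7mer-1a", "7mer-m8"),
                             min_overlap = 6L) {
  if (length(allowed_site_types) == 0L) {
    abort("`allowed_site_types` must be non-empty", class = "mirtrack_config_error")
  }
  if (min_overlap < 1L) {
    abort("`min_overlap` must be >= 1", class = "mirtrack_config_error")
  }
  list(miranda_max_energy = miranda_max_energy,
       miranda_min_score = miranda_min_score,
       pita_max_ddg = pita_max_ddg,
       allowed_site_types = allowed_site_types,
       min_overlap = as.integer(min_overlap))
}

#' Apply per-engine retention thresholds to candidate sites
#'
#' @param sites a candidate-site tibble (any mix of engines).
#' @param cfg thresholds from [threshold_config()].
#' @return the retained subset, order preserved.
#' @export
apply_thresholds <- function(sites, cfg = threshold_config()) {
  if (nrow(sites) == 0L) return(sites)
  n <- nrow(sites)
  col <- function(nm, default) {
    if (nm %in% names(sites)) sites[[nm]] else rep(default, n)
  }
  keep <- dplyr::case_when(
    sites$engine == "miranda" ~
      col("binding_energy", NA_real_) <= cfg$miranda_max_energy &
      col("alignment_score", NA_real_) >= cfg$miranda_min_score,
    sites$engine == "pita" ~ col("ddg", NA_real_) <= cfg$pita_max_ddg,
    sites$engine == "targetscan" ~
      col("site_type", NA_character_) %in% cfg$allowed_site_types,
    .default = FALSE
  )
  sites[!is.na(keep) & keep, , drop = FALSE]
}

#' Three-way intersection of per-engine sites for one (miRNA, transcript) pair
#'
#' For every triple (one thresholded site per engine) whose common interval
#' intersection spans at least `min_overlap` nucleotides, emits one consensus
#' site whose core is that intersection. When cores from distinct triples
#' overlap, only the triple with the lowest (most negative) miRanda binding
#' energy is kept, ties broken by leftmost core.
#'
#' @param ts,mi,pi candidate-site tibbles for the targetscan, miranda and pita
#'   engines; all rows must share one `mirna_id` and one `transcript_id`.
#' @param min_overlap minimum core length, nt.
#' @return a consensus-site tibble: identifiers, `core_start`/`core_end`, and
#'   the three engines' intervals and scores (`ts_*`, `mi_*`, `pi_*` columns).
#' @export
intersect_three <- function(ts, mi, pi, min_overlap = 6L) {
  ids <- dplyr::bind_rows(ts[c("mirna_id", "transcript_id")],
                          mi[c("mirna_id", "transcript_id")],
                          pi[c("mirna_id", "transcript_id")])
  if (nrow(ids) > 0L &&
      (dplyr::n_distinct(ids$mirna_id) > 1L ||
       dplyr::n_distinct(ids$transcript_id) > 1L)) {
    abort("intersect_three requires sites of a single (miRNA, transcript) pair",
          class = "mirtrack_contract_error")
  }
  if (nrow(ts) == 0L || nrow(mi) == 0L || nrow(pi) == 0L) {
    return(empty_consensus())
  }
  triples <- tidyr::expand_grid(a = seq_len(nrow(ts)), b = seq_len(nrow(mi)),
                                c = seq_len(nrow(pi)))
  core_start <- pmax(ts$t_start[triples$a], mi$t_start[triples$b],
                     pi$t_start[triples$c])
  core_end <- pmin(ts$t_end[triples$a], mi$t_end[triples$b],
                   pi$t_end[triples$c])
  ok <- (core_end - core_start) >= min_overlap
  if (!any(ok)) return(empty_consensus())
  out <- tibble::tibble(
    mirna_id = ts$mirna_id[[1]],
    transcript_id = ts$transcript_id[[1]],
    core_start = as.integer(core_start[ok]),
    core_end = as.integer(core_end[ok]),
    ts_start = ts$t_start[triples$a[ok]],
    ts_end = ts$t_end[triples$a[ok]],
    site_type = ts$site_type[triples$a[ok]],
    mi_start = mi$t_start[triples$b[ok]],
    mi_end = mi$t_end[triples$b[ok]],
    alignment_score = mi$alignment_score[triples$b[ok]],
    binding_energy = mi$binding_energy[triples$b[ok]],
    alignment_text = mi$alignment_text[triples$b[ok]],
    pi_start = pi$t_start[triples$c[ok]],
    pi_end = pi$t_end[triples$c[ok]],
    ddg = pi$ddg[triples$c[ok]]
  )
  collapse_overlapping_cores(out)
}

empty_consensus <- function() {
  tibble::tibble(
    mirna_id = character(), transcript_id = character(),
    core_start = integer(), core_end = integer(),
    ts_start = integer(), ts_end = integer(), site_type = character(),
    mi_start = integer(), mi_end = integer(), alignment_score = numeric(),
    binding_energy = numeric(), alignment_text = character(),
    pi_start = integer(), pi_end = integer(), ddg = numeric()
  )
}

# Greedy collapse of overlapping cores: keep lowest miRanda energy, ties by
# leftmost core (then shortest, then ts interval for full determinism).
collapse_overlapping_cores <- function(x) {
  x <- dplyr::arrange(x, .data$binding_energy, .data$core_start,
                      .data$core_end, .data$ts_start, .data$pi_start)
  kept <- integer()
  for (i in seq_len(nrow(x))) {
    if (length(kept) == 0L ||
        all(x$core_end[kept] <= x$core_start[i] |
            x$core_start[kept] >= x$core_end[i])) {
      kept <- c(kept, i)
    }
  }
  dplyr::arrange(x[kept, , drop = FALSE], .data$core_start)
}

#' Consensus calling over all (miRNA, transcript) pairs
#'
#' Applies the per-engine thresholds, then intersects the three engines' calls
#' within each (miRNA, transcript) pair. Only sites supported by all three
#' engines with at least `cfg$min_overlap` nt of transcript-space overlap
#' survive; these are the pipeline's high-confidence predicted targets.
#'
#' @param sites candidate-site tibble pooling all engines (as produced by
#'   [predict_sites()] or the native adapters).
#' @param cfg thresholds from [threshold_config()].
#' @return a consensus-site tibble sorted by (transcript, core start, miRNA).
#' @export
consensus_all <- function(sites, cfg = threshold_config()) {
  kept <- apply_thresholds(sites, cfg)
  if (nrow(kept) == 0L) return(empty_consensus())
  kept <- dplyr::arrange(kept, .data$engine, .data$t_start, .data$t_end)
  out <- kept %>%
    dplyr::group_by(.data$mirna_id, .data$transcript_id) %>%
    dplyr::group_map(function(d, key) {
      d$mirna_id <- key$mirna_id[[1]]
      d$transcript_id <- key$transcript_id[[1]]
      intersect_three(
        ts = d[d$engine == "targetscan", , drop = FALSE],
        mi = d[d$engine == "miranda", , drop = FALSE],
        pi = d[d$engine == "pita", , drop = FALSE],
        min_overlap = cfg$min_overlap
      )
    }) %>%
    dplyr::bind_rows()
  if (nrow(out) == 0L) return(empty_consensus())
  dplyr::arrange(out, .data$transcript_id, .data$core_start, .data$mirna_id)
}
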