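#' Default column maps for native predictor output files
#'
#' Names the columns the adapter expects to find in each tool's tabular
#' output. Override any entry to match a local dialect, e.g.
#' `native_col_map("pita", transcript_id = "RefSeq")`.
#'
#' @param engine `"targetscan"`, `"miranda"` or `"pita"`.
#' @param ... named overrides, `internal_field = "column name in file"`.
#' @return named character vector mapping internal fields to file columns.
#' @export
native_col_map <- function(engine = c("targetscan", "miranda", "pita"), ...) {
  engine <- match.arg(engine)
  map <- switch(engine,
    targetscan = c(transcript_id = "a_Gene_ID", mirna_id = "miRNA_family_ID",
                   t_start = "UTR_start", t_end = "UTR_end",
                   site_type = "Site_type"),
    miranda = c(transcript_id = "Target", mirna_id = "miRNA",
                t_start = "Target_start", t_end = "Target_end",
                alignment_score = "Score", binding_energy = "Energy"),
    pita = c(transcript_id = "RefSeq", mirna_id = "microRNA",
             t_start = "Start", t_end = "End", ddg = "ddG")
  )
  overrides <- c(...)
  map[names(overrides)] <- overrides
  map
}

#' Parse a native predictor output file into candidate sites
#'
#' Reads the tab-separated output of TargetScan, miRanda or PITA (one row per
#' predicted site) and converts it into the package's candidate-site tibble,
#' converting the tools' 1-based closed coordinates to internal 0-based
#' half-open. Column names are resolved through a configurable map
#' ([native_col_map()]).
#'
#' @param engine `"targetscan"`, `"miranda"` or `"pita"`.
#' @param path path to the native tabular output file.
#' @param col_map column map, as from [native_col_map()].
#' @return a candidate-site tibble with the engine's score fields populated;
#'   zero rows for an empty file.
#' @export
parse_native_output <- function(engine = c("targetscan", "miranda", "pita"),
                                path, col_map = native_col_map(engine)) {
  engine <- match.arg(engine)
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (nrow(d) == 0L && ncol(d) == 0L) d <- tibble::tibble()
  missing <- setdiff(unname(col_map), names(d))
  if (length(missing) > 0L && nrow(d) > 0L) {
    abort(sprintf("native %s output is missing required column '%s'",
                  engine, missing[[1]]),
          class = "mirtrack_format_error")
  }
  if (nrow(d) == 0L) {
    out <- tibble::tibble(
      mirna_id = character(), transcript_id = character(), engine = character(),
      t_start = integer(), t_end = integer()
    )
    return(add_engine_score_cols(out, engine))
  }
  out <- tibble::tibble(
    mirna_id = as.character(d[[col_map[["mirna_id"]]]]),
    transcript_id = as.character(d[[col_map[["transcript_id"]]]]),
    engine = engine,
    t_start = as.integer(d[[col_map[["t_start"]]]]) - 1L,
    t_end = as.integer(d[[col_map[["t_end"]]]])
  )
  if (engine == "targetscan") {
    out$site_type <- as.character(d[[col_map[["site_type"]]]])
  } else if (engine == "miranda") {
    out$alignment_score <- as.numeric(d[[col_map[["alignment_score"]]]])
    out$binding_energy <- as.numeric(d[[col_map[["binding_energy"]]]])
    out$alignment_text <- NA_character_
  } else {
    out$ddg <- as.numeric(d[[col_map[["ddg"]]]])
  }
  out
}

# Ensure an empty adapter result carries the engine's score columns.
add_engine_score_cols <- function(x, engine) {
  if (engine == "targetscan") x$site_type <- character()
  if (engine == "miranda") {
    x$alignment_score <- numeric()
    x$binding_energy <- numeric()
    x$alignment_text <- character()
  }
  if (engine == "pita") x$ddg <- numeric()
  x
}
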