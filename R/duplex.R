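#' Per-pair RNA duplex energy
#'
#' A deliberately simple stacking-free per-pair energy model: each
#' Watson-Crick G:C pair contributes -3.0 kcal/mol, each Watson-Crick A:U pair
#' -2.0, each G:U wobble -1.0, and unpaired or mismatched columns 0. The total
#' is the plain sum. This is a documented stand-in for nearest-neighbor
#' thermodynamics, not Turner parity; it preserves the orderings the
#' downstream thresholds rely on (more/longer complementarity means more
#' negative energy).
#'
#' @param pairs a tibble (or data frame) with character columns `t` (target
#'   base), `q` (miRNA base) and logical `paired`, one row per duplex column
#'   in order.
#' @return the duplex free energy in kcal/mol (<= 0).
#' @examples
#' duplex_energy(tibble::tibble(t = rep("G", 10), q = rep("C", 10),
#'                              paired = TRUE))  # -30
#' @export
duplex_energy <- function(pairs) {
  if (nrow(pairs) == 0L) {
    abort("`pairs` must be non-empty", class = "mirtrack_contract_error")
  }
  ok <- pairs$t %in% names(RNA_COMPLEMENT) & pairs$q %in% names(RNA_COMPLEMENT)
  if (!all(ok)) {
    abort(sprintf("invalid base symbol in duplex pair %d", which(!ok)[1]),
          class = "mirtrack_contract_error")
  }
  sum(pair_energy(pairs$t, pairs$q) * as.numeric(pairs$paired))
}

# Vectorised per-pair energies: GC -3, AU -2, GU -1, else 0.
pair_energy <- function(t, q) {
  gc <- (t == "G" & q == "C") | (t == "C" & q == "G")
  au <- (t == "A" & q == "U") | (t == "U" & q == "A")
  gu <- is_gu_pair(t, q)
  -3.0 * gc - 2.0 * au - 1.0 * (gu & !gc & !au)
}
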