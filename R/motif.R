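# Walker-motif scanning.
#
# The KdpD N-terminal domain carries an atypical Walker A motif with one
# extra spacer residue (G-X5-G-K-T rather than the classical G-X4-G-K-T)
# plus a Walker B motif whose D/E pair polarizes the gamma-phosphate. The
# Walker B consensus used for pattern scanning is >=3 consecutive
# hydrophobic residues (A/V/I/L/M/F/C) immediately followed by DE; for
# well-aligned chains the authoritative Walker B signal is conservation of
# the projected D/E anchor columns, with this scan as fallback.
#
# Wildcard (X) positions in patterns match only the 20 canonical residues:
# the ambiguity letters B/Z/U and the unknown-residue letter X never count
# as matches, so motif calls stay conservative on dirty sequences.

motif_patterns <- function(allow_gks = FALSE) {
  canon <- paste0("[", paste(AA_CANONICAL, collapse = ""), "]")
  hydro <- paste0("[", paste(AA_HYDROPHOBIC, collapse = ""), "]")
  gkt <- if (allow_gks) "GK[TS]" else "GKT"
  list(
    walkerA_atypical = paste0("G", canon, "{5}", gkt),
    walkerA_classic  = paste0("G", canon, "{4}", gkt),
    walkerB          = paste0(hydro, "{3,}DE")
  )
}

#' Scan a sequence for Walker motifs
#'
#' Finds all (possibly overlapping) occurrences of a named motif, optionally
#' restricted to a 1-based inclusive interval. Hits are reported only when
#' they lie entirely inside the interval.
#'
#' Motifs: `walkerA_atypical` (G-X5-G-K-T, the KdpD-domain P-loop variant),
#' `walkerA_classic` (G-X4-G-K-T), and `walkerB` (>=3 hydrophobic residues
#' from A/V/I/L/M/F/C immediately followed by DE). Spacer (X) positions
#' match canonical residues only; B/Z/U/X never match.
#'
#' @param sequence non-empty amino-acid string.
#' @param motif one of `"walkerA_atypical"`, `"walkerA_classic"`, `"walkerB"`.
#' @param interval optional `c(start, end)` 1-based inclusive search window.
#' @param allow_gks if `TRUE`, permit GKS in place of the literal GKT in
#'   Walker A patterns (off by default; the motif as described is G-X5-GKT).
#' @return data.frame with columns `motif`, `start`, `end`, `match`,
#'   sorted by start; zero rows when there is no hit.
#' @examples
#' scan_motif("GAAAAAGKT", "walkerA_atypical")  # one hit spanning 1..9
#' scan_motif("AVLDEK", "walkerB")              # hit "AVLDE" at 1..5
#' @export
scan_motif <- function(sequence, motif, interval = NULL, allow_gks = FALSE) {
  pats <- motif_patterns(allow_gks)
  if (!is.character(motif) || length(motif) != 1L || !motif %in% names(pats)) {
    stop_config(sprintf("unknown motif name '%s' (expected one of %s)",
                        paste(motif, collapse = ","),
                        paste(names(pats), collapse = ", ")))
  }
  sequence <- normalize_sequence(sequence, "sequence")
  n <- nchar(sequence)
  offset <- 0L
  if (!is.null(interval)) {
    if (length(interval) != 2L || any(!is.finite(interval)) ||
        interval[1] < 1L || interval[2] > n || interval[1] > interval[2]) {
      stop_validation(sprintf("interval must lie within 1..%d", n))
    }
    offset <- as.integer(interval[1]) - 1L
    sequence <- substr(sequence, interval[1], interval[2])
  }
  # zero-width lookahead with a capture makes overlapping hits visible;
  # each start position admits at most one match for these patterns
  rx <- paste0("(?=(", pats[[motif]], "))")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(attr(m, "capture.start")[, 1])
  lens <- as.integer(attr(m, "capture.length")[, 1])
  data.frame(
    motif = motif,
    start = starts + offset,
    end = starts + lens - 1L + offset,
    match = substring(sequence, starts, starts + lens - 1L),
    stringsAsFactors = FALSE
  )
}
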