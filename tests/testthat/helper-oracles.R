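# Independent oracles used by the property and acceptance tests.

# Brute-force global-alignment score: recursive enumeration over all
# global alignments, scoring gap runs as open + length * ext (a run is
# charged its opening when the neighbouring column to the right is not a
# gap in the same sequence). Exponential; only for short sequences.
oracle_align_score <- function(a, b, smat, open, ext) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, nxt) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- rec(i - 1L, j - 1L, 0L) + smat[A[i], B[j]]
    }
    if (i > 0L) {
      cand <- rec(i - 1L, j, 1L) - ext - if (nxt == 1L) 0 else open
      if (cand > best) best <- cand
    }
    if (j > 0L) {
      cand <- rec(i, j - 1L, 2L) - ext - if (nxt == 2L) 0 else open
      if (cand > best) best <- cand
    }
    best
  }
  rec(length(A), length(B), 0L)
}

unit_matrix <- function() {
  m <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(m) <- 1
  m
}

# BLOSUM62 with the package's conventions (X scores 0 against everything,
# letters absent from BLOSUM62 score 0) as a plain matrix for the oracle
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  full <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  keep <- intersect(rownames(e$BLOSUM62), LETTERS)
  full[keep, keep] <- e$BLOSUM62[keep, keep]
  full["X", ] <- 0
  full[, "X"] <- 0
  full
}

# Naive motif oracle: anchored regex tested against every substring that
# could match (fixed-length patterns only admit substrings of that length;
# the Walker B pattern needs length >= 5).
oracle_scan_motif <- function(sequence, motif, allow_gks = FALSE) {
  canon <- "[ACDEFGHIKLMNPQRSTVWY]"
  hydro <- "[AVILMFC]"
  gkt <- if (allow_gks) "GK[TS]" else "GKT"
  pat <- switch(motif,
    walkerA_atypical = list(rx = paste0("^G", canon, "{5}", gkt, "$"),
                            lens = 9L),
    walkerA_classic = list(rx = paste0("^G", canon, "{4}", gkt, "$"),
                           lens = 8L),
    walkerB = list(rx = paste0("^", hydro, "{3,}DE$"),
                   lens = 5L:nchar(sequence))
  )
  n <- nchar(sequence)
  starts <- integer(0); ends <- integer(0)
  for (len in pat$lens) {
    if (len > n) next
    st <- seq_len(n - len + 1L)
    sub <- substring(sequence, st, st + len - 1L)
    hit <- grepl(pat$rx, sub)
    starts <- c(starts, st[hit])
    ends <- c(ends, st[hit] + len - 1L)
  }
  if (length(starts) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  }
  o <- order(starts, ends)
  data.frame(start = starts[o], end = ends[o],
             match = substring(sequence, starts[o], ends[o]),
             stringsAsFactors = FALSE)
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                      "K", "L", "M", "N", "P", "Q", "R", "S",
                                      "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
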