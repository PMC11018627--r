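# Amino-acid alphabets used throughout. Sequences may carry the ambiguity
# letters B/Z and selenocysteine U plus the wildcard X after normalization;
# motif scanning and mutation draw only from the 20 canonical residues.

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_CANONICAL, "X", "U", "B", "Z")

# hydrophobic set used for the Walker B consensus (hhh followed by DE)
AA_HYDROPHOBIC <- c("A", "V", "I", "L", "M", "F", "C")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

normalize_sequence <- function(x, context = "sequence") {
  x <- toupper(gsub("[[:space:]]", "", x))
  if (nchar(x) == 0L) {
    stop_validation(sprintf("%s is empty after normalization", context))
  }
  bad <- setdiff(unique(seq_chars(x)), AA_ALLOWED)
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "%s contains letters outside the allowed amino-acid alphabet: %s",
      context, paste(bad, collapse = ", ")
    ))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# %.17g round-trips doubles through text exactly
format_num <- function(x) {
  ifelse(is.na(x), "NA", vapply(x, function(v) sprintf("%.17g", v), ""))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_validation(sprintf("%s must be a single number in [0, 1], got %s",
                            name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}
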