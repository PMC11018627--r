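#' Reference annotation for KdpD
#'
#' A reference annotation bundles the reference KdpD amino-acid sequence,
#' its domain intervals (1-based inclusive), and the anchor residues used
#' for capability calls. For \emph{E. coli} KdpD (894 residues) the anchors
#' are the atypical Walker A triad G36/K37/T38, the adenine-coordinating
#' W39/R190 pair, the Walker B pair D109/E110 (all in the N-terminal KdpD
#' domain, residues 1-230), and the histidine-kinase catalytic H673 inside
#' the DHp/CA transmitter (residues 663-894). The Usp, TM and GAF interval
#' boundaries are not fixed by the residue numbering above; the shipped
#' defaults are reconstructions and can be overridden via [read_reference()].
#'
#' @param id reference identifier.
#' @param sequence reference amino-acid sequence.
#' @param domains named list of `c(start, end)` intervals; must contain
#'   `KdpD`, `Usp`, `TM`, `GAF`, `DHpCA`.
#' @param anchors named integer vector of anchor positions; must contain
#'   `walkerA_G`, `walkerA_K`, `walkerA_T`, `adenine_W`, `walkerB_D`,
#'   `walkerB_E`, `adenine_R`, `HK_His`.
#' @return an object of class `kdpd_reference`.
#' @export
new_reference <- function(id, sequence, domains, anchors) {
  sequence <- normalize_sequence(sequence, "reference sequence")
  anchors <- unlist(anchors)
  storage.mode(anchors) <- "integer"
  domains <- lapply(domains, function(d) as.integer(unlist(d)))
  ref <- structure(
    list(id = id, sequence = sequence, domains = domains, anchors = anchors),
    class = "kdpd_reference"
  )
  validate_reference(ref)
  ref
}

anchor_letters <- c(
  walkerA_G = "G", walkerA_K = "K", walkerA_T = "T", adenine_W = "W",
  walkerB_D = "D", walkerB_E = "E", adenine_R = "R", HK_His = "H"
)

# anchors expected inside the N-terminal KdpD domain; HK_His sits in DHpCA
ntd_anchor_names <- c("walkerA_G", "walkerA_K", "walkerA_T", "adenine_W",
                      "walkerB_D", "walkerB_E", "adenine_R")

#' Validate a reference annotation
#'
#' Checks that all domain intervals lie within the sequence, that every
#' anchor lies inside its expected domain (the Walker A/B and adenine
#' anchors inside `KdpD`, `HK_His` inside `DHpCA`), and that the residue at
#' each anchor matches its expected letter (G, K, T, W, D, E, R, H).
#'
#' @param ref a `kdpd_reference`.
#' @return `ref`, invisibly; signals a validation error otherwise.
#' @export
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "kdpd_reference"))
  n <- nchar(ref$sequence)
  need_dom <- c("KdpD", "Usp", "TM", "GAF", "DHpCA")
  missing_dom <- setdiff(need_dom, names(ref$domains))
  if (length(missing_dom)) {
    stop_validation(paste("reference lacks domain interval(s):",
                          paste(missing_dom, collapse = ", ")))
  }
  for (dn in names(ref$domains)) {
    d <- ref$domains[[dn]]
    if (length(d) != 2L || d[1] < 1L || d[2] > n || d[1] > d[2]) {
      stop_validation(sprintf("domain %s interval [%s] is not within 1..%d",
                              dn, paste(d, collapse = ","), n))
    }
  }
  missing_anchor <- setdiff(names(anchor_letters), names(ref$anchors))
  if (length(missing_anchor)) {
    stop_validation(paste("reference lacks anchor(s):",
                          paste(missing_anchor, collapse = ", ")))
  }
  chars <- seq_chars(ref$sequence)
  for (an in names(anchor_letters)) {
    pos <- ref$anchors[[an]]
    home <- if (an %in% ntd_anchor_names) ref$domains$KdpD else ref$domains$DHpCA
    if (pos < home[1] || pos > home[2]) {
      stop_validation(sprintf("anchor %s (%d) lies outside its domain [%d,%d]",
                              an, pos, home[1], home[2]))
    }
    if (chars[pos] != anchor_letters[[an]]) {
      stop_validation(sprintf(
        "anchor %s: residue at %d is %s, expected %s",
        an, pos, chars[pos], anchor_letters[[an]]))
    }
  }
  invisible(ref)
}

# run code under a private, fixed RNG stream without disturbing the caller's
with_fixed_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic KdpD reference
#'
#' Returns the package's built-in reference annotation: a constructed
#' (synthetic) 894-residue sequence satisfying every invariant of a KdpD
#' reference — GKT at 36-38 preceded by the motif glycine at 30, W39,
#' D109/E110 preceded by a hydrophobic stretch, R190, H673 — with the
#' standard domain intervals (`KdpD` 1-230, `DHpCA` 663-894; `Usp`, `TM`,
#' `GAF` boundaries are reconstructions tiling the remainder). The sequence
#' is sanitized so that the Walker A GKT at 36-38 is the only GKT in the
#' molecule and the only Walker B pattern in the N-terminal domain is the
#' one ending at E110, which makes planted-motif bookkeeping exact for the
#' synthetic proteome generator. It is deterministic across sessions.
#'
#' This is a synthetic stand-in for a real curated KdpD record; supply one
#' (e.g. UniProt P21865 for \emph{E. coli}) via [read_reference()] to run
#' against real annotations.
#'
#' @return a `kdpd_reference`.
#' @examples
#' ref <- kdpd_reference()
#' substr(ref$sequence, 36, 39)  # "GKTW"
#' @export
kdpd_reference <- function() {
  if (is.null(.kdparch_env$default_ref)) {
    .kdparch_env$default_ref <- build_synthetic_reference()
  }
  .kdparch_env$default_ref
}

kdpd_domains_default <- list(
  KdpD = c(1L, 230L), Usp = c(231L, 395L), TM = c(396L, 500L),
  GAF = c(501L, 662L), DHpCA = c(663L, 894L)
)

kdpd_anchors_default <- c(
  walkerA_G = 36L, walkerA_K = 37L, walkerA_T = 38L, adenine_W = 39L,
  walkerB_D = 109L, walkerB_E = 110L, adenine_R = 190L, HK_His = 673L
)

build_synthetic_reference <- function() {
  with_fixed_rng(19404L, {
    n <- 894L
    chars <- sample(AA_CANONICAL, n, replace = TRUE)
    # planted anchors and motif context
    chars[30] <- "G"                       # leading G of G-X5-GKT
    chars[36:39] <- c("G", "K", "T", "W")
    chars[106:108] <- c("I", "V", "L")     # hydrophobic run before Walker B
    chars[109:110] <- c("D", "E")
    chars[190] <- "R"
    chars[673] <- "H"

    dom <- kdpd_domains_default
    for (iter in 1:50) {
      s <- paste(chars, collapse = "")
      dirty <- FALSE
      # exactly one GKT, at 36 (kills every stray Walker A pattern)
      g <- gregexpr("(?=GKT)", s, perl = TRUE)[[1]]
      stray <- setdiff(if (g[1] == -1L) integer() else as.integer(g), 36L)
      if (length(stray)) {
        chars[stray + 1L] <- "N"
        dirty <- TRUE
      }
      # in the NTD, the only hydrophobic-run/DE pattern ends at E110
      hits <- scan_motif(s, "walkerB", interval = dom$KdpD)
      bad <- hits$end[hits$end != 110L]
      if (length(bad)) {
        chars[bad] <- "Q"
        dirty <- TRUE
      }
      # domain-initial KT would form GKT across a G-rich linker junction
      # when the generator concatenates segments
      for (st in vapply(dom, `[`, integer(1), 1L)) {
        if (st > 1L && chars[st] == "K" && st < n && chars[st + 1L] == "T") {
          chars[st] <- "Q"
          dirty <- TRUE
        }
      }
      if (!dirty) break
    }
    ref <- new_reference(
      id = "KdpD_reference_synthetic",
      sequence = paste(chars, collapse = ""),
      domains = dom,
      anchors = kdpd_anchors_default
    )
    # construction guarantees for generator bookkeeping
    hitA <- scan_motif(ref$sequence, "walkerA_atypical")
    stopifnot(nrow(hitA) == 1L, hitA$start == 30L, hitA$end == 38L)
    ref
  })
}

#' Read or write a reference annotation (YAML/JSON)
#'
#' The on-disk document has fields `id`, `sequence`, `domains` (named
#' two-element start/end lists) and `anchors` (named positions). Format is
#' chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return [read_reference()] returns a validated `kdpd_reference`;
#'   [write_reference()] returns `path` invisibly.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    stop_missing_input(sprintf("reference annotation file not found: %s", path))
  }
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  need <- c("id", "sequence", "domains", "anchors")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop_schema(paste("reference document lacks field(s):",
                      paste(missing, collapse = ", ")))
  }
  new_reference(doc$id, doc$sequence, doc$domains, doc$anchors)
}

#' @rdname read_reference
#' @param ref a `kdpd_reference` to serialize.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "kdpd_reference"))
  doc <- list(
    id = ref$id, sequence = ref$sequence,
    domains = lapply(ref$domains, as.integer),
    anchors = as.list(ref$anchors)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.kdpd_reference <- function(x, ...) {
  cat(sprintf("KdpD reference '%s' (%d aa)\n", x$id, nchar(x$sequence)))
  for (dn in names(x$domains)) {
    cat(sprintf("  %-6s %4d-%4d\n", dn, x$domains[[dn]][1], x$domains[[dn]][2]))
  }
  cat("  anchors:", paste(sprintf("%s=%d", names(x$anchors), x$anchors),
                          collapse = " "), "\n")
  invisible(x)
}
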