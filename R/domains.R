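#' Check conservation of a reference anchor residue in a query
#'
#' Projects a reference position through the alignment and tests whether
#' the query carries the expected residue in the homologous column. This is
#' the mechanism used for the HK catalytic histidine (H673) and for the
#' Walker B (D109/E110) and adenine-pair (W39/R190) conservation checks.
#'
#' @param aln a `kdpd_alignment` of the query against the reference.
#' @param position 1-based reference position of the anchor.
#' @param expected expected single residue letter.
#' @return `TRUE` iff the projected column is not a gap and the query
#'   residue there equals `expected`.
#' @export
check_anchor_residue <- function(aln, position, expected) {
  qpos <- project_positions(aln, position)
  !is.na(qpos) && substr(aln$query, qpos, qpos) == expected
}

#' Call presence of a reference domain in a query chain
#'
#' Projects a reference domain interval through the alignment and measures
#' coverage (fraction of reference-domain columns aligned to query
#' residues) and local identity (fraction identical over those columns).
#' The domain is called present when both clear their thresholds.
#'
#' @param aln a `kdpd_alignment`.
#' @param interval `c(start, end)` reference interval, 1-based inclusive.
#' @param coverage_min minimum coverage for presence (default 0.6).
#' @param identity_min minimum local identity for presence (default 0.2).
#' @param domain optional domain name carried into the result.
#' @return an object of class `kdpd_domain_call`: list with `domain`,
#'   `present`, `coverage`, `identity` (`NA` when no column maps),
#'   and `query_interval` (`c(start, end)` or `NULL`).
#' @export
call_domain <- function(aln, interval, coverage_min = 0.6,
                        identity_min = 0.2, domain = NA_character_) {
  stopifnot(inherits(aln, "kdpd_alignment"))
  check_fraction(coverage_min, "coverage_min")
  check_fraction(identity_min, "identity_min")
  m <- length(aln$column_map)
  if (length(interval) != 2L || interval[1] < 1L || interval[2] > m ||
      interval[1] > interval[2]) {
    stop_validation(sprintf("domain interval must lie within 1..%d", m))
  }
  cols <- interval[1]:interval[2]
  qpos <- aln$column_map[cols]
  mapped <- which(!is.na(qpos))
  coverage <- length(mapped) / length(cols)
  if (length(mapped)) {
    rc <- substring(aln$reference, cols[mapped], cols[mapped])
    qc <- substring(aln$query, qpos[mapped], qpos[mapped])
    identity <- mean(rc == qc)
    qint <- range(qpos[mapped])
  } else {
    identity <- NA_real_
    qint <- NULL
  }
  present <- coverage >= coverage_min && isTRUE(identity >= identity_min)
  structure(
    list(domain = domain, present = present, coverage = coverage,
         identity = identity, query_interval = qint),
    class = "kdpd_domain_call"
  )
}

#' @export
print.kdpd_domain_call <- function(x, ...) {
  cat(sprintf("domain %s: %s (coverage %.2f, identity %s)\n",
              x$domain, if (x$present) "present" else "absent", x$coverage,
              if (is.na(x$identity)) "NA" else sprintf("%.2f", x$identity)))
  invisible(x)
}
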