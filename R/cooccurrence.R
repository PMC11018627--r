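# Version-distribution and gene co-occurrence summaries: the distribution
# of KdpD versions overall and per phylum, the split of versions by
# presence of the response regulator KdpE, and the association of
# TM/GAF-less versions with diadenylate cyclases.

#' Distribution of species version classes
#'
#' Counts and proportions of species classes, overall or per group.
#' `ABSENT` species (metadata rows with no surviving chain) form their own
#' category; `proportion` uses all species of the group as denominator,
#' while `proportion_excl_absent` re-bases on non-`ABSENT` species (`NA`
#' for the `ABSENT` rows themselves).
#'
#' @param species_calls data.frame of [classify_species()] rows.
#' @param by `NULL` for a single overall table, or the name of a grouping
#'   column (typically `"phylum"`).
#' @return data.frame with columns `group`, `class`, `n_group`, `count`,
#'   `proportion`, `proportion_excl_absent`; zero rows for empty input.
#' @export
version_distribution <- function(species_calls, by = NULL) {
  empty <- data.frame(group = character(), class = character(),
                      n_group = integer(), count = integer(),
                      proportion = numeric(),
                      proportion_excl_absent = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(species_calls) || nrow(species_calls) == 0L) return(empty)
  grp <- if (is.null(by)) rep("all", nrow(species_calls)) else {
    if (!by %in% names(species_calls)) {
      stop_validation(sprintf("grouping column '%s' not found", by))
    }
    as.character(species_calls[[by]])
  }
  out <- empty
  for (g in sort(unique(grp), method = "radix")) {
    cls <- species_calls$class[grp == g]
    n <- length(cls)
    n_present <- sum(cls != "ABSENT")
    seen <- intersect(SPECIES_CLASSES, unique(cls))  # canonical order
    cnt <- vapply(seen, function(k) sum(cls == k), integer(1))
    out <- rbind(out, data.frame(
      group = g, class = seen, n_group = n, count = unname(cnt),
      proportion = unname(cnt) / n,
      proportion_excl_absent = ifelse(
        seen == "ABSENT", NA_real_,
        if (n_present > 0) unname(cnt) / n_present else NA_real_),
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Cross-tabulate a boolean outcome against a boolean split
#'
#' Produces per-group counts and percentages of a boolean outcome over the
#' two groups defined by a boolean split variable — e.g. the percentage of
#' HK-capable KdpD systems among species with vs. without KdpE, or the
#' percentage of diadenylate-cyclase carriers among species whose KdpD
#' lacks the TM/GAF sensing domains. An empty split group is reported with
#' `n = 0` and `NA` percentages (an explicit null, never a silent zero).
#'
#' @param data data.frame holding (or computing) both variables, typically
#'   species calls merged with metadata.
#' @param outcome,split a column name, or a function of `data` returning a
#'   logical vector.
#' @param outcome_name,split_name labels for the report (default: deparsed
#'   arguments).
#' @param wilson add a Wilson 95% score interval per percentage
#'   (off by default).
#' @return an object of class `contingency_summary`: a data.frame with one
#'   row per split group (`TRUE`, `FALSE`) and columns `n`, `n_true`,
#'   `n_false`, `pct_true`, `pct_false` (+ `wilson_lo`/`wilson_hi`), with
#'   the variable names in attributes.
#' @examples
#' d <- data.frame(hk = c(TRUE, TRUE, FALSE, TRUE),
#'                 kdpe = c(TRUE, TRUE, FALSE, FALSE))
#' crosstab_binary(d, "hk", "kdpe")
#' @export
crosstab_binary <- function(data, outcome, split,
                            outcome_name = NULL, split_name = NULL,
                            wilson = FALSE) {
  eval_pred <- function(p, what) {
    v <- if (is.function(p)) p(data) else data[[p]]
    if (is.null(v) || !is.logical(v) || length(v) != nrow(data)) {
      stop_validation(sprintf(
        "%s must name a logical column or be a predicate returning one logical per row", what))
    }
    v
  }
  out_v <- eval_pred(outcome, "outcome")
  spl_v <- eval_pred(split, "split")
  outcome_name <- outcome_name %||%
    (if (is.character(outcome)) outcome else "outcome")
  split_name <- split_name %||%
    (if (is.character(split)) split else "split")
  rows <- lapply(c(TRUE, FALSE), function(g) {
    sel <- !is.na(spl_v) & spl_v == g
    n <- sum(sel)
    nt <- sum(out_v[sel], na.rm = TRUE)
    r <- data.frame(
      split_value = g, n = n, n_true = nt, n_false = n - nt,
      pct_true = if (n > 0) 100 * nt / n else NA_real_,
      pct_false = if (n > 0) 100 * (n - nt) / n else NA_real_
    )
    if (wilson) {
      ci <- if (n > 0) wilson_interval(nt, n) else c(NA_real_, NA_real_)
      r$wilson_lo <- 100 * ci[1]
      r$wilson_hi <- 100 * ci[2]
    }
    r
  })
  res <- do.call(rbind, rows)
  attr(res, "outcome") <- outcome_name
  attr(res, "split") <- split_name
  class(res) <- c("contingency_summary", "data.frame")
  res
}

# Wilson 95% score interval for a binomial proportion
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.contingency_summary <- function(x, ...) {
  cat(sprintf("Cross-tabulation of '%s' by '%s'\n",
              attr(x, "outcome"), attr(x, "split")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
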