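#' Classify a set of KdpD chains across species
#'
#' The package's main entry point: curates candidate chains against the
#' reference, classifies each surviving chain by domain architecture and
#' kinase capability, and aggregates chains into species-level version
#' calls. Species listed in the metadata but left without a surviving
#' chain are reported as `ABSENT`.
#'
#' @param chains data.frame with `accession`, `species_id`, `sequence`
#'   (from [read_fasta()] or [generate_dataset()]).
#' @param species optional species metadata data.frame (from
#'   [read_species_table()]); when `NULL`, a minimal table is derived from
#'   the distinct `species_id` values on the chains.
#' @param reference a `kdpd_reference` (default: the built-in synthetic
#'   reference, [kdpd_reference()]).
#' @param config a [classify_config()].
#' @return an object of class `kdpd_arch` with components `chain_calls`,
#'   `species_calls`, `rejected`, `counts`, `reference_id`, `config`.
#' @examples
#' sim <- generate_dataset(generator_config(n_species = 5, seed = 1))
#' fit <- kdpd_classify(sim$chains, sim$species)
#' summary(fit)
#' @export
kdpd_classify <- function(chains, species = NULL,
                          reference = kdpd_reference(),
                          config = classify_config()) {
  if (!is.data.frame(chains) ||
      !all(c("accession", "species_id", "sequence") %in% names(chains))) {
    stop_validation(
      "chains must be a data.frame with accession, species_id, sequence")
  }
  if (!is.null(species)) {
    chains <- join_dataset(chains, species)
  } else {
    ids <- unique(chains$species_id)
    species <- data.frame(
      species_id = ids, phylum = rep(NA_character_, length(ids)),
      has_kdpE = rep(NA, length(ids)), has_dac = rep(NA, length(ids)),
      chain_accessions = vapply(ids, function(s)
        paste(chains$accession[chains$species_id == s], collapse = ";"), ""),
      stringsAsFactors = FALSE
    )
  }
  cur <- curate_chains(chains, reference, config)
  chain_calls <- if (nrow(cur$kept)) {
    do.call(rbind, lapply(seq_len(nrow(cur$kept)), function(i) {
      classify_chain(cur$kept[i, ], reference, config,
                     aln = cur$alignments[[cur$kept$accession[i]]])
    }))
  } else {
    classify_chain(list(accession = "x", species_id = "x",
                        sequence = reference$sequence),
                   reference, config)[0, ]
  }
  species_calls <- do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
    sel <- chain_calls[chain_calls$species_id == species$species_id[i], ,
                       drop = FALSE]
    classify_species(species[i, ], sel)
  }))
  if (is.null(species_calls)) {
    species_calls <- classify_species(
      list(species_id = "x"), chain_calls[0, ])[0, ]
  }
  counts <- c(read = nrow(chains), curated = nrow(cur$kept),
              rejected = nrow(cur$rejected), classified = nrow(chain_calls),
              species = nrow(species_calls))
  if (counts[["read"]] != counts[["curated"]] + counts[["rejected"]] ||
      counts[["classified"]] != counts[["curated"]]) {
    stop_internal("record-count conservation violated in classification")
  }
  structure(
    list(chain_calls = chain_calls, species_calls = species_calls,
         rejected = cur$rejected, counts = counts,
         reference_id = reference$id, config = config),
    class = "kdpd_arch"
  )
}

#' @export
print.kdpd_arch <- function(x, ...) {
  cat("KdpD architecture classification\n")
  cat(sprintf("  reference: %s\n", x$reference_id))
  cat(sprintf("  chains: %d read, %d curated, %d rejected\n",
              x$counts[["read"]], x$counts[["curated"]],
              x$counts[["rejected"]]))
  cat(sprintf("  species: %d\n", x$counts[["species"]]))
  tab <- version_distribution(x$species_calls)
  if (nrow(tab)) {
    cat("  species classes:\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-22s %5d (%5.1f%%)\n", tab$class[i], tab$count[i],
                  100 * tab$proportion[i]))
    }
  }
  invisible(x)
}

#' @export
summary.kdpd_arch <- function(object, ...) {
  sc <- object$species_calls
  res <- list(
    counts = object$counts,
    distribution = version_distribution(sc),
    by_phylum = if (any(!is.na(sc$phylum)))
      version_distribution(sc, by = "phylum") else NULL,
    capabilities = c(
      ask_capable = sum(sc$ask_capable),
      hk_capable = sum(sc$hk_capable),
      n_species = nrow(sc)
    ),
    kdpe_crosstab = if (any(!is.na(sc$has_kdpE)))
      crosstab_binary(sc, "hk_capable", "has_kdpE") else NULL,
    dac_crosstab = if (any(!is.na(sc$has_dac)))
      crosstab_binary(sc, "has_dac",
                      function(d) !d$has_tm_gaf & d$class != "ABSENT",
                      split_name = "lacks_tm_gaf") else NULL
  )
  class(res) <- "summary.kdpd_arch"
  res
}

#' @export
print.summary.kdpd_arch <- function(x, ...) {
  cat("Species version distribution:\n")
  print.data.frame(x$distribution, row.names = FALSE, digits = 3)
  cat(sprintf("\nASK-capable species: %d / %d; HK-capable: %d / %d\n",
              x$capabilities[["ask_capable"]], x$capabilities[["n_species"]],
              x$capabilities[["hk_capable"]], x$capabilities[["n_species"]]))
  if (!is.null(x$kdpe_crosstab)) {
    cat("\nHK capability by KdpE presence:\n")
    print(x$kdpe_crosstab)
  }
  if (!is.null(x$dac_crosstab)) {
    cat("\nDiadenylate-cyclase presence by TM/GAF-less architecture:\n")
    print(x$dac_crosstab)
  }
  invisible(x)
}

#' @export
plot.kdpd_arch <- function(x, ...) {
  tab <- version_distribution(x$species_calls)
  if (!nrow(tab)) return(invisible(x))
  op <- par(mar = c(9, 4, 2, 1))
  on.exit(par(op))
  barplot(setNames(100 * tab$proportion, tab$class), las = 2,
          ylab = "% of species", main = "KdpD version distribution", ...)
  invisible(x)
}

#' Fig-style summary tables from a classification
#'
#' Re-derives the distribution and co-occurrence tables from species-level
#' calls: the overall and per-phylum version distributions, HK capability
#' split by KdpE presence (reported with both the per-species denominator,
#' the default reading, and the per-chain denominator), and
#' diadenylate-cyclase presence split by TM/GAF-less architecture.
#'
#' @param species_calls data.frame of species calls (columns as produced
#'   by [classify_species()]).
#' @param chain_calls optional chain calls for the per-chain denominator.
#' @param wilson add Wilson intervals to the crosstabs.
#' @return named list of data.frames.
#' @export
kdpd_summaries <- function(species_calls, chain_calls = NULL,
                           wilson = FALSE) {
  out <- list(
    distribution = version_distribution(species_calls),
    by_phylum = version_distribution(species_calls, by = "phylum"),
    hk_by_kdpe_species = crosstab_binary(species_calls, "hk_capable",
                                         "has_kdpE", wilson = wilson),
    dac_by_short = crosstab_binary(
      species_calls, "has_dac",
      function(d) !d$has_tm_gaf & d$class != "ABSENT",
      split_name = "lacks_tm_gaf", wilson = wilson)
  )
  if (!is.null(chain_calls) && nrow(chain_calls)) {
    merged <- merge(chain_calls,
                    species_calls[c("species_id", "has_kdpE")],
                    by = "species_id", sort = TRUE)
    out$hk_by_kdpe_chains <- crosstab_binary(merged, "hk_capable",
                                             "has_kdpE", wilson = wilson)
  }
  out
}
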