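# Readers and writers for the pipeline's on-disk formats.
#
# FASTA header dialect: ">accession|species_id" (pipe-delimited). Plain
# ">accession" headers are also accepted; the species is then resolved by
# joining against the species table ([join_dataset()]). All coordinates in
# every output are 1-based inclusive, matching residue numbering such as
# H673.

#' Read candidate chains from a protein multi-FASTA
#'
#' Headers are `>accession|species_id` or plain `>accession` (species then
#' `NA` until joined with a species table). Sequences are normalized to
#' uppercase, whitespace is stripped, and the alphabet is restricted to the
#' 20 canonical residues plus X/U/B/Z.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `accession`, `species_id`, `sequence`,
#'   one row per record in file order; zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_missing_input(sprintf("FASTA file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    return(data.frame(accession = character(), species_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop_parse(sprintf(
      "%s: line %d: expected a '>' FASTA header as the first record", path,
      nonblank[1]))
  }
  headers <- which(startsWith(trimws(lines), ">"))
  # a header directly followed by another header (or EOF) has no sequence
  nxt <- c(headers[-1], length(lines) + 1L)
  for (k in seq_along(headers)) {
    body <- lines[setdiff(seq(headers[k] + 1L, length.out = nxt[k] - headers[k] - 1L),
                          integer(0))]
    if (nxt[k] - headers[k] <= 1L || all(trimws(body) == "")) {
      stop_validation(sprintf("%s: line %d: header '%s' has an empty sequence",
                              path, headers[k], trimws(lines[headers[k]])))
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- trimws(names(set))
  acc <- sub("\\|.*$", "", ids)
  sp <- ifelse(grepl("|", ids, fixed = TRUE), sub("^[^|]*\\|", "", ids),
               NA_character_)
  seqs <- vapply(seq_along(set), function(i) {
    normalize_sequence(as.character(set[[i]]),
                       sprintf("%s: record '%s'", path, acc[i]))
  }, character(1))
  data.frame(accession = acc, species_id = sp, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write chains to FASTA
#'
#' Emits `>accession|species_id` headers (plain `>accession` when the
#' species is `NA`), wrapped at `width` columns.
#'
#' @param chains data.frame with `accession`, `species_id`, `sequence`.
#' @param path output path.
#' @param width line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path, width = 60L) {
  ids <- ifelse(is.na(chains$species_id), chains$accession,
                paste0(chains$accession, "|", chains$species_id))
  set <- Biostrings::BStringSet(setNames(chains$sequence, ids))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

species_table_columns <- c("species_id", "phylum", "has_kdpE", "has_dac",
                           "chain_accessions")

parse_bool_column <- function(x, column, path) {
  ok <- c("0", "1", "true", "false", "TRUE", "FALSE")
  bad <- setdiff(unique(x), ok)
  if (length(bad)) {
    stop_validation(sprintf(
      "%s: column %s contains token(s) %s; accepted: 0, 1, true, false",
      path, column, paste(sQuote(bad), collapse = ", ")))
  }
  x %in% c("1", "true", "TRUE")
}

#' Read the species metadata table
#'
#' Tab-separated with header columns `species_id`, `phylum`, `has_kdpE`,
#' `has_dac`, `chain_accessions` (semicolon-separated accession list, may
#' be empty). Booleans accept the tokens 0/1/true/false. Duplicate
#' `species_id` values are rejected.
#'
#' @param path path to the TSV.
#' @return data.frame with the columns above, booleans as logicals.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) {
    stop_missing_input(sprintf("species table not found: %s", path))
  }
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(species_table_columns, names(tab))
  if (length(missing)) {
    stop_schema(sprintf("%s: missing required column(s): %s", path,
                        paste(missing, collapse = ", ")))
  }
  dup <- unique(tab$species_id[duplicated(tab$species_id)])
  if (length(dup)) {
    stop_validation(sprintf("%s: duplicate species_id: %s", path,
                            paste(dup, collapse = ", ")))
  }
  tab$has_kdpE <- parse_bool_column(tab$has_kdpE, "has_kdpE", path)
  tab$has_dac <- parse_bool_column(tab$has_dac, "has_dac", path)
  tab[species_table_columns]
}

#' @rdname read_species_table
#' @param meta species metadata data.frame to write.
#' @export
write_species_table <- function(meta, path) {
  out <- meta
  out$has_kdpE <- as.integer(out$has_kdpE)
  out$has_dac <- as.integer(out$has_dac)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

split_accessions <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Join chains with species metadata
#'
#' Resolves every `chain_accessions` entry of the metadata against the
#' chain table and fills missing `species_id` values on the chains (the
#' join-by-table mode for plain `>accession` FASTA headers). A dangling
#' accession — listed in the metadata but absent from the FASTA — is a
#' validation error, as is a conflict between a header-supplied species and
#' the table.
#'
#' @param chains data.frame from [read_fasta()].
#' @param meta data.frame from [read_species_table()].
#' @return `chains` with `species_id` filled from the table.
#' @export
join_dataset <- function(chains, meta) {
  lookup <- character(0)
  for (i in seq_len(nrow(meta))) {
    for (acc in split_accessions(meta$chain_accessions[i])) {
      if (!acc %in% chains$accession) {
        stop_validation(sprintf(
          "species %s lists chain accession %s, not present in the FASTA",
          meta$species_id[i], acc))
      }
      lookup[acc] <- meta$species_id[i]
    }
  }
  mapped <- unname(lookup[chains$accession])
  conflict <- !is.na(chains$species_id) & !is.na(mapped) &
    chains$species_id != mapped
  if (any(conflict)) {
    stop_validation(sprintf(
      "species_id conflict between FASTA header and table for: %s",
      paste(chains$accession[conflict], collapse = ", ")))
  }
  chains$species_id <- ifelse(is.na(chains$species_id), mapped,
                              chains$species_id)
  chains
}

#' Write a tabular report (TSV) with optional JSON run metadata
#'
#' Numeric columns are serialized with 17 significant digits so that
#' re-reading the TSV reproduces the table exactly. When `metadata` is
#' non-empty, a JSON sidecar `<path>.meta.json` records it (typically the
#' config hash, seed and package version).
#'
#' @param report data.frame; all rows share the schema.
#' @param path output TSV path.
#' @param metadata optional named list written to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, metadata = NULL) {
  out <- report
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"),
    error = function(e) stop_io(sprintf("cannot write report to %s: %s",
                                        path, conditionMessage(e)))
  )
  if (!is.null(metadata) && length(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop_missing_input(sprintf("report not found: %s", path))
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}
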