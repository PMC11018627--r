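# Fixture builders shared across tests; everything is generated in code.

ref_fixture <- function() kdpd_reference()

# chain assembled from reference domain segments (unmutated template)
template_chain <- function(segments, reference = ref_fixture()) {
  kdparch:::build_chain_template(segments, reference)$sequence
}

toy_fasta <- function(path, records) {
  lines <- unlist(lapply(names(records), function(h) {
    c(paste0(">", h), records[[h]])
  }))
  writeLines(lines, path)
  path
}

toy_species_tsv <- function(path, rows) {
  header <- "species_id\tphylum\thas_kdpE\thas_dac\tchain_accessions"
  writeLines(c(header, rows), path)
  path
}
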