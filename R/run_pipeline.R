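# Pipeline driver with a config file, stage logging and exit-code
# contracts (0 ok, 2 missing input, 3 schema/validation/config failure,
# 4 internal invariant breach). The Rscript front-end in
# inst/scripts/kdparch is a thin wrapper around run_pipeline().

pipeline_config_spec <- list(
  fasta = NULL, species_table = NULL, reference = NULL, out_dir = "kdparch_out",
  alignment = list(matrix = "BLOSUM62", gap_open = 10, gap_ext = 1),
  thresholds = list(min_identity = 0.15, coverage_min = 0.6,
                    identity_min = 0.2),
  allow_gks = FALSE,
  report = list(wilson = FALSE),
  simulate = list(n_species = 100L, mutation_rate = 0.1,
                  protect_motifs = TRUE, class_probs = NULL,
                  ablation_rates = NULL, p_kdpe_given_hk = NULL,
                  p_kdpe_given_not_hk = NULL, p_dac_given_short = NULL,
                  p_dac_given_other = NULL, phylum_probs = NULL),
  seed = NULL,
  log_level = "info"
)

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_validation(sprintf("unknown config key(s)%s: %s",
                            if (nzchar(path)) paste0(" under ", path) else "",
                            paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], k)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected and
#' all thresholds are range-checked. [default_pipeline_config()] returns
#' the full default configuration (useful for auditing what a run used).
#'
#' @param config path to a YAML document, a named list of overrides, or
#'   `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(config = NULL) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_missing_input(sprintf("config file not found: %s", config))
    }
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop_validation("config must be a file path or a named list")
  }
  cfg <- merge_config(pipeline_config_spec, user)
  for (nm in names(cfg$thresholds)) check_fraction(cfg$thresholds[[nm]], nm)
  if (!is.null(cfg$simulate$mutation_rate)) {
    check_fraction(cfg$simulate$mutation_rate, "simulate.mutation_rate")
  }
  cfg
}

#' @rdname load_pipeline_config
#' @export
default_pipeline_config <- function() pipeline_config_spec

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # drop unserializable entries, canonicalize
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

log_line <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) {
    message(sprintf("[kdparch] %s", sprintf(...)))
  }
}

classify_config_from <- function(cfg) {
  classify_config(
    params = aln_params(cfg$alignment$matrix, cfg$alignment$gap_open,
                        cfg$alignment$gap_ext),
    min_identity = cfg$thresholds$min_identity,
    coverage_min = cfg$thresholds$coverage_min,
    identity_min = cfg$thresholds$identity_min,
    allow_gks = isTRUE(cfg$allow_gks)
  )
}

write_summary_tables <- function(tabs, out_dir, meta) {
  for (nm in names(tabs)) {
    write_report(as.data.frame(tabs[[nm]]),
                 file.path(out_dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a pipeline stage
#'
#' `simulate` writes a synthetic dataset (FASTA + species TSV + truth TSV);
#' `classify` runs curation and classification on a FASTA (+ optional
#' species table) and writes per-chain, per-species, rejection and summary
#' tables plus a JSON manifest with the config hash, input checksums and
#' record counts at each stage; `summarize` re-derives the summary tables
#' from an existing per-species table. Errors are caught and mapped to
#' exit-status integers (0 success, 2 missing input, 3 validation/schema/
#' config error, 4 internal invariant breach), which the command-line
#' wrapper passes to the shell.
#'
#' @param command one of `"simulate"`, `"classify"`, `"summarize"`.
#' @param config a YAML path or named list (see [load_pipeline_config()]).
#' @param seed optional integer overriding `config$seed` (simulate only).
#' @return the exit status, invisibly; written artifacts as side effects.
#' @export
run_pipeline <- function(command = c("simulate", "classify", "summarize"),
                         config = NULL, seed = NULL) {
  command <- match.arg(command)
  status <- tryCatch({
    cfg <- load_pipeline_config(config)
    if (!is.null(seed)) cfg$seed <- seed
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    switch(command,
           simulate = pipeline_simulate(cfg),
           classify = pipeline_classify(cfg),
           summarize = pipeline_summarize(cfg))
    0L
  },
  kdparch_missing_input_error = function(e) { message(conditionMessage(e)); 2L },
  kdparch_parse_error = function(e) { message(conditionMessage(e)); 3L },
  kdparch_schema_error = function(e) { message(conditionMessage(e)); 3L },
  kdparch_validation_error = function(e) { message(conditionMessage(e)); 3L },
  kdparch_config_error = function(e) { message(conditionMessage(e)); 3L },
  kdparch_io_error = function(e) { message(conditionMessage(e)); 3L },
  kdparch_internal_error = function(e) { message(conditionMessage(e)); 4L })
  invisible(status)
}

pipeline_simulate <- function(cfg) {
  if (is.null(cfg$seed)) stop_config("simulate requires a seed")
  sim_args <- cfg$simulate
  sim_args <- sim_args[!vapply(sim_args, is.null, logical(1))]
  sim_args$seed <- cfg$seed
  if (!is.null(sim_args$class_probs)) {
    sim_args$class_probs <- unlist(sim_args$class_probs)
  }
  if (!is.null(sim_args$ablation_rates)) {
    sim_args$ablation_rates <- unlist(sim_args$ablation_rates)
  }
  gcfg <- do.call(generator_config, sim_args)
  log_line(cfg, "simulate: %d species, seed %d", gcfg$n_species, gcfg$seed)
  res <- generate_dataset(gcfg, dir = cfg$out_dir)
  log_line(cfg, "simulate: wrote %d chains for %d species",
           nrow(res$chains), nrow(res$species))
  jsonlite::write_json(
    list(command = "simulate", config_hash = config_hash(cfg),
         seed = cfg$seed, version = as.character(packageVersion("kdparch")),
         counts = list(species = nrow(res$species),
                       chains = nrow(res$chains))),
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

pipeline_classify <- function(cfg) {
  if (is.null(cfg$fasta)) stop_config("classify requires config$fasta")
  chains <- read_fasta(cfg$fasta)
  log_line(cfg, "classify: read %d chains from %s", nrow(chains), cfg$fasta)
  species <- if (!is.null(cfg$species_table)) {
    read_species_table(cfg$species_table)
  } else NULL
  reference <- if (!is.null(cfg$reference)) {
    read_reference(cfg$reference)
  } else kdpd_reference()
  ccfg <- classify_config_from(cfg)
  fit <- kdpd_classify(chains, species, reference, ccfg)
  log_line(cfg, "classify: %d curated, %d rejected, %d species",
           fit$counts[["curated"]], fit$counts[["rejected"]],
           fit$counts[["species"]])
  write_report(fit$chain_calls, file.path(cfg$out_dir, "chain_calls.tsv"))
  write_report(fit$species_calls, file.path(cfg$out_dir, "species_calls.tsv"))
  write_report(fit$rejected, file.path(cfg$out_dir, "rejected.tsv"))
  tabs <- kdpd_summaries(fit$species_calls, fit$chain_calls,
                         wilson = isTRUE(cfg$report$wilson))
  inputs <- as.character(c(cfg$fasta, cfg$species_table, cfg$reference))
  meta <- list(
    command = "classify", config_hash = config_hash(cfg),
    version = as.character(packageVersion("kdparch")),
    reference = reference$id,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    counts = as.list(fit$counts)
  )
  write_summary_tables(tabs, cfg$out_dir, meta)
  log_line(cfg, "classify: wrote tables to %s", cfg$out_dir)
  invisible(fit)
}

pipeline_summarize <- function(cfg) {
  sc_path <- file.path(cfg$out_dir, "species_calls.tsv")
  if (!is.null(cfg$species_table)) sc_path <- cfg$species_table
  if (!file.exists(sc_path)) {
    stop_missing_input(sprintf("per-species table not found: %s", sc_path))
  }
  sc <- read_report(sc_path)
  need <- c("species_id", "class", "ask_capable", "hk_capable",
            "has_tm_gaf", "has_kdpE", "has_dac")
  missing <- setdiff(need, names(sc))
  if (length(missing)) {
    stop_schema(sprintf("%s: missing column(s): %s", sc_path,
                        paste(missing, collapse = ", ")))
  }
  cc_path <- file.path(cfg$out_dir, "chain_calls.tsv")
  cc <- if (file.exists(cc_path)) read_report(cc_path) else NULL
  log_line(cfg, "summarize: %d species", nrow(sc))
  tabs <- kdpd_summaries(sc, cc, wilson = isTRUE(cfg$report$wilson))
  meta <- list(
    command = "summarize", config_hash = config_hash(cfg),
    version = as.character(packageVersion("kdparch")),
    counts = list(species = nrow(sc))
  )
  write_summary_tables(tabs, cfg$out_dir, meta)
  invisible(tabs)
}
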