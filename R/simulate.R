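# Synthetic proteome generator with planted architectures.
#
# Species are simulated by drawing an architecture class, building each
# chain from the reference's domain segments (joined by short G-rich
# linkers that cannot complete a Walker pattern across a junction),
# optionally ablating motifs (Walker A GKT->AAC, Walker B DE->AA, HK
# His->A), applying point mutations that may protect anchor/motif spans,
# and sampling KdpE / diadenylate-cyclase presence from a conditional
# model given the planted capabilities. The emitted truth table is the
# oracle for every downstream stage.

CLASS_SEGMENTS <- list(
  FULL_LENGTH = list(c("KdpD", "Usp", "TM", "GAF", "DHpCA")),
  SHORT_KDPD_USP = list(c("KdpD", "Usp")),
  SPLIT_ASK_HK = list(c("KdpD", "Usp"), c("TM", "GAF", "DHpCA")),
  HK_TRUNCATED = list(c("KdpD", "Usp", "TM", "GAF")),
  KDPD_ONLY = list(c("KdpD"))
)

LINKER <- "GGSGG"

# default phylum labels; sampling is independent of class (decorative)
DEFAULT_PHYLA <- c("Pseudomonadota", "Bacillota", "Bacteroidota",
                   "Cyanobacteriota", "Deinococcota", "Acidobacteriota",
                   "Chloroflexota", "Myxococcota", "Campylobacterota",
                   "Archaea")

#' Generator configuration
#'
#' Defines the study conditions a synthetic dataset emulates. The default
#' class mix puts roughly three quarters of species on the full-length
#' architecture with the remainder spread over the shorter variants, and
#' couples metadata to planted capability: KdpE is present with
#' probability 0.95 given an HK-capable system and 0.05 otherwise, and a
#' diadenylate cyclase with probability 0.9 for species whose KdpD lacks
#' the TM/GAF sensing domains (short classes) and 0.5 otherwise.
#'
#' @param n_species number of species to generate.
#' @param class_probs named probability vector over
#'   `FULL_LENGTH`, `SHORT_KDPD_USP`, `SPLIT_ASK_HK`, `HK_TRUNCATED`,
#'   `KDPD_ONLY`; must sum to 1.
#' @param mutation_rate per-residue substitution probability in `[0, 1]`.
#' @param protect_motifs when `TRUE` (default), anchor positions and motif
#'   spans are exempt from point mutation.
#' @param ablation_rates named vector `walkerA`, `walkerB`, `hk_his`:
#'   probability that an eligible chain carries the ablation.
#' @param p_kdpe_given_hk,p_kdpe_given_not_hk conditional probabilities of
#'   KdpE presence given species HK capability.
#' @param p_dac_given_short,p_dac_given_other conditional probabilities of
#'   diadenylate-cyclase presence given a short (TM/GAF-less) species class.
#' @param phylum_probs named probability vector of phylum labels.
#' @param seed mandatory integer seed; the dataset is fully reproducible
#'   from it.
#' @param reference the `kdpd_reference` whose domain segments are used.
#' @return an object of class `kdpd_generator_config`.
#' @export
generator_config <- function(n_species,
                             class_probs = c(FULL_LENGTH = 0.74,
                                             SHORT_KDPD_USP = 0.12,
                                             SPLIT_ASK_HK = 0.05,
                                             HK_TRUNCATED = 0.05,
                                             KDPD_ONLY = 0.04),
                             mutation_rate = 0.1,
                             protect_motifs = TRUE,
                             ablation_rates = c(walkerA = 0, walkerB = 0,
                                                hk_his = 0),
                             p_kdpe_given_hk = 0.95,
                             p_kdpe_given_not_hk = 0.05,
                             p_dac_given_short = 0.9,
                             p_dac_given_other = 0.5,
                             phylum_probs = NULL,
                             seed,
                             reference = kdpd_reference()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("a single integer seed is mandatory")
  }
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 0 ||
      n_species != floor(n_species)) {
    stop_config("n_species must be a non-negative integer")
  }
  if (is.null(names(class_probs)) ||
      !all(names(class_probs) %in% names(CLASS_SEGMENTS))) {
    stop_config(sprintf("class_probs names must be among: %s",
                        paste(names(CLASS_SEGMENTS), collapse = ", ")))
  }
  if (any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-12) {
    stop_config("class_probs must be non-negative and sum to 1")
  }
  check_fraction(mutation_rate, "mutation_rate")
  need_abl <- c("walkerA", "walkerB", "hk_his")
  if (is.null(names(ablation_rates)) ||
      !setequal(names(ablation_rates), need_abl)) {
    stop_config("ablation_rates must be named walkerA, walkerB, hk_his")
  }
  ablation_rates <- ablation_rates[need_abl]
  for (nm in need_abl) check_fraction(ablation_rates[[nm]], nm)
  for (nm in c("p_kdpe_given_hk", "p_kdpe_given_not_hk",
               "p_dac_given_short", "p_dac_given_other")) {
    check_fraction(get(nm), nm)
  }
  if (is.null(phylum_probs)) {
    phylum_probs <- setNames(rep(1 / length(DEFAULT_PHYLA),
                                 length(DEFAULT_PHYLA)), DEFAULT_PHYLA)
  }
  if (any(phylum_probs < 0) || abs(sum(phylum_probs) - 1) > 1e-12) {
    stop_config("phylum_probs must be non-negative and sum to 1")
  }
  stopifnot(inherits(reference, "kdpd_reference"))
  structure(
    list(n_species = as.integer(n_species), class_probs = class_probs,
         mutation_rate = mutation_rate, protect_motifs = protect_motifs,
         ablation_rates = ablation_rates,
         p_kdpe_given_hk = p_kdpe_given_hk,
         p_kdpe_given_not_hk = p_kdpe_given_not_hk,
         p_dac_given_short = p_dac_given_short,
         p_dac_given_other = p_dac_given_other,
         phylum_probs = phylum_probs, seed = as.integer(seed),
         reference = reference),
    class = "kdpd_generator_config"
  )
}

#' Point-mutate a sequence segment
#'
#' Each unprotected position is independently substituted with probability
#' `rate` by a uniformly drawn \emph{different} canonical residue.
#' Protected positions are never touched; length is preserved. Uses the
#' current RNG state.
#'
#' @param segment amino-acid string.
#' @param rate substitution probability in `[0, 1]`.
#' @param protected integer positions exempt from mutation.
#' @return the mutated string.
#' @export
mutate_segment <- function(segment, rate, protected = integer(0)) {
  check_fraction(rate, "rate")
  chars <- seq_chars(segment)
  n <- length(chars)
  hit <- runif(n) < rate
  if (length(protected)) hit[protected[protected >= 1 & protected <= n]] <- FALSE
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA_CANONICAL, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# chain template for one segment set: sequence, per-chain coordinates of
# anchors/motif spans, and which ablations the chain is eligible for
build_chain_template <- function(segments, reference) {
  dom <- reference$domains
  parts <- character(0)
  offsets <- integer(0)  # chain coordinate offset of each segment start
  pos <- 0L
  for (k in seq_along(segments)) {
    seg <- dom[[segments[k]]]
    if (k > 1L) {
      parts <- c(parts, LINKER)
      pos <- pos + nchar(LINKER)
    }
    offsets[segments[k]] <- pos
    parts <- c(parts, substr(reference$sequence, seg[1], seg[2]))
    pos <- pos + (seg[2] - seg[1] + 1L)
  }
  seqstr <- paste(parts, collapse = "")
  has_ntd <- "KdpD" %in% segments
  has_dhpca <- "DHpCA" %in% segments
  protected <- integer(0)
  sites <- list()
  if (has_ntd) {
    off <- offsets[["KdpD"]]  # KdpD segment starts at reference position 1
    sites$walkerA <- off + 36:38
    sites$walkerA_span <- off + 30:39          # leading G .. adenine W
    sites$walkerB <- off + 109:110
    sites$walkerB_span <- off + 106:110
    sites$adenine_R <- off + 190L
    protected <- c(protected, sites$walkerA_span, sites$walkerB_span,
                   sites$adenine_R)
  }
  if (has_dhpca) {
    off <- offsets[["DHpCA"]] - (dom$DHpCA[1] - 1L)
    sites$hk_his <- off + reference$anchors[["HK_His"]]
    protected <- c(protected, sites$hk_his)
  }
  list(sequence = seqstr, has_ntd = has_ntd, has_dhpca = has_dhpca,
       sites = sites, protected = sort(unique(protected)))
}

apply_ablation <- function(chars, template, which_abl) {
  s <- template$sites
  if (which_abl == "walkerA") chars[s$walkerA] <- c("A", "A", "C")
  if (which_abl == "walkerB") chars[s$walkerB] <- c("A", "A")
  if (which_abl == "hk_his") chars[s$hk_his] <- "A"
  chars
}

# sanity checks on the unmutated class templates: the planted Walker A is
# the only one, and Walker B ends where planted (no junction artifacts)
assert_templates <- function(templates) {
  for (cls in names(templates)) {
    for (tpl in templates[[cls]]) {
      hitsA <- scan_motif(tpl$sequence, "walkerA_atypical")
      if (tpl$has_ntd) {
        ok <- nrow(hitsA) == 1L && hitsA$start == 30L && hitsA$end == 38L
      } else {
        ok <- nrow(hitsA) == 0L
      }
      if (!ok) {
        stop_internal(sprintf(
          "template for class %s has unexpected Walker A hits", cls))
      }
      if (tpl$has_ntd) {
        hitsB <- scan_motif(tpl$sequence, "walkerB",
                            interval = c(1L, 230L))
        if (!all(hitsB$end == 110L) || nrow(hitsB) == 0L) {
          stop_internal(sprintf(
            "template for class %s has unexpected Walker B hits", cls))
        }
      }
    }
  }
}

#' Generate a synthetic species dataset with known truth
#'
#' Draws `n_species` species under a [generator_config()], writes the
#' three pipeline inputs/oracles — `chains.fasta`, `species.tsv`,
#' `truth.tsv` — into `dir`, and returns them in memory. Fully
#' reproducible: the same config and seed give byte-identical files.
#'
#' The truth table records, per species, the planted class, capability
#' flags and metadata, plus the per-chain planted classes and ablations
#' (semicolon-separated, aligned with `chain_accessions`). Species-level
#' truth is derived from the per-chain truth by the same aggregation rule
#' the classifier uses (a pure function of the labels), so recovery is
#' well-defined even for species carrying ablations.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed); `NULL` to skip writing.
#' @return list with `chains`, `species`, `truth` data.frames and `paths`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "kdpd_generator_config"))
  ref <- config$reference
  templates <- lapply(CLASS_SEGMENTS, function(segsets) {
    lapply(segsets, build_chain_template, reference = ref)
  })
  assert_templates(templates)

  set.seed(config$seed)
  n <- config$n_species
  classes <- if (n > 0) {
    sample(names(config$class_probs), n, replace = TRUE,
           prob = config$class_probs)
  } else character(0)
  phyla <- if (n > 0) {
    sample(names(config$phylum_probs), n, replace = TRUE,
           prob = config$phylum_probs)
  } else character(0)

  chain_rows <- list()
  species_rows <- list()
  truth_rows <- list()
  for (i in seq_len(n)) {
    sp <- sprintf("species_%05d", i)
    cls <- classes[i]
    tpls <- templates[[cls]]
    accs <- chclass <- abls <- character(length(tpls))
    ask_tr <- hk_tr <- dhpca_tr <- logical(length(tpls))
    ndom_tr <- integer(length(tpls))
    for (k in seq_along(tpls)) {
      tpl <- tpls[[k]]
      accs[k] <- sprintf("SYN%05d_%d", i, k)
      chars <- seq_chars(tpl$sequence)
      abl <- character(0)
      if (tpl$has_ntd &&
          runif(1) < config$ablation_rates[["walkerA"]]) abl <- c(abl, "walkerA")
      if (tpl$has_ntd &&
          runif(1) < config$ablation_rates[["walkerB"]]) abl <- c(abl, "walkerB")
      if (tpl$has_dhpca &&
          runif(1) < config$ablation_rates[["hk_his"]]) abl <- c(abl, "hk_his")
      for (a in abl) chars <- apply_ablation(chars, tpl, a)
      mutated <- mutate_segment(
        paste(chars, collapse = ""), config$mutation_rate,
        protected = if (config$protect_motifs) tpl$protected else integer(0)
      )
      chain_rows[[length(chain_rows) + 1L]] <- data.frame(
        accession = accs[k], species_id = sp, sequence = mutated,
        stringsAsFactors = FALSE
      )
      # planted chain labels
      segcls <- names(which(vapply(CLASS_SEGMENTS, function(ss)
        length(ss) == 1L && identical(ss[[1]],
          CLASS_SEGMENTS[[cls]][[k]]), logical(1))))
      chclass[k] <- if (length(segcls)) segcls else
        if (identical(CLASS_SEGMENTS[[cls]][[k]], c("TM", "GAF", "DHpCA")))
          "HK_ONLY_TM_GAF_DHPCA" else "OTHER"
      ask_tr[k] <- tpl$has_ntd && !("walkerA" %in% abl) &&
        !("walkerB" %in% abl)
      hk_tr[k] <- tpl$has_dhpca && !("hk_his" %in% abl)
      dhpca_tr[k] <- tpl$has_dhpca
      ndom_tr[k] <- length(CLASS_SEGMENTS[[cls]][[k]])
      abls[k] <- if (length(abl)) paste(abl, collapse = ",") else "none"
    }
    sp_ask <- any(ask_tr)
    sp_hk <- any(hk_tr)
    sp_class <- species_class_rule(chclass, ask_tr, hk_tr, dhpca_tr,
                                   ndom_tr, accs)
    short <- cls %in% c("SHORT_KDPD_USP", "KDPD_ONLY")
    has_kdpe <- runif(1) < if (sp_hk) config$p_kdpe_given_hk else
      config$p_kdpe_given_not_hk
    has_dac <- runif(1) < if (short) config$p_dac_given_short else
      config$p_dac_given_other
    species_rows[[i]] <- data.frame(
      species_id = sp, phylum = phyla[i], has_kdpE = has_kdpe,
      has_dac = has_dac, chain_accessions = paste(accs, collapse = ";"),
      stringsAsFactors = FALSE
    )
    truth_rows[[i]] <- data.frame(
      species_id = sp, phylum = phyla[i], has_kdpE = has_kdpe,
      has_dac = has_dac, true_class = sp_class,
      true_ask = sp_ask, true_hk = sp_hk,
      sampled_class = cls,
      chain_accessions = paste(accs, collapse = ";"),
      chain_classes = paste(chclass, collapse = ";"),
      chain_ablations = paste(abls, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  empty_chains <- data.frame(accession = character(),
                             species_id = character(),
                             sequence = character(), stringsAsFactors = FALSE)
  chains <- if (length(chain_rows)) do.call(rbind, chain_rows) else empty_chains
  species <- if (length(species_rows)) do.call(rbind, species_rows) else
    data.frame(species_id = character(), phylum = character(),
               has_kdpE = logical(), has_dac = logical(),
               chain_accessions = character(), stringsAsFactors = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "chains.fasta"),
      species = file.path(dir, "species.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_fasta(chains, paths$fasta)
    write_species_table(species, paths$species)
    tr <- truth
    tr$has_kdpE <- as.integer(tr$has_kdpE)
    tr$has_dac <- as.integer(tr$has_dac)
    tr$true_ask <- as.integer(tr$true_ask)
    tr$true_hk <- as.integer(tr$true_hk)
    utils::write.table(tr, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(chains = chains, species = species, truth = truth, paths = paths)
}
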