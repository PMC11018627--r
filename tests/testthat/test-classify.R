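test_that("curation keeps homologs and rejects unrelated sequences", {
  ref <- ref_fixture()
  set.seed(501)
  unrelated <- random_aa(300)
  chains <- data.frame(
    accession = c("REF", "JUNK"),
    species_id = c("sp1", "sp2"),
    sequence = c(ref$sequence, unrelated),
    stringsAsFactors = FALSE
  )
  cur <- curate_chains(chains, ref)
  expect_equal(cur$kept$accession, "REF")
  expect_equal(cur$kept$identity, 1)
  expect_equal(cur$kept$global_identity, 1)
  expect_equal(cur$rejected$accession, "JUNK")
  expect_equal(cur$rejected$reason, "low_identity_no_domain")
  expect_lt(cur$rejected$global_identity, 0.15)

  # an intact single-domain chain survives on length-normalized identity
  short <- data.frame(accession = "S1", species_id = "sp3",
                      sequence = template_chain(c("KdpD"), ref),
                      stringsAsFactors = FALSE)
  cs <- curate_chains(short, ref)
  expect_equal(cs$kept$accession, "S1")
  expect_gt(cs$kept$global_identity, 0.15)
  expect_lt(cs$kept$global_identity, 0.3)

  empty <- curate_chains(chains[0, ], ref)
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$rejected), 0L)
})

test_that("chain templates classify to their architecture with correct capabilities", {
  ref <- ref_fixture()
  cases <- list(
    list(segs = c("KdpD", "Usp", "TM", "GAF", "DHpCA"),
         class = "FULL_LENGTH", ask = TRUE, hk = TRUE),
    # the short KdpD/Usp architecture (D. geothermalis-type): ASK without HK
    list(segs = c("KdpD", "Usp"),
         class = "SHORT_KDPD_USP", ask = TRUE, hk = FALSE),
    list(segs = c("KdpD", "Usp", "TM", "GAF"),
         class = "HK_TRUNCATED", ask = TRUE, hk = FALSE),
    list(segs = c("KdpD"), class = "KDPD_ONLY", ask = TRUE, hk = FALSE),
    list(segs = c("TM", "GAF", "DHpCA"),
         class = "HK_ONLY_TM_GAF_DHPCA", ask = FALSE, hk = TRUE)
  )
  for (cs in cases) {
    chain <- list(accession = "t", species_id = "s",
                  sequence = template_chain(cs$segs, ref))
    call <- classify_chain(chain, ref)
    expect_equal(call$class, cs$class, info = paste(cs$segs, collapse = "+"))
    expect_equal(call$ask_capable, cs$ask)
    expect_equal(call$hk_capable, cs$hk)
  }
})

test_that("motif ablations flip capability flags without changing the class", {
  ref <- ref_fixture()
  full <- template_chain(c("KdpD", "Usp", "TM", "GAF", "DHpCA"), ref)

  wa <- full  # Walker A GKT -> AAC (G36A/K37A/T38C-style)
  substr(wa, 36, 38) <- "AAC"
  call_wa <- classify_chain(list(accession = "t", species_id = "s",
                                 sequence = wa), ref)
  expect_equal(call_wa$class, "FULL_LENGTH")
  expect_false(call_wa$ask_capable)
  expect_true(call_wa$hk_capable)

  wb <- full  # Walker B D109/E110 -> AA
  substr(wb, 109, 110) <- "AA"
  call_wb <- classify_chain(list(accession = "t", species_id = "s",
                                 sequence = wb), ref)
  expect_equal(call_wb$class, "FULL_LENGTH")
  expect_false(call_wb$ask_capable)
  expect_true(call_wb$hk_capable)

  hh <- full  # catalytic histidine H673 -> A
  pos <- 673L + 4L * nchar("GGSGG")  # four linkers precede the DHpCA segment
  expect_equal(substr(hh, pos, pos), "H")
  substr(hh, pos, pos) <- "A"
  call_hh <- classify_chain(list(accession = "t", species_id = "s",
                                 sequence = hh), ref)
  expect_equal(call_hh$class, "FULL_LENGTH")
  expect_true(call_hh$ask_capable)
  expect_false(call_hh$hk_capable)
})

test_that("species aggregation follows full-length precedence and split detection", {
  ref <- ref_fixture()
  mk_call <- function(acc, segs) {
    classify_chain(list(accession = acc, species_id = "sp",
                        sequence = template_chain(segs, ref)), ref)
  }
  full <- mk_call("A1", c("KdpD", "Usp", "TM", "GAF", "DHpCA"))
  short <- mk_call("A2", c("KdpD", "Usp"))
  hko <- mk_call("A3", c("TM", "GAF", "DHpCA"))
  meta <- list(species_id = "sp", phylum = "p", has_kdpE = TRUE,
               has_dac = FALSE)

  # a full-length variant dominates other variants of the same species
  sc <- classify_species(meta, rbind(full, short))
  expect_equal(sc$class, "FULL_LENGTH")
  expect_true(sc$ask_capable && sc$hk_capable)

  # ASK and HK on separate polypeptide chains
  sc2 <- classify_species(meta, rbind(short, hko))
  expect_equal(sc2$class, "SPLIT_ASK_HK")
  expect_true(sc2$ask_capable && sc2$hk_capable)
  expect_true(sc2$has_tm_gaf)

  sc3 <- classify_species(meta, short)
  expect_equal(sc3$class, "SHORT_KDPD_USP")
  expect_false(sc3$has_tm_gaf)

  sc4 <- classify_species(meta, full[0, ])
  expect_equal(sc4$class, "ABSENT")
  expect_false(sc4$ask_capable || sc4$hk_capable)
})

test_that("classification is a pure function of its inputs", {
  sim <- generate_dataset(generator_config(n_species = 12, seed = 77))
  f1 <- kdpd_classify(sim$chains, sim$species)
  f2 <- kdpd_classify(sim$chains, sim$species)
  expect_identical(f1$chain_calls, f2$chain_calls)
  expect_identical(f1$species_calls, f2$species_calls)
})
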