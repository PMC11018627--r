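test_that("mutate_segment respects rate, protection and length", {
  set.seed(701)
  s <- random_aa(50)
  expect_identical(mutate_segment(s, 0), s)
  expect_identical(mutate_segment(s, 1, protected = 1:50), s)
  m <- mutate_segment(s, 1)
  expect_equal(nchar(m), 50L)
  expect_equal(sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]]), 50L)
  # partial protection leaves exactly the protected sites untouched
  m2 <- mutate_segment(s, 1, protected = 1:10)
  expect_identical(substr(m2, 1, 10), substr(s, 1, 10))
  expect_equal(sum(strsplit(s, "")[[1]] != strsplit(m2, "")[[1]]), 40L)
})

test_that("generator configs are validated", {
  expect_error(generator_config(10), class = "kdparch_config_error")  # no seed
  expect_error(generator_config(10, class_probs = c(FULL_LENGTH = 0.7),
                                seed = 1),
               class = "kdparch_config_error")
  expect_error(generator_config(10, mutation_rate = 1.5, seed = 1),
               class = "kdparch_validation_error")
  expect_error(generator_config(10, ablation_rates = c(walkerA = 0.1),
                                seed = 1),
               class = "kdparch_config_error")
})

test_that("a degenerate all-full-length config yields only capable full-length species", {
  cfg <- generator_config(
    n_species = 15, class_probs = c(FULL_LENGTH = 1), mutation_rate = 0,
    seed = 5
  )
  sim <- generate_dataset(cfg)
  expect_true(all(sim$truth$true_class == "FULL_LENGTH"))
  expect_true(all(sim$truth$true_ask) && all(sim$truth$true_hk))
  fit <- kdpd_classify(sim$chains, sim$species)
  expect_true(all(fit$chain_calls$class == "FULL_LENGTH"))
  expect_true(all(fit$chain_calls$ask_capable))
  expect_true(all(fit$chain_calls$hk_capable))
})

test_that("identical configs and seeds give byte-identical output files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- function() generator_config(n_species = 25, mutation_rate = 0.1,
                                     ablation_rates = c(walkerA = 0.2,
                                                        walkerB = 0.1,
                                                        hk_his = 0.1),
                                     seed = 99)
  generate_dataset(cfg(), dir = d1)
  generate_dataset(cfg(), dir = d2)
  for (f in c("chains.fasta", "species.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted motifs survive mutation whenever protection is on", {
  sim <- generate_dataset(generator_config(n_species = 40,
                                           mutation_rate = 0.3, seed = 31))
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    accs <- strsplit(tr$chain_accessions[i], ";")[[1]]
    clss <- strsplit(tr$chain_classes[i], ";")[[1]]
    for (k in seq_along(accs)) {
      s <- sim$chains$sequence[sim$chains$accession == accs[k]]
      if (clss[k] != "HK_ONLY_TM_GAF_DHPCA") {
        # ASK-bearing chains: Walker A at 30-38, Walker B pair at 109-110
        expect_equal(substr(s, 36, 38), "GKT")
        expect_equal(substr(s, 30, 30), "G")
        expect_equal(substr(s, 109, 110), "DE")
        expect_equal(nrow(scan_motif(substr(s, 1, 230), "walkerA_atypical")),
                     1L)
      }
    }
  }
})

test_that("empirical class frequencies match configured probabilities", {
  probs <- c(FULL_LENGTH = 0.74, SHORT_KDPD_USP = 0.12, SPLIT_ASK_HK = 0.05,
             HK_TRUNCATED = 0.05, KDPD_ONLY = 0.04)
  sim <- generate_dataset(generator_config(n_species = 5000,
                                           class_probs = probs,
                                           mutation_rate = 0, seed = 41))
  freq <- table(factor(sim$truth$sampled_class, levels = names(probs))) / 5000
  for (cls in names(probs)) {
    se <- sqrt(probs[[cls]] * (1 - probs[[cls]]) / 5000)
    expect_lt(abs(freq[[cls]] - probs[[cls]]), 3 * se,
              label = paste("frequency deviation for", cls))
  }
})

test_that("truth capabilities agree with the classifier at zero mutation", {
  sim <- generate_dataset(generator_config(n_species = 40, mutation_rate = 0,
                                           seed = 53))
  fit <- kdpd_classify(sim$chains, sim$species)
  sc <- fit$species_calls[order(fit$species_calls$species_id), ]
  tr <- sim$truth[order(sim$truth$species_id), ]
  expect_equal(sc$class, tr$true_class)
  expect_equal(sc$ask_capable, tr$true_ask)
  expect_equal(sc$hk_capable, tr$true_hk)
})
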