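test_that("Walker motif patterns match their defining examples", {
  hits <- scan_motif("GAAAAAGKT", "walkerA_atypical")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$match, "GAAAAAGKT")

  expect_equal(nrow(scan_motif("AAAAAA", "walkerA_atypical")), 0L)
  # one spacer residue fewer: the classical P-loop, not the atypical one
  expect_equal(nrow(scan_motif("GAAAAGKT", "walkerA_atypical")), 0L)
  expect_equal(nrow(scan_motif("GAAAAGKT", "walkerA_classic")), 1L)

  hb <- scan_motif("AVLDEK", "walkerB")
  expect_equal(hb$start, 1L)
  expect_equal(hb$end, 5L)
  expect_equal(hb$match, "AVLDE")
})

test_that("overlapping hits are all reported, sorted by start", {
  # hydrophobic run of 4: two valid start positions for the same DE
  hb <- scan_motif("AAVLDE", "walkerB")
  expect_equal(hb$start, c(1L, 2L))
  expect_equal(hb$end, c(6L, 6L))
  two <- scan_motif("GAAAAAGKTGAAAAAGKT", "walkerA_atypical")
  expect_equal(two$start, c(1L, 10L))
})

test_that("ambiguity letters never satisfy a motif position", {
  expect_equal(nrow(scan_motif("GXXXXXGKT", "walkerA_atypical")), 0L)
  expect_equal(nrow(scan_motif("GABZUAGKT", "walkerA_atypical")), 0L)
  expect_equal(nrow(scan_motif("XVLDE", "walkerB")), 0L)
  # but canonical spacers around them still work
  expect_equal(nrow(scan_motif("GACDEFGKT", "walkerA_atypical")), 1L)
})

test_that("interval restriction keeps only hits fully inside the window", {
  s <- "GAAAAAGKTAAAVLDE"
  expect_equal(nrow(scan_motif(s, "walkerA_atypical", interval = c(1, 9))), 1L)
  expect_equal(nrow(scan_motif(s, "walkerA_atypical", interval = c(2, 16))), 0L)
  # the hydrophobic run A(10)A(11)A(12)V(13)L(14) before DE admits three starts
  expect_equal(scan_motif(s, "walkerB")$start, c(10L, 11L, 12L))
  expect_equal(scan_motif(s, "walkerB", interval = c(12, 16))$start, 12L)
  expect_error(scan_motif(s, "walkerB", interval = c(0, 5)),
               class = "kdparch_validation_error")
})

test_that("unknown motif names are a configuration error", {
  expect_error(scan_motif("GKT", "walkerC"), class = "kdparch_config_error")
})

test_that("the permissive switch admits GKS in Walker A", {
  expect_equal(nrow(scan_motif("GAAAAAGKS", "walkerA_atypical")), 0L)
  expect_equal(nrow(scan_motif("GAAAAAGKS", "walkerA_atypical",
                               allow_gks = TRUE)), 1L)
})

test_that("scan_motif equals the naive all-substrings oracle on random sequences", {
  set.seed(301)
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "B", "Z", "U",
                "G", "K", "T", "D", "E", "A", "V")  # bias towards motif letters
  for (rep in 1:40) {
    s <- random_aa(sample(20:150, 1), alphabet = alphabet)
    for (motif in c("walkerA_atypical", "walkerA_classic", "walkerB")) {
      got <- scan_motif(s, motif)
      want <- oracle_scan_motif(s, motif)
      expect_equal(got$start, want$start, info = paste(motif, s))
      expect_equal(got$end, want$end, info = paste(motif, s))
      expect_equal(got$match, want$match, info = paste(motif, s))
    }
  }
})
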