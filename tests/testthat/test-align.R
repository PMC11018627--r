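test_that("worked examples under the unit scheme score as expected", {
  a <- global_align("GKT", "GKT", unit_params())
  expect_equal(a$score, 3)
  expect_equal(a$identity, 1)
  expect_equal(a$column_map, 1:3)

  # GT vs GKT: best global alignment is G/-/T with one internal gap
  b <- global_align("GT", "GKT", unit_params())
  expect_equal(b$score, 0)  # frozen from the enumeration oracle
  expect_equal(b$column_map, c(1L, NA, 2L))

  # all-mismatch diagonal beats gapping under these penalties
  c <- global_align("AAAA", "GGGG", unit_params())
  expect_equal(c$score, -4)
  expect_equal(c$identity, 0)
})

test_that("empty sequences and bad params are rejected", {
  expect_error(global_align("", "GKT"), class = "kdparch_validation_error")
  expect_error(global_align("GKT", "  "), class = "kdparch_validation_error")
  expect_error(aln_params(gap_open = -1), class = "kdparch_validation_error")
})

test_that("self-alignment yields identity 1, identity map, diagonal score", {
  b62 <- blosum62_matrix()
  set.seed(101)
  for (rep in 1:20) {
    s <- random_aa(sample(5:60, 1))
    a <- global_align(s, s, aln_params())
    expect_equal(a$identity, 1)
    expect_equal(a$column_map, seq_len(nchar(s)))
    chars <- strsplit(s, "")[[1]]
    expect_equal(a$score, sum(b62[cbind(chars, chars)]))
  }
})

test_that("score is symmetric under argument swap for symmetric matrices", {
  set.seed(102)
  for (rep in 1:15) {
    x <- random_aa(sample(1:30, 1))
    y <- random_aa(sample(1:30, 1))
    expect_equal(global_align(x, y)$score, global_align(y, x)$score)
    expect_equal(global_align(x, y, unit_params())$score,
                 global_align(y, x, unit_params())$score)
  }
})

test_that("appending identical residues to both sequences never lowers the score", {
  set.seed(103)
  for (rep in 1:15) {
    x <- random_aa(sample(1:25, 1))
    y <- random_aa(sample(1:25, 1))
    tail <- random_aa(sample(1:10, 1))
    expect_gte(global_align(paste0(x, tail), paste0(y, tail))$score,
               global_align(x, y)$score)
  }
})

test_that("alignment agrees with an independent implementation on long pairs", {
  # Biostrings::pairwiseAlignment is a separate code path with the same
  # gap model (open + L * ext); enumeration is infeasible at this length
  set.seed(104)
  b62 <- blosum62_matrix()
  for (rep in 1:10) {
    x <- random_aa(sample(40:120, 1))
    y <- random_aa(sample(40:120, 1))
    ours <- global_align(x, y, aln_params())$score
    theirs <- Biostrings::score(Biostrings::pairwiseAlignment(
      x, y, substitutionMatrix = b62, gapOpening = 10, gapExtension = 1,
      type = "global"))
    expect_equal(ours, theirs)
  }
})

test_that("the wildcard X scores zero against everything", {
  a <- global_align("AXC", "AGC", aln_params())
  b62 <- blosum62_matrix()
  expect_equal(a$score, b62["A", "A"] + 0 + b62["C", "C"])
  expect_equal(a$column_map, 1:3)
})

test_that("column maps are strictly increasing and cover every reference position", {
  set.seed(105)
  for (rep in 1:10) {
    x <- random_aa(sample(10:80, 1))
    y <- random_aa(sample(10:80, 1))
    a <- global_align(x, y)
    expect_length(a$column_map, nchar(y))
    mapped <- a$column_map[!is.na(a$column_map)]
    expect_true(all(diff(mapped) > 0))
    expect_true(all(mapped >= 1 & mapped <= nchar(x)))
  }
})

test_that("position projection maps anchors and rejects bad input", {
  a <- global_align("GKTDE", "GKTDE", unit_params())
  expect_equal(project_positions(a, c(1, 5)), c(1L, 5L))
  b <- global_align("GT", "GKT", unit_params())
  expect_equal(project_positions(b, 2), NA_integer_)
  expect_error(project_positions(b, 0), class = "kdparch_validation_error")
  expect_error(project_positions(b, 4), class = "kdparch_validation_error")
})
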