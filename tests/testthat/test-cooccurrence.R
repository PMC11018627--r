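sp_calls <- function(classes, phylum = "p", kdpe = TRUE, dac = FALSE,
                     ask = TRUE, hk = TRUE, tmgaf = TRUE) {
  n <- length(classes)
  data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    phylum = rep_len(phylum, n), has_kdpE = rep_len(kdpe, n),
    has_dac = rep_len(dac, n), n_chains = rep_len(1L, n), class = classes,
    ask_capable = rep_len(ask, n), hk_capable = rep_len(hk, n),
    has_tm_gaf = rep_len(tmgaf, n),
    stringsAsFactors = FALSE
  )
}

test_that("version distributions count and normalize correctly", {
  one <- version_distribution(sp_calls(rep("FULL_LENGTH", 10)))
  expect_equal(one$count, 10L)
  expect_equal(one$proportion, 1)
  expect_equal(one$n_group, 10L)

  mix <- version_distribution(
    sp_calls(c("FULL_LENGTH", "FULL_LENGTH", "SHORT_KDPD_USP")))
  expect_equal(mix$proportion[mix$class == "FULL_LENGTH"], 2 / 3)
  expect_equal(mix$proportion[mix$class == "SHORT_KDPD_USP"], 1 / 3)
  expect_equal(sum(mix$proportion), 1)

  expect_equal(nrow(version_distribution(sp_calls(character(0)))), 0L)
})

test_that("ABSENT species form their own category with re-based proportions", {
  tab <- version_distribution(
    sp_calls(c("FULL_LENGTH", "FULL_LENGTH", "ABSENT", "SHORT_KDPD_USP")))
  expect_equal(tab$proportion[tab$class == "ABSENT"], 1 / 4)
  expect_true(is.na(tab$proportion_excl_absent[tab$class == "ABSENT"]))
  expect_equal(tab$proportion_excl_absent[tab$class == "FULL_LENGTH"], 2 / 3)
  expect_equal(sum(tab$proportion), 1)
})

test_that("per-phylum grouping conserves species counts", {
  calls <- sp_calls(rep(c("FULL_LENGTH", "SHORT_KDPD_USP"), 5),
                    phylum = rep(c("Bacillota", "Archaea"), each = 5))
  tab <- version_distribution(calls, by = "phylum")
  expect_setequal(unique(tab$group), c("Bacillota", "Archaea"))
  expect_equal(sum(tab$count), 10L)
  for (g in unique(tab$group)) {
    expect_equal(sum(tab$proportion[tab$group == g]), 1)
  }
})

test_that("binary cross-tabulation reproduces hand counts", {
  d <- data.frame(
    hk_capable = c(TRUE, TRUE, FALSE, TRUE),
    has_kdpE = c(TRUE, TRUE, FALSE, FALSE)
  )
  ct <- crosstab_binary(d, "hk_capable", "has_kdpE")
  pos <- ct[ct$split_value == TRUE, ]
  neg <- ct[ct$split_value == FALSE, ]
  expect_equal(pos$n, 2L)
  expect_equal(pos$pct_true, 100)
  expect_equal(neg$pct_true, 50)
  expect_equal(pos$pct_true + pos$pct_false, 100)
  expect_equal(neg$pct_true + neg$pct_false, 100)
})

test_that("an empty split group reports n = 0 and NA percentages, not zeros", {
  d <- data.frame(out = c(TRUE, FALSE), grp = c(TRUE, TRUE))
  ct <- crosstab_binary(d, "out", "grp")
  empty <- ct[ct$split_value == FALSE, ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$pct_true))
  expect_true(is.na(empty$pct_false))
})

test_that("moving one species between groups shifts both group sizes by one", {
  set.seed(601)
  d <- data.frame(out = sample(c(TRUE, FALSE), 30, replace = TRUE),
                  grp = sample(c(TRUE, FALSE), 30, replace = TRUE))
  before <- crosstab_binary(d, "out", "grp")
  d$grp[1] <- !d$grp[1]
  after <- crosstab_binary(d, "out", "grp")
  expect_equal(abs(after$n - before$n), c(1L, 1L))
  expect_equal(sum(after$n), sum(before$n))
})

test_that("Wilson intervals match the score interval from prop.test", {
  ct <- crosstab_binary(
    data.frame(out = rep(c(TRUE, FALSE), c(8, 2)), grp = TRUE),
    "out", "grp", wilson = TRUE)
  ref_ci <- stats::prop.test(8, 10, correct = FALSE)$conf.int
  row <- ct[ct$split_value == TRUE, ]
  expect_equal(row$wilson_lo, 100 * ref_ci[1], tolerance = 1e-8)
  expect_equal(row$wilson_hi, 100 * ref_ci[2], tolerance = 1e-8)
})

test_that("estimated metadata conditionals converge to the generator's values", {
  # P(kdpE | hk) = 0.95 and P(kdpE | ~hk) = 0.05 planted; compare the
  # recovered conditional percentages with the Bayes-implied values under
  # the realized capability counts, at 3 binomial standard errors
  for (n in c(500, 2000)) {
    seed <- if (n == 500) 201L else 202L
    sim <- generate_dataset(generator_config(n_species = n, seed = seed))
    tr <- sim$truth
    p_hk <- mean(tr$true_hk)
    implied_pos <- 100 * 0.95 * p_hk / (0.95 * p_hk + 0.05 * (1 - p_hk))
    d <- data.frame(hk = tr$true_hk, kdpe = tr$has_kdpE)
    ct <- crosstab_binary(d, "hk", "kdpe")
    obs <- ct$pct_true[ct$split_value == TRUE]
    n_pos <- ct$n[ct$split_value == TRUE]
    se <- 100 * sqrt(implied_pos / 100 * (1 - implied_pos / 100) / n_pos)
    expect_lt(abs(obs - implied_pos), 3 * se + 1e-9)
  }
})
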