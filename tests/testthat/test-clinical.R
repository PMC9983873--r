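test_that("IHC binning reproduces the printed bin boundaries and partitions the grid", {
  expect_equal(as.character(bin_ihc(0)), "negative")
  expect_equal(as.character(bin_ihc(0.5)), "weak_positive")
  expect_equal(as.character(bin_ihc(2.5)), "weak_positive")
  expect_equal(as.character(bin_ihc(3)), "strong_positive")
  expect_equal(as.character(bin_ihc(4)), "strong_positive")
  grid <- seq(0, 4, by = 0.5)
  bins <- bin_ihc(grid)
  expect_false(any(is.na(bins)))          # every grid score maps to a bin
  expect_equal(as.vector(table(bins)), c(1, 5, 3))
  expect_error(bin_ihc(1.3), "grid")
  expect_error(bin_ihc(4.5), "grid")
})

test_that("exact Mann-Whitney matches full enumeration of labelings", {
  mw <- mann_whitney(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)
  orc <- oracle_mw_exact(c(1, 2), c(3, 4))
  expect_equal(orc$U, 0)
  expect_equal(orc$p, 1 / 3, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:20) {
    a <- sample(seq(1, 400), sample(3:6, 1))
    b <- sample(seq(401, 800), sample(3:6, 1)) / 100  # distinct -> no ties
    got <- mann_whitney(a, b, mode = "exact")
    want <- oracle_mw_exact(a, b)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney handles ties, identical groups and exact fallback", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_warning(mw <- mann_whitney(c(1, 1, 2), c(2, 3, 4), mode = "exact"), "ties")
  expect_equal(mw$method, "asymptotic")
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p is invariant under monotone transforms", {
  set.seed(5)
  a <- rnorm(5); b <- rnorm(6) + 0.5
  p0 <- mann_whitney(a, b, mode = "exact")$p_value
  expect_equal(mann_whitney(exp(a), exp(b), mode = "exact")$p_value, p0)
  expect_equal(mann_whitney(a^3, b^3, mode = "exact")$p_value, p0)
})

test_that("exact and asymptotic Mann-Whitney p agree at moderate n", {
  set.seed(12)
  diffs <- replicate(40, {
    a <- rnorm(6); b <- rnorm(6)
    abs(mann_whitney(a, b, mode = "exact")$p_value -
          mann_whitney(a, b, mode = "asymptotic")$p_value)
  })
  expect_lt(max(diffs), 0.06)
  expect_lt(mean(diffs), 0.03)
})

test_that("Kaplan-Meier reproduces the hand product-limit and its invariants", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = c(FALSE, TRUE, TRUE))
  km <- km_estimate(rec)
  # hand product-limit: censor at 1 (no drop); t=2 risk 2, event 1 -> 1/2;
  # t=3 risk 1, event 1 -> 0
  expect_equal(km_survival_at(km, c(1, 2, 3)), c(1, 0.5, 0))

  # record order is irrelevant
  km2 <- km_estimate(rec[c(3, 1, 2), ])
  expect_equal(km, km2)

  # survival is non-increasing and starts at 1
  expect_true(all(diff(km$survival) <= 0))
  expect_equal(km_survival_at(km, 0.5), 1)

  allc <- km_estimate(tibble::tibble(time = c(2, 4, 9), event = FALSE))
  expect_true(all(allc$survival == 1))

  one <- km_estimate(tibble::tibble(time = 7, event = TRUE))
  expect_equal(km_survival_at(one, c(6.9, 7)), c(1, 0))

  expect_error(km_estimate(tibble::tibble(time = -1, event = TRUE)), "non-negative")
})

test_that("log-rank matches a hand O/E/V table and its symmetries", {
  # 3 per arm, all events, alternating times 1..6:
  # O_A = 3, E_A = 1/2 + 2/5 + 1/2 + 1/3 + 1/2 = 2.2333,
  # V = 1/4 + 6/25 + 1/4 + 2/9 + 1/4 = 1.21222, chi2 = 0.7667^2 / 1.21222
  dat <- tibble::tibble(time = 1:6, event = TRUE,
                        group = rep(c("A", "B"), 3))
  lr <- logrank_test(dat)
  expect_equal(lr$statistic, (3 - 67 / 30)^2 / (109.1 / 90), tolerance = 1e-6)
  expect_equal(lr$df, 1)

  # swapping group labels leaves the statistic unchanged
  swapped <- dplyr::mutate(dat, group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank_test(swapped)$statistic, lr$statistic)

  # duplicated arms: no separation at all
  dup <- dplyr::bind_rows(
    tibble::tibble(time = c(2, 5, 8), event = c(TRUE, TRUE, FALSE), group = "A"),
    tibble::tibble(time = c(2, 5, 8), event = c(TRUE, TRUE, FALSE), group = "B")
  )
  lr0 <- logrank_test(dup)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank_test(tibble::tibble(time = 1:3, event = FALSE,
                                           group = c("A", "A", "B"))), "event")
  expect_error(logrank_test(tibble::tibble(time = 1:3, event = TRUE, group = "A")),
               "two groups")
})

test_that("lymph-node ratio stratification follows the 30% rule with low boundary", {
  df <- tibble::tibble(patient_id = 1:3,
                       positive_ln = c(5, 0, 3), examined_ln = c(12, 15, 10))
  out <- ln_ratio_group(df)
  expect_equal(as.character(out$ln_group), c("high_ratio", "no_ln_met", "low_ratio"))
  expect_equal(out$ln_ratio[1], 5 / 12)
  expect_error(ln_ratio_group(tibble::tibble(positive_ln = 1, examined_ln = 0)),
               "examined_ln")
  expect_error(ln_ratio_group(tibble::tibble(positive_ln = 9, examined_ln = 5)),
               "between")
})

test_that("marker correlations behave under identity, reflection and monotone maps", {
  x <- c(1.2, 3.4, 2.2, 5.5, 4.1, 0.3)
  expect_equal(marker_correlation(x, x, "pearson")$estimate, 1)
  expect_equal(marker_correlation(x, x, "spearman")$estimate, 1)
  expect_equal(marker_correlation(x, -x, "spearman")$estimate, -1)
  nl <- marker_correlation(x, x^3, "pearson")
  expect_lt(nl$estimate, 1)
  expect_equal(marker_correlation(x, x^3, "spearman")$estimate, 1)
  expect_error(marker_correlation(x, rep(2, 6)), "constant")
  expect_error(marker_correlation(x, x[-1]), "equal length")
})

test_that("median split labels strictly-above-median values as high", {
  g <- median_split(c(1, 2, 3, 4, 5))
  expect_equal(as.character(g), c("low", "low", "low", "high", "high"))
})
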