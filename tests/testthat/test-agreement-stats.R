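test_that("iss_group reproduces the six analysis bins and their boundaries", {
  expect_equal(iss_group(16), 3L)
  expect_equal(iss_group(c(0, 75)), c(1L, 6L))
  expect_equal(iss_group(c(8, 9, 15, 16, 24, 25, 40, 41, 49, 50)),
               c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L))
  expect_error(iss_group(-1))
  expect_error(iss_group(76))
})

test_that("the bins partition every integer score 0-75", {
  g <- iss_group(0:75)
  expect_true(all(g %in% 1:6))
  expect_equal(length(g), 76L)
  # each score falls in exactly one bin and bins are contiguous
  expect_true(all(diff(g) %in% c(0L, 1L)))
  expect_equal(as.vector(table(g)), c(9L, 7L, 9L, 16L, 9L, 26L))
})

test_that("crosstab conserves totals and recovers structure", {
  set.seed(5)
  pairs <- generate_paired_scores(generator_config(640, seed = 1))
  tab <- crosstab(pairs)
  expect_equal(sum(tab), 640L)

  same <- data.frame(manual_iss = c(3, 20, 50), auto_iss = c(3, 20, 50))
  expect_equal(sum(diag(crosstab(same))), 3L)
  expect_equal(sum(crosstab(same)) - sum(diag(crosstab(same))), 0L)
})

test_that("weighted kappa matches the published cross-tabulation value", {
  k <- weighted_kappa(reference_crosstab(), "linear")
  expect_equal(round(k$kappa, 2), 0.47)
  expect_equal(k$band, "moderate")
})

test_that("weighted kappa agrees with the double-sum oracle on random tables", {
  set.seed(31)
  for (i in 1:200) {
    tab <- random_count_table()
    if (sum(tab) == 0) next
    for (w in c("linear", "quadratic"))
      expect_equal(weighted_kappa(tab, w)$kappa, oracle_kappa(tab, w),
                   tolerance = 1e-9)
  }
})

test_that("kappa hits its analytic anchors and invariances", {
  diagonal <- diag(c(5, 10, 2, 8, 1, 4))
  expect_equal(weighted_kappa(diagonal)$kappa, 1)

  # independence: table equal to the outer product of its marginals
  r <- c(1, 2, 3, 1, 2, 1); s <- c(2, 1, 1, 3, 1, 2)
  expect_equal(weighted_kappa(outer(r, s))$kappa, 0, tolerance = 1e-9)

  tab <- random_count_table() + 1
  expect_equal(weighted_kappa(tab * 7L)$kappa, weighted_kappa(tab)$kappa,
               tolerance = 1e-9)

  degenerate <- matrix(0, 6, 6); degenerate[2, 2] <- 10
  expect_error(weighted_kappa(degenerate), "degenerate")
})

test_that("paired TOST computes one-sided t p-values and the 90% CI", {
  set.seed(8)
  d <- rnorm(40, 1, 2)
  res <- paired_tost(d, -3, 3, 0.05)
  # cross-check each one-sided p against stats::t.test
  expect_equal(res$p_lower,
               t.test(d, mu = -3, alternative = "greater")$p.value)
  expect_equal(res$p_upper,
               t.test(d, mu = 3, alternative = "less")$p.value)
  expect_equal(res$p_tost, max(res$p_lower, res$p_upper))
  expect_true(res$ci_low <= res$mean_diff && res$mean_diff <= res$ci_high)
  # 90% CI equals the (1 - 2 * alpha) t interval
  ci <- t.test(d, conf.level = 0.9)$conf.int
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(ci))
})

test_that("TOST boundary and degenerate behaviour", {
  # mean exactly at the upper bound: t statistic 0, one-sided p = 0.5
  d <- c(2, 4) + 0  # mean 3 = high
  expect_equal(paired_tost(d)$p_upper, 0.5)

  set.seed(12)
  big <- rnorm(1000)
  expect_lt(paired_tost(big)$p_tost, 1e-6)

  expect_error(paired_tost(5), "at least 2")

  z <- paired_tost(rep(1, 10))
  expect_true("zero_variance" %in% z$flags)
  expect_true(z$equivalent)  # mean 1 strictly inside (-3, 3)
  z2 <- paired_tost(rep(5, 10))
  expect_false(z2$equivalent)
})

test_that("Wilcoxon NHST uses the exact null for small n and conventions for zeros", {
  # tie-free positive sample: exact two-sided tail = 2 * 2^-n
  expect_equal(nhst_wilcoxon(1:10), 2 * 2^-10, tolerance = 1e-10)
  # all differences +1 are fully tied, forcing the corrected normal
  # approximation; the decision is unchanged
  expect_lt(nhst_wilcoxon(rep(1, 20)), 0.001)

  # perfectly symmetric differences sit at the null centre
  expect_gt(nhst_wilcoxon(c(1, -1, 2, -2, 3, -3, 4, -4)), 0.9)

  expect_warning(p <- nhst_wilcoxon(rep(0, 5)), "zero")
  expect_equal(p, 1)
  # zeros dropped before testing
  expect_equal(nhst_wilcoxon(c(0, 0, rep(1, 20))), nhst_wilcoxon(rep(1, 20)))
})

test_that("the dual-criterion verdict follows significant TOST + non-significant NHST", {
  expect_true(equivalence_verdict(0.001, 0.286, 0.05))
  expect_false(equivalence_verdict(0.015, 0.005, 0.05))  # both significant
  expect_false(equivalence_verdict(0.99, 0.001, 0.05))
  expect_false(equivalence_verdict(0.99, 0.50, 0.05))    # neither
  expect_error(equivalence_verdict(1.2, 0.5), "\\[0, 1\\]")
})

test_that("verdict is monotone in the equivalence bounds", {
  set.seed(3)
  for (i in 1:40) {
    d <- rnorm(30, runif(1, -2, 2), runif(1, 0.5, 6))
    narrow <- paired_tost(d, -3, 3)
    wide <- paired_tost(d, -6, 6)
    if (isTRUE(narrow$equivalent)) expect_true(wide$equivalent)
    # p_tost dominates each one-sided p
    expect_gte(narrow$p_tost, narrow$p_lower)
    expect_gte(narrow$p_tost, narrow$p_upper)
  }
})

test_that("group-wise absolute-difference summaries", {
  same <- data.frame(manual_iss = c(1, 10, 20), auto_iss = c(1, 10, 20))
  s <- group_abs_diff_summary(same)
  expect_equal(s$mean_abs_diff[s$group == "overall"], 0)

  two <- data.frame(manual_iss = c(2, 3), auto_iss = c(4, 7))  # |diff| 2 and 4
  s2 <- group_abs_diff_summary(two)
  g1 <- s2[s2$group == "1", ]
  expect_equal(g1$n, 2)
  expect_equal(g1$mean_abs_diff, 3)
  expect_equal(g1$sd_abs_diff, sqrt(2))
  expect_equal(s2$n[s2$group == "6"], 0)
})

test_that("TOST sample size brackets the Monte-Carlo power oracle", {
  n <- tost_sample_size(3, -3, 3, 0.05, 0.8)
  # brute-force oracle: smallest n whose MC rejection rate reaches 80%
  set.seed(17)
  n_mc <- 5L
  while (mc_tost_power(n_mc, 3, reps = 4000) < 0.8) n_mc <- n_mc + 1L
  expect_lte(abs(n - n_mc), 1L)

  # tiny sd: the minimum of 2 pairs suffices
  expect_equal(as.integer(tost_sample_size(1e-6)), 2L)

  # asymptotic n ~ sd^2: doubling sd about quadruples n
  n1 <- as.integer(tost_sample_size(6)); n2 <- as.integer(tost_sample_size(12))
  expect_lt(abs(n2 / n1 - 4), 0.4)

  expect_error(tost_sample_size(-1), "sd")
  expect_error(tost_sample_size(3, low = 1, high = 3), "bounds")
})

test_that("Bonferroni multiplies by the family size and clamps at 1", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
  expect_error(bonferroni(c(0.5, 1.3)), "\\[0, 1\\]")
})

test_that("compare_report assembles the full protocol", {
  pairs <- generate_paired_scores(generator_config(640, seed = 4))
  rep1 <- compare_report(pairs)
  expect_equal(nrow(rep1$equivalence), 7L)
  expect_equal(rep1$equivalence$group[7], "0-75")
  expect_equal(sum(rep1$crosstab), 640L)
  expect_null(rep1$regions)

  # Bonferroni columns clamp and scale by the 7-test family
  ok <- !is.na(rep1$equivalence$p_tost)
  expect_equal(rep1$equivalence$p_tost_bonf[ok],
               pmin(1, sum(ok) * rep1$equivalence$p_tost[ok]))

  # group-level reconstruction of the published table prints kappa 0.47
  rep3 <- compare_report(reference_crosstab_pairs())
  expect_equal(round(rep3$kappa$kappa, 2), 0.47)

  expect_error(compare_report(data.frame(patient_id = 1, manual_iss = 3)),
               "auto_iss")
})

test_that("compare_report analyses per-region AIS columns when present", {
  set.seed(9)
  n <- 120
  pairs <- data.frame(patient_id = seq_len(n),
                      manual_iss = sample(0:40, n, TRUE),
                      auto_iss = sample(0:40, n, TRUE))
  for (r in iss_regions()) {
    m <- sample(0:5, n, TRUE)
    pairs[[paste0("manual_ais_", r)]] <- m
    pairs[[paste0("auto_ais_", r)]] <- pmin(5, pmax(0, m + sample(-1:1, n, TRUE)))
  }
  rep2 <- compare_report(pairs)
  expect_equal(nrow(rep2$regions), 6L)
  expect_true(all(rep2$regions$kappa > 0.4))  # +-1 noise keeps agreement high
})
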