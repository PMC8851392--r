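test_that("frequency correlation handles ties like the average-rank formula", {
  set.seed(21)
  ab <- matrix(rbinom(6 * 10, 1, 0.5), nrow = 6)
  css <- matrix(rbinom(6 * 10, 1, 0.3), nrow = 6)
  m <- fake_matrix(ab, css)
  res <- spearman_frequency_correlation(m)
  freq <- region_frequencies(m)
  oracle <- spearman_oracle(freq$freq_css, freq$freq_ab)
  expect_equal(res$rs, oracle$rs, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)

  # identical frequency vectors with at least two distinct values
  m2 <- fake_matrix(css, css)
  expect_equal(spearman_frequency_correlation(m2)$rs, 1)

  # a constant vector leaves the correlation undefined
  m3 <- fake_matrix(matrix(1, 4, 8), css[1:4, 1:8])
  expect_true(spearman_frequency_correlation(m3)$undefined)
})

test_that("concordance table reports margins and independence expectation", {
  cc <- concordance_from_counts(94, 76, 239, 191)
  expect_equal(cc$N, 600)
  expect_equal(cc$expected_a, 94.35)  # printed as 94.4
  expect_equal(round(cc$pct_ab_pos, 1), 55.5)
  expect_equal(round(cc$pct_css_pos, 1), 28.3)
  expect_equal(round(cc$pct_concordant, 1), 15.7)

  all_pos <- concordance_from_counts(50, 0, 0, 0)
  expect_equal(all_pos$expected_a, all_pos$N)
  expect_equal(all_pos$pct_concordant, 100)

  g <- glance(cc)
  expect_equal(g$observed_a, 94)
  expect_equal(sum(tidy(cc)$n), 600)
})

test_that("observed concordance is centred on expectation under independence", {
  set.seed(13)
  n_sim <- 1000; N <- 600
  p_css <- 0.3; p_ab <- 0.55
  diffs <- replicate(n_sim, {
    cells <- rmultinom(1, N, c(p_css * p_ab, p_css * (1 - p_ab),
                               (1 - p_css) * p_ab, (1 - p_css) * (1 - p_ab)))
    cc <- concordance_from_counts(cells[1], cells[2], cells[3], cells[4])
    cc$a - cc$expected_a
  })
  se <- sd(diffs) / sqrt(n_sim)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("paired t matches the textbook formula and flags degeneracy", {
  set.seed(2)
  x <- rnorm(30); y <- rnorm(30)
  res <- paired_t(x, y)
  oracle <- paired_t_oracle(x, y)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)

  same <- paired_t(x, x)
  expect_true(same$degenerate)
  expect_equal(same$direction, 0)

  shifted <- paired_t(x + 0.5, x)
  expect_true(shifted$degenerate)
  expect_equal(shifted$direction, 1)
  expect_true(is.na(shifted$p))

  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("two-sample t defaults to the Welch form and reproduces cohort p-values", {
  pa <- c(74, 79, 79, 75, 70, 85, 71, 45, 80, 75)
  hc <- c(63, 60, 66, 58, 65, 65, 69, 70, 66, 66, 64, 72, 59, 80)
  res <- welch_t(pa, hc)
  oracle <- welch_oracle(pa, hc)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.073)
  # the pooled form would give a different (significant) answer
  expect_lt(welch_t(pa, hc, var_equal = TRUE)$p, 0.05)

  sub <- welch_t(c(74, 75, 75, 71, 45), c(85, 70, 79, 79, 80))
  expect_equal(round(sub$p, 3), 0.148)

  x <- rnorm(10)
  ident <- welch_t(x, x)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  flat <- welch_t(rep(1, 5), rep(1, 5))
  expect_true(flat$degenerate)
})

test_that("chi-square without continuity correction matches the O/E sum", {
  res <- chi_square_2x2(6, 4, 8, 6)
  expect_equal(round(res$chi2, 3), 0.020)
  expect_equal(round(res$p, 3), 0.889)

  # table proportional to its margins has zero statistic
  expect_equal(chi_square_2x2(10, 20, 5, 10)$chi2, 0)

  set.seed(9)
  for (i in 1:10) {
    cells <- rpois(4, 20) + 1
    res_i <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(res_i$chi2, chi2_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "margins")
})

test_that("hierarchical adjustment applies BH within the lobe then Bonferroni", {
  expect_equal(adjust_lobe_p(c(0.01, 0.02, 0.03, 0.04)),
               c(0.2, 0.2, 0.2, 0.2))
  # four equal raw values are a BH fixed point
  expect_equal(adjust_lobe_p(rep(0.07, 4)), rep(min(1, 5 * 0.07), 4))
  # values above 1 are capped
  expect_equal(adjust_lobe_p(c(0.5, 0.6, 0.7, 0.8)), rep(1, 4))

  set.seed(4)
  for (i in 1:20) {
    p <- runif(4)
    adj <- adjust_lobe_p(p)
    expect_equal(adj, pmin(1, 5 * bh_oracle(p)), tolerance = 1e-12)
    # invariant to input order, monotone in the sorted raw p's
    perm <- sample(4)
    expect_equal(adjust_lobe_p(p[perm]), adj[perm])
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})

test_that("lobe comparisons pool (patient, region) units and handle empty lobes", {
  set.seed(8)
  n <- 20
  suvr <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = n / 2),
    lobe = rep(c("frontal", "parietal"), n / 2),
    css_pos = TRUE,
    suvr_voi = rnorm(n, 1.5, 0.1)
  )
  suvr$suvr_css1 <- suvr$suvr_voi - 0.1 + rnorm(n, 0, 0.01)
  suvr$suvr_css0 <- suvr$suvr_voi + rnorm(n, 0, 0.01)
  suvr$suvr_control <- NA_real_
  out <- lobe_comparisons(suvr)
  comp <- out[out$lobe == "composite", ]
  expect_equal(unique(comp$n[comp$contrast != "css0_vs_control"]), n)
  # composite n equals the sum of the per-lobe n's
  per_lobe <- out[out$lobe %in% c("frontal", "temporal", "parietal", "PCG") &
                    out$contrast == "css_vs_css1", ]
  expect_equal(comp$n[comp$contrast == "css_vs_css1"], sum(per_lobe$n))
  # planted 0.1 deficit in the direct stratum is detected
  expect_lt(comp$p_adj[comp$contrast == "css_vs_css1"], 0.05)
  # no controls anywhere: contrast 4 is n.a.
  expect_true(all(is.na(out$p_raw[out$contrast == "css0_vs_control"])))
  expect_true(all(out$p_adj <= 1, na.rm = TRUE))
  # empty lobes (temporal, PCG here) report NA
  expect_true(all(is.na(out$mean_a[out$lobe == "PCG"])))
})

test_that("demographics analysis reproduces the cohort comparisons", {
  res <- demographics_analysis(study_subjects())
  tests <- res$tests
  getp <- function(cmp) tests$p[tests$comparison == cmp]
  expect_equal(round(getp("age_caa_vs_hc"), 3), 0.073)
  expect_equal(round(getp("sex_caa_vs_hc"), 3), 0.889)
  expect_equal(round(getp("dose_caa_vs_hc"), 3), 0.080)
  expect_equal(round(getp("age_subgroups"), 3), 0.148)
  expect_equal(round(getp("dose_subgroups"), 3), 0.775)
  expect_equal(round(getp("mmse_subgroups"), 3), 0.759)
  caa <- res$groups[res$groups$group == "CAA", ]
  expect_equal(round(caa$mean_age, 1), 73.3)
  expect_equal(round(caa$mean_dose, 1), 294.8)
  expect_equal(round(caa$mean_mmse, 1), 22.6)
  expect_equal(round(caa$mean_overlap_pct, 1), 57.1)
})
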