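combined <- combine_cohorts(nrxn3_counts())
rs1 <- combined[combined$snp_id == "rs11845632", c("group", "n_AA", "n_AG", "n_GG")]
rs2 <- combined[combined$snp_id == "rs2196447", c("group", "n_AA", "n_AG", "n_GG")]

test_that("hwe_test reproduces exact-HWE, hand-computed and published values", {
  exact <- hwe_test(25, 50, 25)
  expect_equal(exact$chi_square, 0)
  expect_equal(exact$p, 1)

  hand <- hwe_test(10, 10, 10) # expecteds 7.5 / 15 / 7.5
  expect_equal(hand$chi_square, 10 / 3, tolerance = 1e-12)
  expect_equal(hand$p, 0.0679, tolerance = 1e-3)

  # rs11845632, all 924 combined subjects
  pub <- hwe_test(140, 457, 327)
  expect_equal(round(pub$p, 3), 0.339)

  mono <- hwe_test(10, 0, 0)
  expect_true(mono$monomorphic)
  expect_equal(mono$p, 1)
  expect_error(hwe_test(0, 0, 0), "at least one")
})

test_that("hwe_test agrees with a goodness-of-fit oracle on random samples", {
  set.seed(19)
  for (i in 1:50) {
    tab <- random_count_table()
    counts <- tab$case + tab$control
    if (sum(counts) == 0 || (2 * counts[1] + counts[2]) %in% c(0, 2 * sum(counts))) next
    got <- hwe_test(counts[1], counts[2], counts[3])
    want <- oracle_hwe(counts[1], counts[2], counts[3])
    expect_equal(got$chi_square, want$chi_square, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("allele_test reproduces the published NRXN3 allele statistics", {
  g1 <- allele_test(rs1, allele = "G")
  expect_equal(round(100 * g1$freq_case, 1), 64.9)
  expect_equal(round(100 * g1$freq_control, 1), 56.3)
  expect_equal(round(g1$or, 2), 1.44)
  expect_equal(round(g1$ci_lower, 2), 1.19)
  expect_equal(round(g1$ci_upper, 2), 1.73)
  expect_equal(round(g1$p, 4), 2e-4)

  g2 <- allele_test(rs2, allele = "A")
  expect_equal(round(100 * g2$freq_case, 1), 43.3) # 43.2 in display rounding of 0.43276
  expect_equal(100 * g2$freq_case, 43.2, tolerance = 0.2)
  expect_equal(round(100 * g2$freq_control, 1), 34.9)
  expect_equal(round(g2$or, 2), 1.43)
  expect_equal(round(g2$ci_lower, 2), 1.18)
  expect_equal(round(g2$ci_upper, 2), 1.72)
  expect_equal(round(g2$p, 4), 2e-4)
})

test_that("allele_test basics: null identity, allele flip, zero cells", {
  same <- counts_df(c(10, 20, 30), c(10, 20, 30))
  res <- allele_test(same)
  expect_equal(res$or, 1)
  expect_equal(res$p, 1)

  tab <- counts_df(c(5, 10, 20), c(12, 9, 4))
  flip_g <- allele_test(tab, allele = "G")
  flip_a <- allele_test(tab, allele = "A")
  expect_equal(flip_g$or, 1 / flip_a$or, tolerance = 1e-12)
  expect_equal(flip_g$p, flip_a$p, tolerance = 1e-12)
  expect_equal(flip_g$freq_case, 1 - flip_a$freq_case)

  zero <- counts_df(c(0, 0, 10), c(5, 5, 5))
  res_zero <- allele_test(zero)
  expect_true(is.finite(res_zero$or)) # Haldane-Anscombe correction applied
  mono <- allele_test(counts_df(c(0, 0, 10), c(0, 0, 5)))
  expect_true(mono$monomorphic)
})

test_that("trend_test matches the textbook Cochran-Armitage statistic", {
  # proportional rows carry no trend
  none <- trend_test(counts_df(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(none$chi_square, 0, tolerance = 1e-12)

  t1 <- trend_test(rs1)
  o1 <- oracle_ca_trend(c(46, 195, 168), c(94, 262, 159))
  expect_equal(t1$chi_square, o1$chi_square, tolerance = 1e-10)
  expect_equal(t1$chi_square, 14.5, tolerance = 0.01)

  # affine score invariance and case/control swap invariance
  tab <- counts_df(c(5, 15, 30), c(20, 18, 7))
  expect_equal(
    trend_test(tab)$chi_square,
    trend_test(tab, scores = c(10, 20, 30))$chi_square,
    tolerance = 1e-12
  )
  swapped <- tab
  swapped$group <- rev(swapped$group)
  expect_equal(trend_test(tab)$chi_square, trend_test(swapped)$chi_square,
               tolerance = 1e-12)

  degen <- trend_test(counts_df(c(0, 10, 0), c(0, 8, 0)))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
  expect_error(trend_test(tab, scores = c(1, 1, 2)), "monotone")
})

test_that("trend_test equals the oracle on random tables", {
  set.seed(23)
  for (i in 1:200) {
    tab <- random_count_table()
    got <- trend_test(counts_df(tab$case, tab$control))
    if (got$degenerate) next
    keep <- tab$case + tab$control > 0
    want <- oracle_ca_trend(tab$case[keep], tab$control[keep],
                            scores = (0:2)[keep])
    expect_equal(got$chi_square, want$chi_square, tolerance = 1e-10)
  }
})

test_that("genotype_or reproduces the published GG-vs-AA odds ratios", {
  or1 <- genotype_or(rs1)
  gg1 <- or1[or1$genotype == "GG vs AA", ]
  expect_equal(round(gg1$or, 2), 2.16)
  expect_equal(round(gg1$ci_lower, 2), 1.43)
  expect_equal(round(gg1$ci_upper, 2), 3.27)

  or2 <- genotype_or(rs2)
  gg2 <- or2[or2$genotype == "GG vs AA", ]
  expect_equal(round(gg2$or, 2), 0.49)
  expect_equal(round(gg2$ci_lower, 2), 0.32)
  expect_equal(round(gg2$ci_upper, 2), 0.74)

  null_or <- genotype_or(counts_df(c(10, 20, 30), c(10, 20, 30)))
  expect_equal(null_or$or, c(1, 1))

  undef <- genotype_or(counts_df(c(0, 10, 5), c(0, 8, 9)))
  expect_true(all(undef$undefined))
})

test_that("genotype_test_2df is the Pearson test with df adjustment", {
  none <- genotype_test_2df(counts_df(c(10, 20, 30), c(10, 20, 30)))
  expect_equal(none$chi_square, 0, tolerance = 1e-12)
  expect_equal(none$p, 1)

  g1 <- genotype_test_2df(rs1)
  m <- matrix(c(46, 195, 168, 94, 262, 159), nrow = 2, byrow = TRUE)
  want <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(g1$chi_square, unname(want$statistic), tolerance = 1e-10)
  expect_equal(g1$p, want$p.value, tolerance = 1e-10)
  expect_equal(g1$df, 2L)
  expect_equal(g1$p, 7e-4, tolerance = 0.02)

  adj <- genotype_test_2df(counts_df(c(0, 10, 5), c(0, 8, 9)))
  expect_equal(adj$df, 1L)
  expect_true(adj$df_adjusted)
})

test_that("combine_cohorts sums counts and guards allele labels", {
  counts <- nrxn3_counts()
  comb <- combine_cohorts(counts)
  row <- comb[comb$snp_id == "rs11845632" & comb$group == "case", ]
  expect_equal(as.integer(row[c("n_AA", "n_AG", "n_GG")]), c(46L, 195L, 168L))
  expect_true(all(comb$cohort == "combined"))

  zero <- counts
  zero[zero$cohort == "replication", c("n_AA", "n_AG", "n_GG")] <- 0L
  comb_zero <- combine_cohorts(zero)
  test_rows <- counts[counts$cohort == "test",
                      c("snp_id", "group", "n_AA", "n_AG", "n_GG")]
  expect_equal(
    dplyr::arrange(comb_zero[names(test_rows)], .data$snp_id, .data$group),
    dplyr::arrange(test_rows, .data$snp_id, .data$group)
  )

  flipped <- counts
  flipped$allele_ref[flipped$cohort == "replication"] <- "G"
  flipped$allele_alt[flipped$cohort == "replication"] <- "A"
  expect_error(combine_cohorts(flipped), "allele labels differ")
})

test_that("power_chisq matches the non-central chi-square definition", {
  expect_equal(power_chisq(0.05, 1, 0), 0.05, tolerance = 1e-12)
  expect_equal(power_chisq(0.05, 1, 7.849), 0.80, tolerance = 1e-3)
  expect_gt(power_chisq(0.05, 1, 200), 0.999999)
  expect_error(power_chisq(1.2, 1, 1), "alpha")
  expect_error(power_chisq(0.05, 1, -2), "ncp")
})

test_that("snp_association fits both SNPs with tidy and glance methods", {
  fit <- snp_association(nrxn3_counts(),
                         allele = c(rs11845632 = "G", rs2196447 = "A"))
  g <- glance(fit)
  expect_equal(nrow(g), 2)
  expect_equal(g$n_case, c(409, 409))
  expect_equal(g$n_control, c(515, 515))
  td <- tidy(fit)
  expect_setequal(
    names(td),
    c("snp_id", "cohort", "term", "estimate", "conf.low", "conf.high", "p.value")
  )
  expect_equal(nrow(td), 6) # allele + 2 genotype terms per SNP
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_output(print(fit), "rs11845632")
  plt <- ggplot2::autoplot(fit)
  expect_s3_class(plt, "ggplot")
})
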