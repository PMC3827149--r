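test_that("ras computes A/(A+B) and rejects undefined records", {
  expect_equal(ras(50, 50), 0.5)
  expect_equal(ras(70, 0), 1)
  expect_equal(ras(60, 40), 0.6)
  expect_error(ras(0, 0), "undefined")
  expect_error(ras(-1, 2), "non-negative")
})

test_that("raf_corrected applies k and reduces to ras at k = 1", {
  expect_equal(raf_corrected(50, 50, 1), 0.5)
  expect_equal(raf_corrected(60, 40, 0.87), 60 / (60 + 34.8))
  expect_equal(raf_corrected(0, 40, 0.87), 0)
  expect_error(raf_corrected(60, 40, 0), "positive")
  expect_error(raf_corrected(60, 40, -1), "positive")
  set.seed(1)
  a <- runif(50, 1, 100)
  b <- runif(50, 1, 100)
  expect_equal(raf_corrected(a, b, 1), ras(a, b))
  # monotone: increasing in A, decreasing in k
  expect_true(all(diff(raf_corrected(1:10, 5, 0.9)) > 0))
  expect_true(all(diff(sapply(c(0.5, 1, 2), \(k) raf_corrected(6, 4, k))) < 0))
})

test_that("normalize_to_homozygotes rescales between anchors with clipping", {
  expect_equal(normalize_to_homozygotes(0.1, 0.9, 0.1), 0)
  expect_equal(normalize_to_homozygotes(0.6, 0.9, 0.1), 0.625)
  expect_equal(normalize_to_homozygotes(0.05, 0.9, 0.1), 0)
  expect_equal(normalize_to_homozygotes(0.95, 0.9, 0.1), 1)
  expect_warning(
    out <- normalize_to_homozygotes(0.5, 0.5, 0.5),
    "non-calibratable"
  )
  expect_true(is.na(out))
})

test_that("compute_k is the mean heterozygote dye ratio", {
  expect_equal(compute_k(c(10, 20, 30), c(10, 20, 30)), 1)
  expect_equal(compute_k(c(20, 40), c(10, 20)), 2)
  expect_error(compute_k(c(1, 2), c(0, 0)), "not estimable")
  expect_warning(k <- compute_k(c(1, 5), c(0, 10)), "dropped")
  expect_equal(k, 0.5)
})

test_that("estimated k matches the mean-of-ratios oracle under noise", {
  set.seed(7)
  n <- 1000
  cv <- 0.05
  sdlog <- sqrt(log1p(cv^2))
  noise <- function(n) rlnorm(n, -sdlog^2 / 2, sdlog)
  a <- 1000 * noise(n)
  b <- 1000 / 0.87 * noise(n)
  k_hat <- compute_k(a, b)
  expect_equal(k_hat, oracle_mean_ratio(a, b), tolerance = 1e-12)
  expect_lt(abs(k_hat - 0.87), 0.02)
})

test_that("summarize_replicates averages and applies the SD threshold", {
  d <- tibble::tibble(snp_id = "s", pool_id = "A", raf = c(0.5, 0.5, 0.5))
  out <- summarize_replicates(d, replicate_sd_max = 0.02)
  expect_equal(out$raf_mean, 0.5)
  expect_equal(out$replicate_sd, 0)
  expect_true(out$qc_pass)

  d2 <- tibble::tibble(snp_id = "s", pool_id = "A", raf = c(0.50, 0.50, 0.56))
  out2 <- summarize_replicates(d2, replicate_sd_max = 0.02)
  expect_equal(out2$replicate_sd, sd(c(0.50, 0.50, 0.56)))
  expect_equal(out2$replicate_sd, 0.0346410, tolerance = 1e-6)
  expect_false(out2$qc_pass)

  d3 <- tibble::tibble(snp_id = "s", pool_id = "A", raf = c(0.50, 0.52))
  out3 <- summarize_replicates(d3, replicate_sd_max = 0.02)
  expect_equal(out3$replicate_sd, 0.0141421, tolerance = 1e-5)
  expect_true(out3$qc_pass)

  expect_warning(
    out1 <- summarize_replicates(
      tibble::tibble(snp_id = "s", pool_id = "A", raf = 0.4)
    ),
    "single replicate"
  )
  expect_true(out1$qc_pass)
  expect_error(
    summarize_replicates(tibble::tibble(snp_id = character(),
                                        pool_id = character(),
                                        raf = numeric())),
    "no replicate data"
  )
})

test_that("QC is record-local: dropping one pool never changes another", {
  d <- tibble::tibble(
    snp_id = rep(c("s1", "s2"), each = 6),
    pool_id = rep(rep(c("A", "B"), each = 3), 2),
    raf = c(0.5, 0.5, 0.9, 0.4, 0.41, 0.42, 0.3, 0.3, 0.3, 0.6, 0.6, 0.61)
  )
  full <- summarize_replicates(d, replicate_sd_max = 0.02)
  partial <- summarize_replicates(
    d[!(d$snp_id == "s1" & d$pool_id == "A"), ], replicate_sd_max = 0.02
  )
  passing <- full[full$qc_pass, ]
  expect_equal(
    passing[c("snp_id", "pool_id", "raf_mean", "replicate_sd")],
    partial[partial$qc_pass, ][c("snp_id", "pool_id", "raf_mean", "replicate_sd")]
  )
})

test_that("estimates are invariant to rescaling both channels", {
  cfg <- sim_config(n_snps = 8, n_effect_snps = 0, seed = 17)
  st <- simulate_pool_study(cfg)
  ref <- calibration_reference(st$calibration)
  raf1 <- estimate_raf(st$pools, ref)
  scaled <- dplyr::mutate(
    st$pools,
    channel_A = .data$channel_A * 37.5, channel_B = .data$channel_B * 37.5
  )
  raf2 <- estimate_raf(scaled, ref)
  expect_equal(raf1$raf_mean, raf2$raf_mean, tolerance = 1e-12)
  expect_true(all(raf1$raf_mean >= 0 & raf1$raf_mean <= 1))
})

test_that("noise-free calibration recovers pool frequencies to machine precision", {
  cfg <- sim_config(
    n_cases_female = 30, n_cases_male = 25, n_controls_female = 40,
    n_controls_male = 35, n_snps = 25, n_effect_snps = 5,
    noise_cv = 0, k_sd = 0.2, seed = 29
  )
  st <- simulate_pool_study(cfg)
  ref <- calibration_reference(st$calibration)
  # per-SNP k is recovered exactly from noise-free heterozygotes
  expect_equal(ref$k, st$params$k, tolerance = 1e-12)
  raf <- estimate_raf(st$pools, ref)
  m <- dplyr::inner_join(raf, st$truth, by = c("snp_id", "pool_id"))
  expect_equal(m$raf_mean, m$true_raf, tolerance = 1e-12)
  expect_true(all(m$qc_pass))
})

test_that("calibration_reference flags SNPs without heterozygotes", {
  ints <- tibble::tibble(
    snp_id = c("s1", "s1", "s2", "s2"),
    genotype_class = c("AA", "BB", "AB", "AB"),
    channel_A = c(100, 0, 90, 85),
    channel_B = c(0, 100, 100, 100)
  )
  expect_warning(ref <- calibration_reference(ints), "fallback")
  expect_equal(ref$k[ref$snp_id == "s1"], 1)
  expect_true(ref$k_fallback[ref$snp_id == "s1"])
  expect_equal(ref$k[ref$snp_id == "s2"], mean(c(0.9, 0.85)))
})

test_that("estimate_raf rejects duplicate replicate indices", {
  pools <- tibble::tibble(
    snp_id = "s", pool_id = "A", replicate = c(1, 1),
    channel_A = c(10, 11), channel_B = c(10, 9)
  )
  ref <- tibble::tibble(snp_id = "s", k = 1, ras_hom_A = 1, ras_hom_B = 0)
  expect_error(estimate_raf(pools, ref), "unique")
})
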