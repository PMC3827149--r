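# Independent reference implementations used to cross-check the package.
# These deliberately take a different route than the package code
# (chisq.test / explicit loops / textbook formulas rather than the
# vectorised closed forms used internally).

oracle_pearson_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  out <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi_square = unname(out$statistic), p = out$p.value)
}

oracle_hwe <- function(n_aa, n_ag, n_gg) {
  n <- n_aa + n_ag + n_gg
  p <- (2 * n_aa + n_ag) / (2 * n)
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  out <- suppressWarnings(
    stats::chisq.test(c(n_aa, n_ag, n_gg), p = probs)
  )
  # chisq.test uses df = k - 1 = 2; HWE estimates one parameter, so df = 1
  chi <- unname(out$statistic)
  list(chi_square = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Textbook Cochran-Armitage trend statistic on a 3x2 table.
oracle_ca_trend <- function(case, control, scores = c(0, 1, 2)) {
  n <- case + control
  big_n <- sum(n)
  big_r <- sum(case)
  u <- sum(scores * case) - big_r / big_n * sum(scores * n)
  v <- (big_r / big_n) * (1 - big_r / big_n) *
    (sum(scores^2 * n) - sum(scores * n)^2 / big_n)
  chi <- u^2 / v
  list(chi_square = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up, written as the literal procedure.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  passed <- which(sorted <= seq_len(m) / m * q)
  flags <- rep(FALSE, m)
  if (length(passed) > 0) {
    flags[ord[seq_len(max(passed))]] <- TRUE
  }
  flags
}

oracle_mean_ratio <- function(a, b) {
  total <- 0
  n <- 0
  for (i in seq_along(a)) {
    if (b[i] > 0) {
      total <- total + a[i] / b[i]
      n <- n + 1
    }
  }
  total / n
}

# Brute-force combined ordering: explicit sort over the documented keys.
oracle_rank_order <- function(snp_id, p_f, p_m, d_f, d_m) {
  rf <- rank(p_f)
  rm_ <- rank(p_m)
  key <- data.frame(
    snp_id = snp_id, rs = rf + rm_,
    nd = -(abs(d_f) + abs(d_m)) / 2,
    stringsAsFactors = FALSE
  )
  key$snp_id[order(key$rs, key$nd, key$snp_id)]
}

# A random small 3x2 genotype count table guaranteed non-degenerate.
random_count_table <- function() {
  repeat {
    case <- stats::rpois(3, lambda = sample(3:30, 1)) + c(1L, 0L, 0L)
    control <- stats::rpois(3, lambda = sample(3:30, 1)) + c(0L, 0L, 1L)
    if (sum(case) > 0 && sum(control) > 0 && sum(case + control > 0) >= 2) {
      return(list(case = case, control = control))
    }
  }
}

counts_df <- function(case, control) {
  tibble::tibble(
    group = c("case", "control"),
    n_AA = c(case[1], control[1]),
    n_AG = c(case[2], control[2]),
    n_GG = c(case[3], control[3])
  )
}
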