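#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' 1-df Pearson chi-square of observed genotype counts against the HWE
#' expectations `p^2, 2pq, q^2` at the sample allele frequency, without
#' continuity correction. Vectorised over SNPs/samples.
#'
#' Which population to test (controls only, cases, or everyone) is the
#' caller's choice: pass the corresponding counts.
#'
#' @param n_aa,n_ag,n_gg Genotype counts (AA = two A alleles, etc.).
#' @return A tibble: `chi_square`, `p`, `monomorphic` (only one allele
#'   observed; `chi_square = 0`, `p = 1`).
#' @examples
#' hwe_test(140, 457, 327)
#' @export
hwe_test <- function(n_aa, n_ag, n_gg) {
  n <- max(length(n_aa), length(n_ag), length(n_gg))
  n_aa <- rep_len(n_aa, n); n_ag <- rep_len(n_ag, n); n_gg <- rep_len(n_gg, n)
  if (any(c(n_aa, n_ag, n_gg) < 0, na.rm = TRUE)) {
    abort("genotype counts must be non-negative")
  }
  total <- n_aa + n_ag + n_gg
  if (any(total < 1, na.rm = TRUE)) {
    abort("at least one genotyped individual is required")
  }
  p_a <- (2 * n_aa + n_ag) / (2 * total)
  monomorphic <- p_a == 0 | p_a == 1
  e_aa <- total * p_a^2
  e_ag <- total * 2 * p_a * (1 - p_a)
  e_gg <- total * (1 - p_a)^2
  chi <- (n_aa - e_aa)^2 / e_aa + (n_ag - e_ag)^2 / e_ag + (n_gg - e_gg)^2 / e_gg
  chi[monomorphic] <- 0
  tibble::tibble(
    chi_square = chi,
    p = pchisq(chi, df = 1, lower.tail = FALSE),
    monomorphic = monomorphic
  )
}

# Woolf (log) confidence interval for a 2x2 odds ratio; Haldane-Anscombe 0.5
# added to every cell of the table only when some cell is zero.
woolf_or <- function(a, b, c_, d, z = 1.96) {
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  tibble::tibble(
    or = or,
    ci_lower = exp(log(or) - z * se),
    ci_upper = exp(log(or) + z * se)
  )
}

# Pearson chi-square on a 2x2 of raw counts, no continuity correction.
pearson_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    return(list(chi_square = 0, p = 1, monomorphic = TRUE))
  }
  chi <- n * (a * d - b * c_)^2 / prod(margins)
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE), monomorphic = FALSE)
}

case_control_rows <- function(data) {
  check_columns(data, c("group", "n_AA", "n_AG", "n_GG"), "`data`")
  if (!setequal(unique(data$group), c("case", "control")) || nrow(data) != 2) {
    abort("`data` must contain exactly one 'case' and one 'control' row")
  }
  list(
    case = as.numeric(data[data$group == "case", c("n_AA", "n_AG", "n_GG")]),
    control = as.numeric(data[data$group == "control", c("n_AA", "n_AG", "n_GG")])
  )
}

# Run a per-SNP-table computation over an optionally grouped count table.
by_snp_table <- function(data, fn) {
  keys <- intersect(c("snp_id", "cohort"), names(data))
  if (length(keys) == 0) {
    return(fn(data))
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ fn(.x)) |>
    dplyr::ungroup()
}

#' Allele-based case-control association test
#'
#' Collapses genotype counts to a 2x2 allele table (allele count =
#' heterozygotes + 2 x homozygotes), applies the 1-df Pearson chi-square
#' without continuity correction, and reports the per-allele odds ratio with
#' a Woolf 95% confidence interval (log OR +/- 1.96 SE; 0.5 added to every
#' cell only when a cell is zero).
#'
#' @param data A data frame with one case and one control row per SNP
#'   (columns `group`, `n_AA`, `n_AG`, `n_GG`; optional `snp_id`/`cohort`
#'   grouping columns).
#' @param allele Which allele's odds ratio and frequencies to report:
#'   `"G"` (the allele counted by `n_GG`; default) or `"A"`. Switching
#'   allele inverts the OR and leaves the chi-square unchanged.
#' @return A tibble per SNP: `freq_case`, `freq_control` (frequency of the
#'   chosen allele), `chi_square`, `p`, `or`, `ci_lower`, `ci_upper`,
#'   `monomorphic`.
#' @examples
#' counts <- nrxn3_counts() |> combine_cohorts()
#' allele_test(counts[counts$snp_id == "rs11845632", ])
#' @export
allele_test <- function(data, allele = c("G", "A")) {
  allele <- match.arg(allele)
  by_snp_table(data, function(tab) {
    rows <- case_control_rows(tab)
    n_case_g <- rows$case[2] + 2 * rows$case[3]
    n_case_a <- rows$case[2] + 2 * rows$case[1]
    n_ctrl_g <- rows$control[2] + 2 * rows$control[3]
    n_ctrl_a <- rows$control[2] + 2 * rows$control[1]
    if (allele == "A") {
      tmp <- n_case_g; n_case_g <- n_case_a; n_case_a <- tmp
      tmp <- n_ctrl_g; n_ctrl_g <- n_ctrl_a; n_ctrl_a <- tmp
    }
    test <- pearson_2x2(n_case_g, n_case_a, n_ctrl_g, n_ctrl_a)
    ci <- if (test$monomorphic) {
      tibble::tibble(or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
    } else {
      woolf_or(n_case_g, n_case_a, n_ctrl_g, n_ctrl_a)
    }
    tibble::tibble(
      freq_case = n_case_g / (n_case_g + n_case_a),
      freq_control = n_ctrl_g / (n_ctrl_g + n_ctrl_a),
      chi_square = test$chi_square, p = test$p,
      or = ci$or, ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
      monomorphic = test$monomorphic
    )
  })
}

#' Cochran-Armitage trend test
#'
#' 1-df chi-square test for a monotone trend of the case proportion across
#' genotype classes, with dosage scores (default 0, 1, 2 for AA, AG, GG).
#' Invariant under affine transformation of the scores and under swapping
#' the case/control labels. Degenerate tables (a single non-empty genotype
#' class, or no variation in case status) return `p = 1` with a flag.
#'
#' @inheritParams allele_test
#' @param scores Strictly monotone numeric scores for AA, AG, GG.
#' @return A tibble per SNP: `chi_square`, `p`, `degenerate`.
#' @examples
#' counts <- nrxn3_counts() |> combine_cohorts()
#' trend_test(counts[counts$snp_id == "rs11845632", ])
#' @export
trend_test <- function(data, scores = c(0, 1, 2)) {
  if (length(scores) != 3 || !(all(diff(scores) > 0) || all(diff(scores) < 0))) {
    abort("`scores` must be three strictly monotone values")
  }
  by_snp_table(data, function(tab) {
    rows <- case_control_rows(tab)
    x <- rows$case
    n_tot <- rows$case + rows$control
    nonzero <- n_tot > 0
    degenerate <- sum(nonzero) < 2 || sum(x) == 0 || sum(rows$control) == 0
    if (degenerate) {
      return(tibble::tibble(chi_square = 0, p = 1, degenerate = TRUE))
    }
    pt <- suppressWarnings(
      prop.trend.test(x[nonzero], n_tot[nonzero], score = scores[nonzero])
    )
    tibble::tibble(
      chi_square = unname(pt$statistic), p = pt$p.value, degenerate = FALSE
    )
  })
}

#' Genotype odds ratios against a reference genotype
#'
#' Crude (cross-product) odds ratios of each non-reference genotype class
#' versus the reference, with Woolf 95% confidence intervals and the
#' Haldane-Anscombe 0.5 correction on zero-cell tables.
#'
#' @inheritParams allele_test
#' @param reference Reference genotype class, default `"AA"`.
#' @return A tibble per SNP with one row per non-reference genotype:
#'   `genotype`, `or`, `ci_lower`, `ci_upper`, `undefined` (reference class
#'   empty in both groups).
#' @examples
#' counts <- nrxn3_counts() |> combine_cohorts()
#' genotype_or(counts[counts$snp_id == "rs11845632", ])
#' @export
genotype_or <- function(data, reference = c("AA", "AG", "GG")) {
  reference <- match.arg(reference)
  classes <- c("AA", "AG", "GG")
  by_snp_table(data, function(tab) {
    rows <- case_control_rows(tab)
    ref_i <- match(reference, classes)
    ref_empty <- rows$case[ref_i] == 0 && rows$control[ref_i] == 0
    purrr::map_dfr(setdiff(classes, reference), function(cls) {
      i <- match(cls, classes)
      if (ref_empty) {
        return(tibble::tibble(
          genotype = paste0(cls, " vs ", reference),
          or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
          undefined = TRUE
        ))
      }
      ci <- woolf_or(rows$case[i], rows$case[ref_i],
                     rows$control[i], rows$control[ref_i])
      tibble::tibble(
        genotype = paste0(cls, " vs ", reference),
        or = ci$or, ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
        undefined = FALSE
      )
    })
  })
}

#' Overall genotype-distribution test (2 df)
#'
#' Pearson chi-square on the 3x2 genotype-by-status table. Genotype classes
#' empty in both groups are dropped with the degrees of freedom reduced
#' accordingly (and flagged).
#'
#' @inheritParams allele_test
#' @return A tibble per SNP: `chi_square`, `df`, `p`, `df_adjusted`.
#' @export
genotype_test_2df <- function(data) {
  by_snp_table(data, function(tab) {
    rows <- case_control_rows(tab)
    m <- rbind(rows$case, rows$control)
    keep <- colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    df <- ncol(m) - 1L
    if (df < 1 || any(rowSums(m) == 0)) {
      return(tibble::tibble(
        chi_square = 0, df = 0L, p = 1, df_adjusted = TRUE
      ))
    }
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    chi <- sum((m - e)^2 / e)
    tibble::tibble(
      chi_square = chi, df = df,
      p = pchisq(chi, df, lower.tail = FALSE),
      df_adjusted = df < 2L
    )
  })
}

#' Sum test and replication cohorts into a combined cohort
#'
#' Elementwise sum of the genotype counts of the `"test"` and
#' `"replication"` cohorts per SNP and group. If allele-label columns
#' (`allele_ref`, `allele_alt`) are present they must agree between the
#' cohorts being combined (no silent strand flipping).
#'
#' @param data A count table with columns `snp_id`, `cohort`, `group`,
#'   `n_AA`, `n_AG`, `n_GG`.
#' @param cohorts The cohort labels to sum (default `c("test",
#'   "replication")`).
#' @return A tibble of the same shape with `cohort = "combined"`.
#' @examples
#' combine_cohorts(nrxn3_counts())
#' @export
combine_cohorts <- function(data, cohorts = c("test", "replication")) {
  check_columns(data, c("snp_id", "cohort", "group", "n_AA", "n_AG", "n_GG"),
                "`data`")
  sub <- data[data$cohort %in% cohorts, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("no rows with cohort in {", paste(cohorts, collapse = ", "), "}"))
  }
  has_alleles <- all(c("allele_ref", "allele_alt") %in% names(data))
  if (has_alleles) {
    bad <- sub |>
      dplyr::distinct(.data$snp_id, .data$allele_ref, .data$allele_alt) |>
      dplyr::count(.data$snp_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(bad) > 0) {
      abort(paste0(
        "allele labels differ between cohorts for: ",
        paste(bad$snp_id, collapse = ", ")
      ))
    }
  }
  keys <- c("snp_id", "group", if (has_alleles) c("allele_ref", "allele_alt"))
  sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_AA = sum(.data$n_AA), n_AG = sum(.data$n_AG), n_GG = sum(.data$n_GG),
      .groups = "drop"
    ) |>
    dplyr::mutate(cohort = "combined") |>
    dplyr::select(
      "snp_id", "cohort", "group", "n_AA", "n_AG", "n_GG",
      dplyr::any_of(c("allele_ref", "allele_alt"))
    )
}

#' Power of a chi-square test
#'
#' `P(noncentral chi-square(df, ncp) > central critical value at alpha)` --
#' the power of a chi-square test with the given non-centrality parameter.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @param ncp Non-centrality parameter (>= 0).
#' @return Power in `[0, 1]`; equals `alpha` at `ncp = 0`.
#' @examples
#' power_chisq(0.05, 1, 7.849) # ~0.80
#' @export
power_chisq <- function(alpha, df = 1, ncp) {
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (any(df < 1) || any(df != round(df))) abort("`df` must be an integer >= 1")
  if (any(ncp < 0)) abort("`ncp` must be >= 0")
  crit <- qchisq(1 - alpha, df)
  pchisq(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Full association analysis of individually genotyped SNPs
#'
#' Runs the second-stage battery on a genotype count table: HWE (on cases
#' plus controls of the analysed cohort), allele test with per-allele OR and
#' Woolf CI, Cochran-Armitage trend test, 2-df genotype test, and crude
#' per-genotype ORs versus AA. Returns a `snp_assoc` object with
#' [tidy()]/[glance()] methods and an [autoplot()] forest plot.
#'
#' @param data A count table (`snp_id`, `cohort`, `group`, `n_AA`, `n_AG`,
#'   `n_GG`), e.g. [nrxn3_counts()].
#' @param cohort Which cohort to analyse; `"combined"` (default) is formed
#'   with [combine_cohorts()] if not already present.
#' @param allele Allele reported by the allele test, per SNP. A single value
#'   (`"G"` default or `"A"`) or a named character vector keyed by snp_id.
#' @return An object of class `snp_assoc`.
#' @examples
#' fit <- snp_association(nrxn3_counts())
#' glance(fit)
#' tidy(fit)
#' @export
snp_association <- function(data, cohort = "combined", allele = "G") {
  check_columns(data, c("snp_id", "cohort", "group", "n_AA", "n_AG", "n_GG"),
                "`data`")
  if (!cohort %in% data$cohort) {
    if (cohort == "combined") {
      data <- dplyr::bind_rows(data, combine_cohorts(data))
    } else {
      abort(paste0("cohort '", cohort, "' not present in `data`"))
    }
  }
  sub <- data[data$cohort == cohort, , drop = FALSE]
  snps <- unique(sub$snp_id)
  allele_by_snp <- if (is.null(names(allele))) {
    setNames(rep_len(allele, length(snps)), snps)
  } else {
    out <- setNames(rep("G", length(snps)), snps)
    out[names(allele)] <- allele
    out
  }
  per_snp <- purrr::map_dfr(snps, function(s) {
    tab <- sub[sub$snp_id == s, , drop = FALSE]
    totals <- colSums(tab[, c("n_AA", "n_AG", "n_GG")])
    hwe <- hwe_test(totals[[1]], totals[[2]], totals[[3]])
    al <- allele_test(tab[, c("group", "n_AA", "n_AG", "n_GG")],
                      allele = allele_by_snp[[s]])
    tr <- trend_test(tab[, c("group", "n_AA", "n_AG", "n_GG")])
    g2 <- genotype_test_2df(tab[, c("group", "n_AA", "n_AG", "n_GG")])
    tibble::tibble(
      snp_id = s, cohort = cohort, allele = allele_by_snp[[s]],
      n_case = sum(tab[tab$group == "case", c("n_AA", "n_AG", "n_GG")]),
      n_control = sum(tab[tab$group == "control", c("n_AA", "n_AG", "n_GG")]),
      freq_case = al$freq_case, freq_control = al$freq_control,
      hwe_chi2 = hwe$chi_square, hwe_p = hwe$p,
      allele_chi2 = al$chi_square, allele_p = al$p,
      allele_or = al$or, allele_ci_lower = al$ci_lower,
      allele_ci_upper = al$ci_upper,
      trend_chi2 = tr$chi_square, trend_p = tr$p,
      genotype_chi2 = g2$chi_square, genotype_df = g2$df, genotype_p = g2$p
    )
  })
  ors <- sub |>
    dplyr::select("snp_id", "group", "n_AA", "n_AG", "n_GG") |>
    genotype_or() |>
    dplyr::mutate(cohort = cohort)
  structure(
    list(results = per_snp, genotype_ors = ors, counts = sub),
    class = "snp_assoc"
  )
}

#' @export
print.snp_assoc <- function(x, ...) {
  cat("<snp_assoc> ", nrow(x$results), " SNP(s), cohort '",
      x$results$cohort[1], "'\n\n", sep = "")
  df <- x$results
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cat(sprintf(
      "%s: %s-allele freq case %.1f%% vs control %.1f%%, OR %.2f (%.2f-%.2f), allele p %.4f, trend p %.4g, HWE p %.3f\n",
      r$snp_id, r$allele, 100 * r$freq_case, 100 * r$freq_control,
      r$allele_or, r$allele_ci_lower, r$allele_ci_upper, r$allele_p,
      r$trend_p, r$hwe_p
    ))
  }
  invisible(x)
}
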