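#' Pooled case-control allele-frequency test
#'
#' Compares the corrected allele-frequency estimates of a case pool and a
#' control pool by reconstructing a 2x2 allele-count table and applying the
#' 1-df Pearson chi-square test without continuity correction. By default
#' each pooled individual contributes two chromosomes, so a pool of `n`
#' individuals with estimated frequency `f` is read back as `round(2 n f)`
#' A alleles and the complement B alleles.
#'
#' All arguments are vectorised over SNPs.
#'
#' @param raf_case,raf_control Estimated allele frequencies in `[0, 1]`.
#' @param n_case,n_control Individuals per pool (>= 1).
#' @param effective_n_mode `"chromosomes"` (default; `2 n` alleles per pool)
#'   or `"individuals"` (`n` alleles), controlling the effective sample size
#'   behind the reconstruction.
#' @return A tibble: `chi_square`, `p`, `or` (odds ratio for allele A;
#'   computed with a 0.5 continuity correction on all four cells when any
#'   interior cell is zero), `delta` (case - control frequency), and
#'   `monomorphic` (`TRUE` when a reconstructed margin is zero, in which
#'   case `chi_square = 0`, `p = 1`, `or = NA`).
#' @examples
#' pooled_chisq(0.649, 0.563, 409, 515)
#' @export
pooled_chisq <- function(raf_case, raf_control, n_case, n_control,
                         effective_n_mode = c("chromosomes", "individuals")) {
  effective_n_mode <- match.arg(effective_n_mode)
  if (any(raf_case < 0 | raf_case > 1 | raf_control < 0 | raf_control > 1,
          na.rm = TRUE)) {
    abort("RAF estimates must lie in [0, 1]")
  }
  if (any(n_case < 1 | n_control < 1)) {
    abort("pool sizes must be >= 1")
  }
  mult <- if (effective_n_mode == "chromosomes") 2 else 1
  n <- max(length(raf_case), length(raf_control), length(n_case), length(n_control))
  raf_case <- rep_len(raf_case, n); raf_control <- rep_len(raf_control, n)
  m1 <- rep_len(mult * n_case, n); m2 <- rep_len(mult * n_control, n)
  a <- round(m1 * raf_case); b <- m1 - a
  c_ <- round(m2 * raf_control); d <- m2 - c_
  total <- m1 + m2
  col_a <- a + c_; col_b <- b + d
  monomorphic <- col_a == 0 | col_b == 0 | is.na(raf_case) | is.na(raf_control)
  chi <- total * (a * d - b * c_)^2 / (m1 * m2 * col_a * col_b)
  chi[monomorphic] <- 0
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  # Haldane-Anscombe 0.5 on the affected table only, for the OR
  zero_cell <- !monomorphic & (a == 0 | b == 0 | c_ == 0 | d == 0)
  or <- (a * d) / (b * c_)
  or[zero_cell] <- ((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5)))[zero_cell]
  or[monomorphic] <- NA_real_
  tibble::tibble(
    chi_square = chi, p = p, or = or,
    delta = raf_case - raf_control, monomorphic = monomorphic
  )
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false discovery rate control at level `q`: flags every p-value at
#' or below the largest `p_(i)` with `p_(i) <= i q / m`.
#'
#' @param p P-values in `(0, 1]` (NA allowed; never flagged).
#' @param q FDR level, default 0.05.
#' @return Logical vector of the same length.
#' @examples
#' fdr_select(c(0.001, 0.008, 0.039, 0.041, 0.27))
#' @export
fdr_select <- function(p, q = 0.05) {
  check_number(q, "q", min = 0, max = 1, strict_min = TRUE)
  if (length(p) == 0) {
    return(logical(0))
  }
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1]")
  }
  out <- p.adjust(p, method = "BH") <= q
  out[is.na(out)] <- FALSE
  out
}

#' Combine per-gender rankings into one candidate ordering
#'
#' SNPs are ranked within each gender by ascending p-value (rank 1 is the
#' smallest p, i.e. the largest |log10 p|; exact ties share their average
#' rank), and the two ranks are summed. The final ordering is ascending in
#' the rank sum; equal sums are broken in favour of the larger
#' gender-averaged absolute case-control frequency difference, and any
#' remaining ties lexically by `snp_id` so the order is a deterministic
#' total order.
#'
#' @param data A data frame with columns `snp_id`, `p_female`, `p_male`,
#'   `delta_female`, `delta_male`. Rows with a missing p-value in either
#'   gender (e.g. QC failures) are excluded with a message.
#' @return The input rows that were rankable, with `rank_female`,
#'   `rank_male`, `rank_sum` and `combined_rank` added, sorted by
#'   `combined_rank`.
#' @export
rank_combine <- function(data) {
  check_columns(
    data, c("snp_id", "p_female", "p_male", "delta_female", "delta_male"),
    "`data`"
  )
  if (anyDuplicated(data$snp_id)) {
    abort("duplicated snp_id in `data`")
  }
  drop <- is.na(data$p_female) | is.na(data$p_male)
  if (any(drop)) {
    inform(paste0(
      sum(drop), " SNP(s) without a p-value in both genders excluded from ranking"
    ))
    data <- data[!drop, , drop = FALSE]
  }
  data |>
    dplyr::mutate(
      rank_female = rank(.data$p_female, ties.method = "average"),
      rank_male = rank(.data$p_male, ties.method = "average"),
      rank_sum = .data$rank_female + .data$rank_male,
      mean_abs_delta = (abs(.data$delta_female) + abs(.data$delta_male)) / 2
    ) |>
    dplyr::arrange(.data$rank_sum, dplyr::desc(.data$mean_abs_delta), .data$snp_id) |>
    dplyr::mutate(combined_rank = dplyr::row_number()) |>
    dplyr::select(-"mean_abs_delta")
}

#' Screen SNPs on effect size and nominal significance
#'
#' Retains records whose folded odds ratio `max(OR, 1/OR)` exceeds `or_min`
#' and whose p-value is below `p_max`; records with an undefined OR
#' (monomorphic) are dropped. The counts at each filter step are attached
#' as the `"funnel"` attribute.
#'
#' @param data A data frame with columns `p` and `or`.
#' @param or_min Folded odds-ratio threshold (default 1.4, exclusive).
#' @param p_max Nominal p-value threshold (default 0.05, exclusive).
#' @return The retained rows, with attribute `funnel` (named integer vector:
#'   `n_in`, `n_or_defined`, `n_or_pass`, `n_out`).
#' @examples
#' screen_candidates(tibble::tibble(
#'   snp_id = c("a", "b", "c"), p = c(0.01, 0.01, 0.001), or = c(1.5, 0.6, 1.2)
#' ))
#' @export
screen_candidates <- function(data, or_min = 1.4, p_max = 0.05) {
  check_columns(data, c("p", "or"), "`data`")
  defined <- !is.na(data$or) & !is.na(data$p)
  folded <- pmax(data$or, 1 / data$or)
  or_pass <- defined & folded > or_min
  keep <- or_pass & data$p < p_max
  out <- data[keep, , drop = FALSE]
  attr(out, "funnel") <- c(
    n_in = nrow(data), n_or_defined = sum(defined),
    n_or_pass = sum(or_pass), n_out = sum(keep)
  )
  out
}

#' Gender-stratified pooled association analysis
#'
#' The complete screening stage on QC-passed pool allele-frequency
#' estimates: within each gender, case and control pools are compared with
#' [pooled_chisq()]; Benjamini-Hochberg FDR is applied within gender and a
#' SNP is called FDR-significant when flagged in both genders; finally the
#' per-gender rankings are combined with [rank_combine()].
#'
#' Only SNPs whose estimates pass replicate QC in all four pools enter the
#' analysis; exclusions are counted in the `"funnel"` attribute.
#'
#' @param raf_estimates An [estimate_raf()] tibble covering the four pools.
#' @param design A pool design table (`pool_id`, `group`, `gender`,
#'   `n_individuals`), e.g. [pool_design()].
#' @param fdr_q FDR level per gender (default 0.05).
#' @param effective_n_mode Passed to [pooled_chisq()].
#' @return A tibble ordered by `combined_rank` with per-gender statistics
#'   (`chi2_*`, `p_*`, `or_*`, `delta_*`), `fdr_female`, `fdr_male`,
#'   `fdr_significant`, ranks and `rank_sum`. Attribute `funnel` counts
#'   SNPs in, QC-excluded, and tested.
#' @export
pooled_association <- function(raf_estimates, design, fdr_q = 0.05,
                               effective_n_mode = c("chromosomes", "individuals")) {
  effective_n_mode <- match.arg(effective_n_mode)
  check_columns(raf_estimates, c("snp_id", "pool_id", "raf_mean", "qc_pass"),
                "`raf_estimates`")
  check_columns(design, c("pool_id", "group", "gender", "n_individuals"),
                "`design`")
  strata <- dplyr::count(design, .data$group, .data$gender)
  if (nrow(strata) != 4 || any(strata$n != 1)) {
    abort("`design` must map each of the four group x gender strata to one pool")
  }
  n_snps_in <- dplyr::n_distinct(raf_estimates$snp_id)
  wide <- raf_estimates |>
    dplyr::filter(.data$qc_pass) |>
    dplyr::inner_join(design, by = "pool_id") |>
    dplyr::select("snp_id", "group", "gender", "raf_mean") |>
    tidyr::pivot_wider(
      names_from = c("group", "gender"), values_from = "raf_mean"
    )
  needed <- c("case_female", "case_male", "control_female", "control_male")
  wide <- wide[stats::complete.cases(wide[intersect(needed, names(wide))]), ]
  if (!all(needed %in% names(wide)) || nrow(wide) == 0) {
    abort("no SNP passed QC in all four pools")
  }
  n_qc <- nrow(wide)
  sizes <- setNames(design$n_individuals, paste(design$group, design$gender, sep = "_"))
  tf <- pooled_chisq(wide$case_female, wide$control_female,
                     sizes[["case_female"]], sizes[["control_female"]],
                     effective_n_mode)
  tm <- pooled_chisq(wide$case_male, wide$control_male,
                     sizes[["case_male"]], sizes[["control_male"]],
                     effective_n_mode)
  res <- tibble::tibble(
    snp_id = wide$snp_id,
    chi2_female = tf$chi_square, p_female = tf$p, or_female = tf$or,
    delta_female = tf$delta,
    chi2_male = tm$chi_square, p_male = tm$p, or_male = tm$or,
    delta_male = tm$delta,
    fdr_female = fdr_select(tf$p, fdr_q),
    fdr_male = fdr_select(tm$p, fdr_q)
  ) |>
    dplyr::mutate(fdr_significant = .data$fdr_female & .data$fdr_male) |>
    rank_combine()
  attr(res, "funnel") <- c(
    n_snps_in = n_snps_in, n_qc_excluded = n_snps_in - n_qc, n_tested = nrow(res)
  )
  res
}

#' Select the top-ranked screening candidates
#'
#' Applies the effect-size/significance screen ([screen_candidates()]) in
#' both genders and keeps the `top_n` surviving SNPs by combined rank --
#' the list that would be carried forward to individual genotyping.
#'
#' @param assoc A [pooled_association()] result.
#' @param or_min,p_max Screen thresholds, applied per gender.
#' @param top_n Number of candidates to retain (default 48).
#' @return The candidate rows of `assoc`, ordered by `combined_rank`, with
#'   a `funnel` attribute recording counts per filter.
#' @export
top_candidates <- function(assoc, or_min = 1.4, p_max = 0.05, top_n = 48) {
  check_columns(
    assoc, c("snp_id", "p_female", "p_male", "or_female", "or_male",
             "combined_rank"),
    "`assoc`"
  )
  check_count(top_n, "top_n")
  sf <- screen_candidates(
    dplyr::rename(assoc, p = "p_female", or = "or_female"), or_min, p_max
  )
  sm <- screen_candidates(
    dplyr::rename(assoc, p = "p_male", or = "or_male"), or_min, p_max
  )
  keep <- intersect(sf$snp_id, sm$snp_id)
  out <- assoc |>
    dplyr::filter(.data$snp_id %in% keep) |>
    dplyr::arrange(.data$combined_rank) |>
    utils::head(top_n)
  attr(out, "funnel") <- c(
    n_tested = nrow(assoc),
    n_screen_female = nrow(sf), n_screen_male = nrow(sm),
    n_screen_both = length(keep), n_candidates = nrow(out)
  )
  out
}
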