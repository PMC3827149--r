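#' Tidy an individual-association fit
#'
#' Broom-style view of a [snp_association()] result: one row per estimated
#' effect (the per-allele OR and each per-genotype OR), with point estimate
#' and 95% confidence bounds on the odds-ratio scale.
#'
#' @param x A `snp_assoc` object.
#' @param ... Unused.
#' @return A tibble: `snp_id`, `cohort`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `p.value` (allele-test p for the allele term, `NA` for
#'   crude genotype ORs).
#' @export
tidy.snp_assoc <- function(x, ...) {
  allele_rows <- x$results |>
    dplyr::transmute(
      .data$snp_id, .data$cohort,
      term = paste0("allele ", .data$allele),
      estimate = .data$allele_or,
      conf.low = .data$allele_ci_lower, conf.high = .data$allele_ci_upper,
      p.value = .data$allele_p
    )
  geno_rows <- x$genotype_ors |>
    dplyr::transmute(
      .data$snp_id, .data$cohort, term = .data$genotype,
      estimate = .data$or, conf.low = .data$ci_lower, conf.high = .data$ci_upper,
      p.value = NA_real_
    )
  dplyr::bind_rows(allele_rows, geno_rows) |>
    dplyr::arrange(.data$snp_id, .data$term)
}

#' Glance at an individual-association fit
#'
#' One row per SNP with the headline statistics: allele frequencies, the
#' test chi-squares and p-values (HWE, allele, trend, 2-df genotype) and
#' the per-allele OR with its interval.
#'
#' @inheritParams tidy.snp_assoc
#' @return The per-SNP results tibble of the fit.
#' @export
glance.snp_assoc <- function(x, ...) {
  x$results
}

#' Forest plot of an individual-association fit
#'
#' @param object A [snp_association()] result.
#' @param ... Unused.
#' @return A ggplot: odds ratios (log scale) with 95% CIs per SNP and term.
#' @method autoplot snp_assoc
#' @export
autoplot.snp_assoc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$estimate, y = .data$term,
                 xmin = .data$conf.low, xmax = .data$conf.high)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$snp_id), ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "odds ratio (95% CI)", y = NULL,
      title = paste0("Case-control odds ratios (", d$cohort[1], " cohort)")
    ) +
    ggplot2::theme_minimal()
}

#' Estimated versus true pool allele frequencies
#'
#' Concordance plot of the calibrated RAF estimates against the simulated
#' truth, one panel per pool; QC failures are highlighted.
#'
#' @param raf_estimates An [estimate_raf()] tibble.
#' @param truth A [pool_truth()] tibble.
#' @return A ggplot.
#' @export
plot_raf_concordance <- function(raf_estimates, truth) {
  d <- dplyr::inner_join(raf_estimates, truth, by = c("snp_id", "pool_id"))
  ggplot2::ggplot(d, ggplot2::aes(.data$true_raf, .data$raf_mean,
                                  colour = .data$qc_pass)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pool_id)) +
    ggplot2::labs(
      x = "true pool allele frequency", y = "estimated RAF",
      colour = "replicate QC"
    ) +
    ggplot2::theme_minimal()
}

#' Filtering funnel of a pipeline run
#'
#' Bar chart of record counts at each named filter step, mirroring the
#' screening funnel (SNPs in, QC-passed, tested, screened, candidates).
#'
#' @param pipeline A [run_pipeline()] result.
#' @return A ggplot.
#' @export
plot_funnel <- function(pipeline) {
  counts <- pipeline$manifest$funnel
  d <- tibble::tibble(
    step = factor(names(counts), levels = names(counts)),
    n = as.integer(counts)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$step, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "SNPs", title = "Screening funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
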