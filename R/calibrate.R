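#' Relative allele signal
#'
#' `RAS = A / (A + B)` for two-channel allele intensities. The uncorrected
#' frequency read-out of a pooled array.
#'
#' @param channel_a,channel_b Non-negative intensity vectors (recycled).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' ras(60, 40)
#' @export
ras <- function(channel_a, channel_b) {
  if (any(channel_a < 0, na.rm = TRUE) || any(channel_b < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  total <- channel_a + channel_b
  if (any(total == 0, na.rm = TRUE)) {
    abort("undefined record: channel_A + channel_B = 0")
  }
  channel_a / total
}

#' Dye-bias corrected allele frequency
#'
#' `RAFk = A / (A + k * B)`: the relative allele signal with the B channel
#' rescaled by the per-SNP correction factor `k`, so that a pool whose true
#' A-allele frequency is `f` reads out `f` instead of `f / (f + k (1 - f))`.
#' Reduces to [ras()] when `k = 1`.
#'
#' @inheritParams ras
#' @param k Per-SNP correction factor(s), strictly positive.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' raf_corrected(60, 40, 0.87)
#' @export
raf_corrected <- function(channel_a, channel_b, k) {
  if (any(!is.finite(k) | k <= 0)) {
    abort("`k` must be a positive correction factor")
  }
  if (any(channel_a < 0, na.rm = TRUE) || any(channel_b < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  denom <- channel_a + k * channel_b
  if (any(denom == 0, na.rm = TRUE)) {
    abort("undefined record: channel_A + k * channel_B = 0")
  }
  channel_a / denom
}

#' Per-SNP correction factor from known heterozygotes
#'
#' A heterozygous individual is equivalent to a pool with a 50% allele
#' frequency, so its dye ratio measures pure channel bias: `k` is the
#' arithmetic mean of the A:B intensity ratios across all known
#' heterozygotes for the SNP.
#'
#' @param channel_a,channel_b Intensities of heterozygote records for one
#'   SNP (equal length). Records with `channel_b = 0` are unusable and
#'   dropped with a warning.
#' @return A single positive `k`.
#' @examples
#' compute_k(c(87, 90), c(100, 100))
#' @export
compute_k <- function(channel_a, channel_b) {
  if (length(channel_a) != length(channel_b)) {
    abort("`channel_a` and `channel_b` must have equal length")
  }
  usable <- is.finite(channel_a) & is.finite(channel_b) & channel_b > 0
  if (!any(usable)) {
    abort("no heterozygote record with channel_B > 0: k is not estimable")
  }
  if (any(!usable)) {
    warn(paste0(sum(!usable), " heterozygote record(s) with channel_B = 0 dropped"))
  }
  mean(channel_a[usable] / channel_b[usable])
}

#' Rescale corrected frequencies to homozygote anchors
#'
#' Known homozygotes define where "all A" and "all B" land on the RAS scale;
#' the corrected frequency is mapped linearly so those anchors become 1 and
#' 0, then clipped to `[0, 1]`. The same affine map is applied to every
#' value (it is the identity for interior values when the anchors sit at
#' 0 and 1), which avoids a discontinuity between "extreme" and interior
#' read-outs.
#'
#' @param raf_raw Corrected frequencies ([raf_corrected()] output).
#' @param ras_hom_a Mean RAS of known A-homozygotes (upper anchor).
#' @param ras_hom_b Mean RAS of known B-homozygotes (lower anchor).
#' @return Numeric vector in `[0, 1]`; `NA` where the anchors coincide
#'   (non-calibratable SNP, flagged with a warning).
#' @examples
#' normalize_to_homozygotes(0.6, 0.9, 0.1)
#' @export
normalize_to_homozygotes <- function(raf_raw, ras_hom_a, ras_hom_b) {
  n <- max(length(raf_raw), length(ras_hom_a), length(ras_hom_b))
  raf_raw <- rep_len(raf_raw, n)
  ras_hom_a <- rep_len(ras_hom_a, n)
  ras_hom_b <- rep_len(ras_hom_b, n)
  bad <- !is.na(ras_hom_a) & !is.na(ras_hom_b) & ras_hom_a <= ras_hom_b
  if (any(bad)) {
    warn(paste0(
      sum(bad), " record(s) non-calibratable (ras_hom_A <= ras_hom_B); NA returned"
    ))
  }
  out <- (raf_raw - ras_hom_b) / (ras_hom_a - ras_hom_b)
  out[bad] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Build the per-SNP calibration reference
#'
#' Summarises individual-level intensities of subjects with known genotypes
#' into, per SNP: the dye-bias factor `k` (mean heterozygote A:B ratio) and
#' the homozygote RAS anchors used for normalization. SNPs without usable
#' heterozygotes fall back to `k = 1` and are flagged; missing homozygote
#' classes fall back to the ideal anchors 1 (AA) and 0 (BB) and are flagged.
#'
#' @param intensities A data frame with columns `snp_id`, `genotype_class`
#'   (`"AA"`, `"AB"`, `"BB"` by A-allele dosage 2/1/0), `channel_A`,
#'   `channel_B` -- e.g. [simulate_individual_intensities()] output.
#' @return A tibble with one row per SNP: `snp_id`, `k`, `ras_hom_A`,
#'   `ras_hom_B`, `n_het`, `n_hom_A`, `n_hom_B`, `k_fallback`,
#'   `anchor_fallback`.
#' @export
calibration_reference <- function(intensities) {
  check_columns(
    intensities, c("snp_id", "genotype_class", "channel_A", "channel_B"),
    "`intensities`"
  )
  bad_class <- setdiff(unique(intensities$genotype_class), c("AA", "AB", "BB"))
  if (length(bad_class) > 0) {
    abort(paste0(
      "unknown genotype_class value(s): ", paste(bad_class, collapse = ", ")
    ))
  }
  ref <- intensities |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      n_het = sum(.data$genotype_class == "AB" & .data$channel_B > 0),
      n_hom_A = sum(.data$genotype_class == "AA"),
      n_hom_B = sum(.data$genotype_class == "BB"),
      k = ifelse(
        .data$n_het > 0,
        mean((.data$channel_A / .data$channel_B)[.data$genotype_class == "AB" &
                                                   .data$channel_B > 0]),
        1
      ),
      ras_hom_A = ifelse(
        .data$n_hom_A > 0,
        mean(ras(.data$channel_A, .data$channel_B)[.data$genotype_class == "AA"]),
        1
      ),
      ras_hom_B = ifelse(
        .data$n_hom_B > 0,
        mean(ras(.data$channel_A, .data$channel_B)[.data$genotype_class == "BB"]),
        0
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      k_fallback = .data$n_het == 0,
      anchor_fallback = .data$n_hom_A == 0 | .data$n_hom_B == 0
    ) |>
    dplyr::select(
      "snp_id", "k", "ras_hom_A", "ras_hom_B",
      "n_het", "n_hom_A", "n_hom_B", "k_fallback", "anchor_fallback"
    )
  n_fb <- sum(ref$k_fallback)
  if (n_fb > 0) {
    warn(paste0(n_fb, " SNP(s) had no usable heterozygote; k = 1 fallback used"))
  }
  ref
}

#' Average replicate allele-frequency estimates with variance QC
#'
#' Replicate chips of the same pool should agree; a large spread indicates a
#' failed measurement. The per-replicate corrected frequencies are averaged
#' and the sample standard deviation (in allele-frequency units) is compared
#' against `replicate_sd_max`: combinations exceeding it fail QC.
#'
#' @param data A data frame with columns `snp_id`, `pool_id`, `raf` (one row
#'   per replicate). `NA` replicates are dropped with a count message.
#' @param replicate_sd_max QC threshold on the replicate standard deviation,
#'   in frequency units. Default 0.05; 0.02 is the stricter option when
#'   replicate agreement is known to be tighter than the array noise here.
#' @return A tibble per (snp, pool): `raf_mean`, `replicate_sd`,
#'   `n_replicates`, `qc_pass`, and the per-replicate values in the
#'   list-column `raf_replicates`. Single-replicate records pass QC by
#'   construction and trigger a warning.
#' @examples
#' d <- tibble::tibble(
#'   snp_id = "rs1", pool_id = "A", raf = c(0.50, 0.50, 0.56)
#' )
#' summarize_replicates(d, replicate_sd_max = 0.05)
#' @export
summarize_replicates <- function(data, replicate_sd_max = 0.05) {
  check_columns(data, c("snp_id", "pool_id", "raf"), "`data`")
  check_number(replicate_sd_max, "replicate_sd_max", min = 0)
  if (nrow(data) == 0) {
    abort("no replicate data supplied")
  }
  n_na <- sum(is.na(data$raf))
  if (n_na > 0) {
    inform(paste0(n_na, " replicate record(s) with missing RAF dropped"))
    data <- data[!is.na(data$raf), , drop = FALSE]
    if (nrow(data) == 0) abort("all replicate RAFs are missing")
  }
  out <- data |>
    dplyr::group_by(.data$snp_id, .data$pool_id) |>
    dplyr::summarise(
      raf_mean = mean(.data$raf),
      replicate_sd = stats::sd(.data$raf),
      n_replicates = dplyr::n(),
      raf_replicates = list(.data$raf),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      qc_pass = is.na(.data$replicate_sd) | .data$replicate_sd <= replicate_sd_max
    ) |>
    dplyr::select(
      "snp_id", "pool_id", "raf_mean", "replicate_sd", "n_replicates",
      "qc_pass", "raf_replicates"
    )
  n_single <- sum(out$n_replicates == 1L)
  if (n_single > 0) {
    warn(paste0(
      n_single, " (snp, pool) combination(s) have a single replicate; ",
      "QC forced to pass"
    ))
  }
  out
}

#' Estimate pool allele frequencies from raw intensities
#'
#' The full calibration chain for pooled arrays: per replicate,
#' `RAFk = A / (A + k B)` with the SNP's reference `k`, rescaled to the
#' homozygote RAS anchors; then replicates are averaged with variance QC
#' ([summarize_replicates()]).
#'
#' @param pools A data frame of pooled intensities: `snp_id`, `pool_id`,
#'   `replicate`, `channel_A`, `channel_B` (e.g. [construct_pools()]).
#' @param reference A [calibration_reference()] tibble.
#' @param replicate_sd_max QC threshold passed to [summarize_replicates()].
#' @return The [summarize_replicates()] tibble.
#' @export
estimate_raf <- function(pools, reference, replicate_sd_max = 0.05) {
  check_columns(
    pools, c("snp_id", "pool_id", "replicate", "channel_A", "channel_B"),
    "`pools`"
  )
  check_columns(reference, c("snp_id", "k", "ras_hom_A", "ras_hom_B"), "`reference`")
  if (anyDuplicated(reference$snp_id)) {
    abort("`reference` must have one row per snp_id")
  }
  dup <- pools |>
    dplyr::count(.data$snp_id, .data$pool_id, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("replicate indices must be unique within (snp_id, pool_id)")
  }
  joined <- dplyr::inner_join(pools, reference, by = "snp_id")
  n_drop <- nrow(pools) - nrow(joined)
  if (n_drop > 0) {
    inform(paste0(n_drop, " pool record(s) without calibration reference dropped"))
  }
  joined |>
    dplyr::mutate(
      raf = normalize_to_homozygotes(
        raf_corrected(.data$channel_A, .data$channel_B, .data$k),
        .data$ras_hom_A, .data$ras_hom_B
      )
    ) |>
    summarize_replicates(replicate_sd_max = replicate_sd_max)
}
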