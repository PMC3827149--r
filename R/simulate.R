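#' Configuration for the synthetic pooling study
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline is meant to analyse: four gender-stratified
#' case/control pools (91 female and 84 male cases, 140 female and 104 male
#' controls), each pool hybridised in triplicate, a per-SNP dye-bias factor
#' `k` centred on 0.87, multiplicative intensity noise with a 5% coefficient
#' of variation, and effect SNPs that shift the case allele frequency from
#' 0.563 to 0.649.
#'
#' @param n_cases_female,n_cases_male,n_controls_female,n_controls_male
#'   Individuals per stratum (each stratum becomes one DNA pool).
#' @param n_snps Number of SNPs to simulate.
#' @param n_effect_snps Number of SNPs carrying a true case/control
#'   allele-frequency difference; the rest are null.
#' @param maf_control Control-group frequency of allele A. A single value
#'   (recycled to all SNPs) or a vector of length `n_snps`.
#' @param effect_delta Additive shift of the case-group A-allele frequency at
#'   effect SNPs, in frequency units.
#' @param k_mean Median of the per-SNP lognormal dye-bias factor `k`
#'   (expected heterozygote A:B intensity ratio).
#' @param k_sd Spread of `k` on the log scale (`sdlog`); `0` makes every SNP
#'   share `k = k_mean`. Draws are clipped to `[0.2, 5]` to avoid degenerate
#'   channels.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied independently to each channel measurement.
#' @param n_replicates Technical replicates (chips) per pool.
#' @param weight_jitter_cv Coefficient of variation of per-individual DNA
#'   contribution weights when pools are formed (pipetting inequality).
#'   `0` (the default) gives exactly equimolar pooling.
#' @param seed Root RNG seed; every stage draws from its own substream so
#'   stages are individually reproducible.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_snps = 50, n_effect_snps = 5, seed = 7)
#' cfg$k_mean
#' @export
sim_config <- function(n_cases_female = 91,
                       n_cases_male = 84,
                       n_controls_female = 140,
                       n_controls_male = 104,
                       n_snps = 1000,
                       n_effect_snps = 50,
                       maf_control = 0.563,
                       effect_delta = 0.086,
                       k_mean = 0.87,
                       k_sd = 0.15,
                       noise_cv = 0.05,
                       n_replicates = 3,
                       weight_jitter_cv = 0,
                       seed = 1) {
  cfg <- list(
    n_cases_female = check_count(n_cases_female, "n_cases_female"),
    n_cases_male = check_count(n_cases_male, "n_cases_male"),
    n_controls_female = check_count(n_controls_female, "n_controls_female"),
    n_controls_male = check_count(n_controls_male, "n_controls_male"),
    n_snps = check_count(n_snps, "n_snps"),
    n_effect_snps = check_count(n_effect_snps, "n_effect_snps", min = 0L),
    effect_delta = check_number(effect_delta, "effect_delta", min = -1, max = 1),
    k_mean = check_number(k_mean, "k_mean", min = 0, strict_min = TRUE),
    k_sd = check_number(k_sd, "k_sd", min = 0),
    noise_cv = check_number(noise_cv, "noise_cv", min = 0),
    n_replicates = check_count(n_replicates, "n_replicates"),
    weight_jitter_cv = check_number(weight_jitter_cv, "weight_jitter_cv", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_effect_snps > cfg$n_snps) {
    abort("`n_effect_snps` cannot exceed `n_snps`")
  }
  if (!is.numeric(maf_control) || anyNA(maf_control) ||
      !(length(maf_control) %in% c(1L, cfg$n_snps))) {
    abort("`maf_control` must be numeric, length 1 or `n_snps`, with no NA")
  }
  if (any(maf_control < 0 | maf_control > 1)) {
    abort("`maf_control` frequencies must lie in [0, 1]")
  }
  cfg$maf_control <- rep_len(as.numeric(maf_control), cfg$n_snps)
  cfg <- structure(cfg, class = "sim_config")
  # Effect SNPs must keep the case frequency inside [0, 1].
  p <- snp_params(cfg)
  bad <- p$true_f_case < 0 | p$true_f_case > 1
  if (any(bad)) {
    abort(paste0(
      "case allele frequency out of [0, 1] after applying `effect_delta` for ",
      sum(bad), " SNP(s), e.g. ", p$snp_id[which(bad)[1]]
    ))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  n_ind <- x$n_cases_female + x$n_cases_male + x$n_controls_female + x$n_controls_male
  cat(
    "<sim_config>\n",
    " individuals: ", n_ind, " (cases ", x$n_cases_female, "F/", x$n_cases_male,
    "M, controls ", x$n_controls_female, "F/", x$n_controls_male, "M)\n",
    " SNPs: ", x$n_snps, " (", x$n_effect_snps, " effect, delta ",
    x$effect_delta, ")\n",
    " k ~ lognormal(median ", x$k_mean, ", sdlog ", x$k_sd, "), noise CV ",
    x$noise_cv, ", ", x$n_replicates, " replicates, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-SNP simulation truth (frequencies, effect status, dye bias)
#'
#' Deterministic given `config$seed`: both the individual-level and the
#' pooled intensity simulators call this, so they share one per-SNP `k`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per SNP: `snp_id`, `true_f_control`,
#'   `true_f_case`, `is_effect`, `k`.
#' @export
snp_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "params", {
    n <- config$n_snps
    snp_id <- sprintf("snp%05d", seq_len(n))
    is_effect <- rep(FALSE, n)
    if (config$n_effect_snps > 0) {
      is_effect[sample.int(n, config$n_effect_snps)] <- TRUE
    }
    k <- if (config$k_sd == 0) {
      rep(config$k_mean, n)
    } else {
      pmin(pmax(rlnorm(n, log(config$k_mean), config$k_sd), 0.2), 5)
    }
    tibble::tibble(
      snp_id = snp_id,
      true_f_control = config$maf_control,
      true_f_case = config$maf_control + ifelse(is_effect, config$effect_delta, 0),
      is_effect = is_effect,
      k = k
    )
  })
}

pool_strata <- function() {
  # Pool letters follow the four-pool design: A/B cases, C/D controls.
  tibble::tibble(
    pool_id = c("A", "B", "C", "D"),
    group = c("case", "case", "control", "control"),
    gender = c("female", "male", "female", "male")
  )
}

#' Simulate individual genotypes under Hardy-Weinberg equilibrium
#'
#' Draws allele-A dosages for every individual in the four group-by-gender
#' strata. Each SNP is independent; within a group, genotype counts follow
#' HWE at that group's allele frequency (effect SNPs use the shifted case
#' frequency in both case strata).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `subject_id`, `group`, `gender`, `snp_id`,
#'   `dosage` (copies of allele A, in 0:2).
#' @examples
#' g <- simulate_genotypes(sim_config(n_snps = 10, n_effect_snps = 0, seed = 1))
#' dplyr::count(g, group, gender)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  params <- snp_params(config)
  strata <- pool_strata()
  sizes <- c(
    config$n_cases_female, config$n_cases_male,
    config$n_controls_female, config$n_controls_male
  )
  with_stage_seed(config$seed, "genotypes", {
    out <- purrr::pmap(
      list(strata$pool_id, strata$group, strata$gender, sizes),
      function(pool_id, group, gender, n_ind) {
        f <- if (group == "case") params$true_f_case else params$true_f_control
        # n_ind x n_snps dosage draws, SNP-major so each SNP uses its own f
        dosage <- rbinom(n_ind * config$n_snps, 2L,
                         rep(f, each = n_ind))
        tibble::tibble(
          subject_id = rep(
            sprintf("%s_%s_%04d", group, substr(gender, 1, 1), seq_len(n_ind)),
            times = config$n_snps
          ),
          group = group,
          gender = gender,
          snp_id = rep(params$snp_id, each = n_ind),
          dosage = as.integer(dosage)
        )
      }
    )
    dplyr::bind_rows(out)
  })
}

#' Simulate individual-level calibration intensities
#'
#' Generates the two-channel array intensities of individually assayed
#' subjects with known genotypes, from which per-SNP dye-bias correction
#' factors are later estimated. Channel A is proportional to the A-allele
#' dosage and channel B to `2 - dosage`; the B channel is inflated by `1/k`
#' so that a heterozygote's expected A:B ratio equals `k`. Both channels
#' carry independent multiplicative lognormal noise with CV `noise_cv`.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return A tibble: `snp_id`, `subject_id`, `genotype_class` (`"AA"`,
#'   `"AB"`, `"BB"` by A dosage 2/1/0), `channel_A`, `channel_B`.
#' @export
simulate_individual_intensities <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(genotypes, c("subject_id", "snp_id", "dosage"), "`genotypes`")
  k <- snp_params(config)$k
  names(k) <- snp_params(config)$snp_id
  base <- 1000 # arbitrary intensity units; downstream is scale-invariant
  with_stage_seed(config$seed, "individual_intensities", {
    n <- nrow(genotypes)
    kk <- unname(k[genotypes$snp_id])
    tibble::tibble(
      snp_id = genotypes$snp_id,
      subject_id = genotypes$subject_id,
      genotype_class = c("BB", "AB", "AA")[genotypes$dosage + 1L],
      channel_A = base * genotypes$dosage * rnoise(n, config$noise_cv),
      channel_B = base * (2L - genotypes$dosage) / kk * rnoise(n, config$noise_cv)
    )
  })
}

#' Pool design table implied by the simulated genotypes
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @return A tibble: `pool_id`, `group`, `gender`, `n_individuals`.
#' @export
pool_design <- function(genotypes) {
  check_columns(genotypes, c("subject_id", "group", "gender"), "`genotypes`")
  genotypes |>
    dplyr::distinct(.data$subject_id, .data$group, .data$gender) |>
    dplyr::count(.data$group, .data$gender, name = "n_individuals") |>
    dplyr::inner_join(pool_strata(), by = c("group", "gender")) |>
    dplyr::select("pool_id", "group", "gender", "n_individuals") |>
    dplyr::arrange(.data$pool_id)
}

#' Construct pooled-array intensities from individual genotypes
#'
#' Forms one DNA pool per group-by-gender stratum by combining (by default)
#' equimolar contributions from every member, and simulates `n_replicates`
#' chip measurements per pool. The pool's channel A signal is proportional
#' to the summed A-allele dosage of its members and channel B to the summed
#' B dosage inflated by the same per-SNP `1/k` bias as individual arrays;
#' each replicate measurement receives independent multiplicative noise.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return A tibble: `snp_id`, `pool_id`, `replicate`, `channel_A`,
#'   `channel_B`.
#' @export
construct_pools <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(
    genotypes, c("subject_id", "group", "gender", "snp_id", "dosage"),
    "`genotypes`"
  )
  params <- snp_params(config)
  strata <- pool_strata()
  present <- dplyr::distinct(genotypes, .data$group, .data$gender)
  missing <- dplyr::anti_join(strata, present, by = c("group", "gender"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "empty pool stratum: ",
      paste(missing$group, missing$gender, sep = "/", collapse = ", ")
    ))
  }
  with_stage_seed(config$seed, "pools", {
    g <- dplyr::inner_join(genotypes, strata, by = c("group", "gender"))
    if (config$weight_jitter_cv > 0) {
      subjects <- unique(g$subject_id)
      w <- setNames(rnoise(length(subjects), config$weight_jitter_cv), subjects)
      g$w <- w[g$subject_id]
    } else {
      g$w <- 1
    }
    sums <- g |>
      dplyr::group_by(.data$snp_id, .data$pool_id) |>
      dplyr::summarise(
        sum_a = sum(.data$w * .data$dosage),
        sum_b = sum(.data$w * (2 - .data$dosage)),
        .groups = "drop"
      ) |>
      dplyr::left_join(params[, c("snp_id", "k")], by = "snp_id")
    reps <- tidyr::expand_grid(sums, replicate = seq_len(config$n_replicates))
    n <- nrow(reps)
    base <- 1000
    tibble::tibble(
      snp_id = reps$snp_id,
      pool_id = reps$pool_id,
      replicate = reps$replicate,
      channel_A = base * reps$sum_a * rnoise(n, config$noise_cv),
      channel_B = base * reps$sum_b / reps$k * rnoise(n, config$noise_cv)
    ) |>
      dplyr::arrange(.data$snp_id, .data$pool_id, .data$replicate)
  })
}

#' Realized per-pool allele frequencies (simulation truth)
#'
#' The true frequency of allele A among the chromosomes actually pooled --
#' the target the intensity-based RAF estimate should recover.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @return A tibble: `snp_id`, `pool_id`, `group`, `gender`, `true_raf`.
#' @export
pool_truth <- function(genotypes) {
  check_columns(genotypes, c("group", "gender", "snp_id", "dosage"), "`genotypes`")
  genotypes |>
    dplyr::inner_join(pool_strata(), by = c("group", "gender")) |>
    dplyr::group_by(.data$snp_id, .data$pool_id, .data$group, .data$gender) |>
    dplyr::summarise(true_raf = sum(.data$dosage) / (2 * dplyr::n()), .groups = "drop")
}

#' Simulate a complete pooled-GWAS study
#'
#' Convenience wrapper running the whole generator: genotypes, individual
#' calibration intensities, pooled intensities, the pool design and the
#' per-SNP / per-pool truth tables.
#'
#' @param config A [sim_config()].
#' @return A named list of tibbles: `genotypes`, `calibration`, `pools`,
#'   `design`, `truth`, `params`.
#' @examples
#' study <- simulate_pool_study(sim_config(n_snps = 20, n_effect_snps = 2))
#' names(study)
#' @export
simulate_pool_study <- function(config) {
  genotypes <- simulate_genotypes(config)
  list(
    genotypes = genotypes,
    calibration = simulate_individual_intensities(genotypes, config),
    pools = construct_pools(genotypes, config),
    design = pool_design(genotypes),
    truth = pool_truth(genotypes),
    params = snp_params(config)
  )
}
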